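# Example two-arm study: fine/compact treated arm vs coarse/irregular
# control arm, matched size and uptake. Used by:
#   pettex run-all --config example_study.yaml --out report/
n_treated: 7
n_control: 7
treated:
  tumor_equivalent_diameter: 7.5
  zone_size_mean: 5
  zone_size_dispersion: 0.15
  shape_irregularity: 0
  psf_fwhm: 0.6
  noise_cv: 0.05
control:
  tumor_equivalent_diameter: 7.5
  zone_size_mean: 30
  zone_size_dispersion: 1.0
  shape_irregularity: 0.4
  psf_fwhm: 0.6
  noise_cv: 0.05
seed: 1
analysis:
  corr_cutoff: 0.8
  alpha_family: 0.05
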