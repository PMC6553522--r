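# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# the repository's standard phantom: 6 mm sphere, 1.2 mm FWHM PSF,
# 5% noise, seed 7
fixture_phantom <- function() fixture("phantom_std", function()
  generate_phantom(phantom_spec(tumor_equivalent_diameter = 6,
                                shape_irregularity = 0, psf_fwhm = 1.2,
                                noise_cv = 0.05, seed = 7)))

fixture_voi <- function() fixture("voi_std", function()
  voi_from_truth(fixture_phantom()))

fixture_features <- function() fixture("features_std", function()
  extract_all(fixture_voi()))

# a bounding volume 2 mm around the truth mask, as a manual crude box would
# be drawn
tight_bounding_volume <- function(ph, margin_mm = 2) {
  d <- dim(ph$truth_mask)
  m <- ceiling(margin_mm / ph$image$spacing)
  ci <- arrayInd(which(ph$truth_mask), d)
  lo <- pmax(apply(ci, 2, min) - m, 1)
  hi <- pmin(apply(ci, 2, max) + m, d)
  bounding_volume(ph$image, rbind(lo, hi))
}

crop_to_box <- function(arr, box)
  arr[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2], box[1, 3]:box[2, 3]]

# the two-arm world used for the headline-direction experiments:
# treated = fine, compact texture; control = coarse, irregular
fine_arm_spec <- function() phantom_spec(zone_size_mean = 5,
                                         zone_size_dispersion = 0.15,
                                         shape_irregularity = 0,
                                         psf_fwhm = 0.6, noise_cv = 0.05)
coarse_arm_spec <- function() phantom_spec(zone_size_mean = 30,
                                           zone_size_dispersion = 1.0,
                                           shape_irregularity = 0.4,
                                           psf_fwhm = 0.6, noise_cv = 0.05)
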