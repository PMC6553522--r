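test_that("degenerate no-blur no-noise phantom has exactly two intensity levels", {
  sp <- phantom_spec(tumor_equivalent_diameter = 6, shape_irregularity = 0,
                     psf_fwhm = 0, noise_cv = 0, n_uptake_classes = 1,
                     seed = 7)
  ph <- generate_phantom(sp)
  expect_length(unique(ph$image$values[ph$truth_mask]), 1L)
  expect_length(unique(ph$image$values[!ph$truth_mask]), 1L)
  expect_gt(min(ph$image$values[ph$truth_mask]),
            max(ph$image$values[!ph$truth_mask]))
})

test_that("voxelized mask volume matches the analytic sphere and converges with voxel size", {
  for (vs in c(0.6, 0.2)) {
    ph <- generate_phantom(phantom_spec(tumor_equivalent_diameter = 6,
                                        shape_irregularity = 0, psf_fwhm = 0,
                                        noise_cv = 0, voxel_size = vs, seed = 7))
    vol <- sum(ph$truth_mask) * vs^3
    expect_lt(abs(vol - 113.1) / 113.1, 0.15)
    if (vs == 0.2) expect_lt(abs(vol - 113.1) / 113.1, 0.01)
  }
})

test_that("generation is deterministic given the seed", {
  sp <- phantom_spec(seed = 42)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$truth_zone_labels, b$truth_zone_labels)
  expect_identical(a$baseline_volume, b$baseline_volume)
})

test_that("zone partition is exhaustive and exclusive over the mask", {
  ph <- generate_phantom(phantom_spec(tumor_equivalent_diameter = 8,
                                      zone_size_mean = 6, seed = 3))
  expect_identical(ph$truth_zone_labels > 0L, ph$truth_mask)
  zs <- tabulate(ph$truth_zone_labels[ph$truth_zone_labels > 0L])
  expect_true(all(zs > 0L))
  expect_identical(sum(zs), sum(ph$truth_mask))
})

test_that("empirical zone-size CV tracks the requested dispersion", {
  for (disp in c(0.5, 1.0)) {
    ph <- generate_phantom(phantom_spec(tumor_equivalent_diameter = 9,
                                        zone_size_mean = 6,
                                        zone_size_dispersion = disp,
                                        psf_fwhm = 0, noise_cv = 0, seed = 11))
    zs <- tabulate(ph$truth_zone_labels[ph$truth_zone_labels > 0L])
    expect_gte(length(zs), 50L)
    cv <- stats::sd(zs) / mean(zs)
    expect_lt(abs(cv - disp) / disp, 0.25)
  }
})

test_that("final volume is consistent with the truth mask within 15%", {
  ph <- fixture_phantom()
  vol_true <- sum(ph$truth_mask) * ph$image$spacing^3
  expect_lt(abs(ph$final_volume - vol_true) / vol_true, 0.15)
  expect_gt(ph$baseline_volume, 0)
})

test_that("spec validation rejects bad inputs", {
  expect_error(phantom_spec(zone_size_mean = 0.5), "zone_size_mean")
  expect_error(phantom_spec(tumor_uptake_mean = 1, background_uptake = 2),
               "exceed")
  expect_error(phantom_spec(voxel_size = 0), "voxel_size")
  expect_error(generate_phantom(phantom_spec(tumor_equivalent_diameter = 12,
                                             grid_dim = c(10, 40, 40))),
               "exceeds grid")
})

test_that("cohorts conserve counts, labels and determinism", {
  coh <- generate_cohort(7, 7, fine_arm_spec(), coarse_arm_spec(), seed = 1)
  expect_length(coh, 14L)
  grp <- vapply(coh, `[[`, "", "group")
  expect_identical(sum(grp == "treated"), 7L)
  expect_identical(sum(grp == "control"), 7L)
  coh2 <- generate_cohort(7, 7, fine_arm_spec(), coarse_arm_spec(), seed = 1)
  expect_identical(lapply(coh, `[[`, "image"), lapply(coh2, `[[`, "image"))
})

test_that("low-dispersion arm has uniformly smaller zone-size SD than high-dispersion arm", {
  t_spec <- phantom_spec(zone_size_dispersion = 0.1, noise_cv = 0)
  c_spec <- phantom_spec(zone_size_dispersion = 1.0, noise_cv = 0)
  coh <- generate_cohort(7, 7, t_spec, c_spec, seed = 1)
  sds <- vapply(coh, function(p) {
    zs <- tabulate(p$truth_zone_labels[p$truth_zone_labels > 0L])
    stats::sd(zs)
  }, 0)
  grp <- vapply(coh, `[[`, "", "group")
  expect_lt(max(sds[grp == "treated"]), min(sds[grp == "control"]))
})
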