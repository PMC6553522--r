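test_that("geometric features: single voxel and 2x2x2 cube closed forms", {
  g1 <- geometric_features(tumor_voi(cbind(1, 1, 1), 5, 0.6))
  expect_equal(unname(g1["vol_met"]), 0.216)
  expect_equal(unname(g1["surface_area"]), 2.16)
  expect_equal(unname(g1["surface_to_volume_ratio"]), 10)

  cube <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  g2 <- geometric_features(tumor_voi(cube, rep(1, 8), 0.6))
  expect_equal(unname(g2["surface_area"]), 8.64)
  expect_equal(unname(g2["vol_met"]), 1.728)
  expect_equal(unname(g2["surface_to_volume_ratio"]), 5)
})

test_that("sphericity ranks a ball above an equal-volume slab", {
  d <- c(20, 20, 20)
  ctr <- 10.5
  ii <- slice.index(array(0, d), 1) - ctr
  jj <- slice.index(array(0, d), 2) - ctr
  kk <- slice.index(array(0, d), 3) - ctr
  mask <- sqrt(ii^2 + jj^2 + kk^2) <= 8
  ball <- tumor_voi(arrayInd(which(mask), d), rep(1, sum(mask)), 1)
  slab_coords <- as.matrix(expand.grid(1, 1:50, 1:50))[seq_len(sum(mask)), ]
  slab <- tumor_voi(slab_coords, rep(1, sum(mask)), 1)
  expect_gt(geometric_features(ball)["sphericity"],
            geometric_features(slab)["sphericity"])
})

test_that("fractal features: solid ball, plane and constant-intensity limits", {
  d <- c(20, 20, 20)
  ctr <- 10.5
  ii <- slice.index(array(0, d), 1) - ctr
  jj <- slice.index(array(0, d), 2) - ctr
  kk <- slice.index(array(0, d), 3) - ctr
  mask <- sqrt(ii^2 + jj^2 + kk^2) <= 8
  ball <- tumor_voi(arrayInd(which(mask), d), rep(1, sum(mask)), 1)
  fb <- fractal_features(ball, quantize(ball, 8))
  # finite-size box counting of a diameter-16 solid ball; the asymptotic
  # limit is 3, the {1,2,4,8}-size estimate sits just below 2.7
  expect_gt(unname(fb["fd_mask"]), 2.5)
  expect_lte(unname(fb["fd_mask"]), 3.0)
  expect_equal(unname(fb["fd_local_std"]), 0)   # constant intensity

  plane <- tumor_voi(as.matrix(expand.grid(1:16, 1:16, 1)), rep(1, 256), 1)
  fp <- fractal_features(plane, quantize(plane, 8))
  expect_gte(unname(fp["fd_mask"]), 1.8)
  expect_lte(unname(fp["fd_mask"]), 2.1)
})

test_that("first-order features: constant, two-level and symmetric cases", {
  vc <- tumor_voi(cbind(1, 1, 1:5), rep(14.22, 5), 0.6)
  f <- first_order_features(vc, quantize(vc, 64))
  expect_equal(unname(f["met_mean"]), 14.22)
  expect_equal(unname(f["sd"]), 0)
  expect_equal(unname(f["entropy"]), 0)

  v2 <- tumor_voi(cbind(1, 1, 1:8), rep(c(0, 63), each = 4), 1)
  f2 <- first_order_features(v2, quantize(v2, 64))
  expect_equal(unname(f2["entropy"]), 1)
  expect_equal(unname(f2["uniformity"]), 0.5)

  vs <- tumor_voi(cbind(1, 1, 1:7), c(1, 2, 3, 4, 5, 6, 7), 1)
  expect_lt(abs(first_order_features(vs, quantize(vs, 8))["skewness"]), 1e-9)
})

test_that("second-order features: point mass, two-cell matrix, totality", {
  P1 <- matrix(0, 4, 4); P1[1, 1] <- 1
  expect_warning(s1 <- second_order_features(P1), "sentinel")
  expect_equal(unname(s1["glcm_entropy"]), 0)
  expect_equal(unname(s1["glcm_energy"]), 1)
  expect_equal(unname(s1["contrast"]), 0)

  P2 <- matrix(0, 2, 2); P2[1, 2] <- P2[2, 1] <- 0.5
  s2 <- suppressWarnings(second_order_features(P2))
  expect_equal(unname(s2["glcm_entropy"]), 1)
  expect_equal(unname(s2["contrast"]), 1)

  set.seed(9)
  for (i in 1:100) {
    Ng <- sample(2:6, 1)
    M <- matrix(stats::runif(Ng^2), Ng)
    M <- (M + t(M))
    M <- M / sum(M)
    expect_true(all(is.finite(suppressWarnings(second_order_features(M)))))
  }
})

test_that("higher-order features: short-run limit and the two SZV formulas", {
  voi <- tumor_voi(cbind(1, 1, 1:4), c(1, 2, 1, 2), 1)
  q <- quantize(voi, 2)
  R <- build_glrlm(q)
  h <- higher_order_features(R, build_glszm(q), build_ngtdm(q),
                             n_voxels = 4)
  expect_equal(unname(h["glrl_sre"]), 1)    # every run has length 1

  # zones {2,2}: variance form 0, non-uniformity form 2
  Z <- matrix(0, 2, 2); Z[1, 2] <- Z[2, 2] <- 1
  g <- pettex:::glszm_features(Z, n_voxels = 4)
  expect_equal(unname(g["glszm_szv_var"]), 0)
  expect_equal(unname(g["glszm_szv_nu"]), 2)

  # zones {1,4} vs {2,3}: same N_z and total voxels, higher variance for {1,4}
  Za <- matrix(0, 1, 4); Za[1, 1] <- 1; Za[1, 4] <- 1
  Zb <- matrix(0, 1, 3); Zb[1, 2] <- 1; Zb[1, 3] <- 1
  expect_gt(pettex:::glszm_features(Za, 5)["glszm_szv_var"],
            pettex:::glszm_features(Zb, 5)["glszm_szv_var"])
})

test_that("extract_all yields the exact 114-feature census, deterministically", {
  fv <- fixture_features()
  expect_length(fv$values, 114L)
  tal <- table(fv$category)
  expect_identical(as.integer(tal[c("geometric", "model_based", "first_order",
                                    "second_order", "higher_order")]),
                   c(15L, 6L, 37L, 21L, 35L))
  expect_false(any(is.na(fv$values)))
  expect_true(all(is.finite(fv$values)))
  fv2 <- extract_all(fixture_voi())
  expect_identical(fv$values, fv2$values)
})

test_that("bin-domain features are invariant under positive affine rescaling; uptake-domain scale", {
  voi <- fixture_voi()
  fv <- fixture_features()
  voi2 <- voi
  voi2$values <- voi$values * 2 + 1
  fv2 <- extract_all(voi2)
  bin_domain <- names(fv$values)[fv$category %in%
                                   c("second_order", "higher_order")]
  expect_equal(fv2$values[bin_domain], fv$values[bin_domain],
               tolerance = 1e-12)
  expect_equal(unname(fv2$values["met_mean"]),
               unname(fv$values["met_mean"]) * 2 + 1)
  expect_equal(unname(fv2$values["met_max"]),
               unname(fv$values["met_max"]) * 2 + 1)
})

test_that("the fine/coarse arms order SRE, SZV and surface-to-volume as expected", {
  # arm means over a small cohort at 5% noise: fine/compact vs
  # coarse/irregular, qualitative directions only
  n_per <- 5L
  coh <- generate_cohort(n_per, n_per, fine_arm_spec(), coarse_arm_spec(),
                         seed = 2026)
  fm <- t(vapply(coh, function(p) extract_all(voi_from_truth(p))$values,
                 numeric(114)))
  grp <- vapply(coh, `[[`, "", "group")
  fine_mean <- colMeans(fm[grp == "treated", ])
  coarse_mean <- colMeans(fm[grp == "control", ])
  expect_gt(fine_mean["glrl_sre"], coarse_mean["glrl_sre"])
  expect_lt(fine_mean["glszm_szv_var"], coarse_mean["glszm_szv_var"])
  expect_lt(fine_mean["surface_to_volume_ratio"],
            coarse_mean["surface_to_volume_ratio"])
})
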