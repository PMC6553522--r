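# Quantizer and the four texture-matrix builders, checked against hand
# examples and the brute-force oracles in helper-oracles.R.

test_that("quantizer follows the closed-form bin rule", {
  voi <- tumor_voi(cbind(1, 1, 1:64), values = 0:63, spacing = 1)
  q <- quantize(voi, 64)
  expect_identical(q$bin, 1:64)
  expect_identical(max(q$bin), 64L)
  # constant VOI -> all bin 1
  voic <- tumor_voi(cbind(1, 1, 1:4), rep(7, 4), 1)
  expect_identical(quantize(voic, 64)$bin, rep(1L, 4))
  expect_error(quantize(voi, 1), "Ng")
})

test_that("quantization is invariant to positive affine rescaling", {
  set.seed(5)
  voi <- tumor_voi(cbind(1, 1, 1:20), stats::runif(20, 2, 20), 1)
  q1 <- quantize(voi, 16)
  voi2 <- voi
  voi2$values <- voi$values * 2.5 + 3
  expect_identical(quantize(voi2, 16)$bin, q1$bin)
})

test_that("GLCM worked examples and invariants", {
  voi <- tumor_voi(matrix(c(1, 1, 1, 1, 1, 2), 2, 3, byrow = TRUE),
                   c(0, 1), 1)
  P <- build_glcm(quantize(voi, 2))
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)
  expect_equal(sum(P), 1)
  # constant VOI of n >= 2 -> all mass at (1,1)
  voic <- tumor_voi(cbind(1, 1, 1:3), rep(4, 3), 1)
  Pc <- build_glcm(quantize(voic, 8))
  expect_equal(Pc[1, 1], 1)
  # single voxel -> no pairs
  expect_error(build_glcm(quantize(tumor_voi(cbind(1, 1, 1), 5, 1), 4)),
               "no co-occurrences")
})

test_that("GLRLM worked examples and run-mass conservation", {
  # constant 1x1x4 line: one length-4 run along the axis, 48 singles
  voi <- tumor_voi(cbind(1, 1, 1:4), rep(5, 4), 1)
  q <- quantize(voi, 2)     # constant -> all bin 1
  R <- build_glrlm(q)
  expect_equal(R[1, 4], 1)
  expect_equal(R[1, 1], 48)
  expect_equal(sum(R %*% seq_len(ncol(R))), 13 * 4)
  # alternating line: no run longer than 1 anywhere
  voi2 <- tumor_voi(cbind(1, 1, 1:4), c(1, 2, 1, 2), 1)
  R2 <- build_glrlm(quantize(voi2, 2))
  expect_identical(ncol(R2), 1L)
  expect_equal(sum(R2), 13 * 4)
})

test_that("GLSZM and NGTDM worked examples", {
  voi <- tumor_voi(cbind(1, 1, 1:4), c(1, 1, 2, 2), 1)
  Z <- build_glszm(quantize(voi, 2))
  expect_equal(Z[1, 2], 1)
  expect_equal(Z[2, 2], 1)
  expect_equal(sum(Z), 2)
  # constant VOI -> one zone covering everything
  Zc <- build_glszm(quantize(tumor_voi(cbind(1, 1, 1:5), rep(2, 5), 1), 4))
  expect_equal(Zc[1, 5], 1)
  expect_equal(sum(Zc), 1)

  nt <- build_ngtdm(quantize(tumor_voi(cbind(1, 1, 1:3), c(1, 3, 1), 1), 3))
  expect_equal(nt$s[3], 2)
  expect_equal(nt$s[1], 4)
  expect_equal(nt$n, c(2, 0, 1))
})

test_that("all four builders match brute-force oracles on random small VOIs", {
  set.seed(42)
  for (i in 1:100) {
    r <- random_small_voi(max_dim = 6L, Ng = 8L)
    expect_lt(max(abs(build_glcm(r$q) - oracle_glcm(r$coords, r$bin, r$Ng))),
              1e-12)
    a <- build_glrlm(r$q); b <- oracle_glrlm(r$coords, r$bin, r$Ng)
    expect_identical(dim(a), dim(b))
    expect_true(all(a == b))
    a <- build_glszm(r$q); b <- oracle_glszm(r$coords, r$bin, r$Ng)
    expect_identical(dim(a), dim(b))
    expect_true(all(a == b))
    a <- build_ngtdm(r$q); b <- oracle_ngtdm(r$coords, r$bin, r$Ng)
    expect_lt(max(abs(a$s - b$s)), 1e-9)
    expect_identical(a$n, b$n)
  }
})

test_that("matrix invariants hold on the fixture VOI", {
  q <- quantize(fixture_voi(), 64)
  mats <- build_matrices(q)
  n <- length(q$bin)
  expect_lt(max(abs(mats$glcm - t(mats$glcm))), 1e-12)
  expect_equal(sum(mats$glcm), 1, tolerance = 1e-9)
  expect_equal(sum(mats$glrlm %*% seq_len(ncol(mats$glrlm))), 13 * n)
  expect_equal(sum(mats$glszm %*% seq_len(ncol(mats$glszm))), n)
  expect_lte(sum(mats$ngtdm$n), n)
})
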