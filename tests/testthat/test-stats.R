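test_that("caliper volume and growth formulas", {
  expect_equal(caliper_volume(8, 6), 144)
  expect_equal(caliper_volume(6, 6), 108)
  expect_equal(caliper_volume(1, 1), 0.5)
  expect_warning(v <- caliper_volume(6, 8), "swap")
  expect_equal(v, 144)
  expect_error(caliper_volume(0, 1), "positive")

  expect_equal(delta_vol(100, 100), 0)
  expect_equal(delta_vol(100, 534.8), 434.8)
  expect_equal(delta_vol(200, 100), -50)
  expect_error(delta_vol(0, 10), "positive")
})

test_that("fold change worked values and the algebraic identity", {
  expect_equal(fold_change(2, 1), 1)
  expect_equal(fold_change(1, 1), 0)
  # (t - c)/c gives -0.5 for a halved mean; the same convention that makes
  # a -0.74-fold change equal 26% of control
  expect_equal(fold_change(0.5, 1), -0.5)
  expect_equal(fold_change(0.26, 1), -0.74)
  expect_error(fold_change(1, 0), "undefined")
  set.seed(3)
  for (i in 1:50) {
    x <- stats::runif(1, -3, 3)
    c_ <- stats::runif(1, 0.1, 10)
    expect_equal(fold_change(x * c_, c_), x - 1, tolerance = 1e-12)
  }
})

test_that("Bonferroni threshold with one-significant-figure rounding", {
  b <- bonferroni_threshold(0.05, 24)
  expect_equal(b$rounded, 0.002)
  expect_equal(b$raw, 0.05 / 24)
  expect_equal(bonferroni_threshold(0.05, 1)$rounded, 0.05)
  expect_equal(bonferroni_threshold(0.05, 10)$rounded, 0.005)
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

test_that("correlation filter drops near-duplicates, keeps independents, is idempotent", {
  set.seed(7)
  n <- 12
  f1 <- stats::rnorm(n)
  x <- cbind(f1 = f1, f2 = 2 * f1 + stats::rnorm(n, 0, 1e-3),
             f3 = stats::rnorm(n))
  res <- correlation_filter(x, 0.8)
  expect_length(res$retained, 2L)
  expect_true("f3" %in% res$retained)
  expect_identical(sort(c(res$retained, res$dropped_pairs$dropped)),
                   c("f1", "f2", "f3"))
  expect_gt(abs(res$dropped_pairs$r[1]), 0.99)
  # cutoff 1 retains everything
  expect_length(correlation_filter(x, 1.0)$retained, 3L)
  # idempotence
  res2 <- correlation_filter(x[, res$retained], 0.8)
  expect_identical(res2$retained, res$retained)
  expect_identical(nrow(res2$dropped_pairs), 0L)
  # a pair at r = 0.87 loses a member at cutoff 0.8
  y <- cbind(a = f1, b = 0.87 * scale(f1)[, 1] +
               sqrt(1 - 0.87^2) * scale(stats::rnorm(n))[, 1])
  expect_length(correlation_filter(y, 0.8)$retained, 1L)
  expect_error(correlation_filter(cbind(a = rep(1, n), b = rep(2, n))),
               "constant")
})

test_that("compare_feature gates on Shapiro-Wilk and recovers known outcomes", {
  set.seed(11)
  t_ <- stats::rnorm(7, 0, 1)
  c_ <- stats::rnorm(7, 5, 1)
  r <- compare_feature(t_, c_)
  expect_identical(r$test_used, "welch_t")
  expect_lt(r$p_raw, 0.001)
  # cross-check the Welch p against the closed-form machinery
  expect_equal(r$p_raw, stats::t.test(t_, c_)$p.value)

  # heavy-tailed data fails the gate -> rank test
  skew_t <- exp(stats::rnorm(20, 0, 2))
  skew_c <- exp(stats::rnorm(20, 0.2, 2))
  r2 <- compare_feature(skew_t, skew_c)
  expect_identical(r2$test_used, "rank_test")

  # identical constant groups: no evidence
  r3 <- suppressWarnings(compare_feature(rep(2, 5), rep(2, 5)))
  expect_equal(r3$fold_change, 0)
  expect_gte(r3$p_raw, 0.99)
})

test_that("run_study separates conventional metrics, gates texture at Bonferroni", {
  set.seed(21)
  coh <- generate_cohort(4, 4, fine_arm_spec(), coarse_arm_spec(), seed = 5)
  feats <- lapply(coh, function(p) extract_all(voi_from_truth(p)))
  tab <- cohort_table(coh, feats)
  s <- suppressWarnings(run_study(tab))
  res <- s$results
  conv <- res[res$category == "conventional", ]
  expect_setequal(conv$feature,
                  c("vol_cal", "delta_vol", "vol_met", "met_mean", "met_max"))
  expect_true(all(is.na(conv$significant_bonferroni)))
  tex <- res[res$category != "conventional", ]
  # gate correctness: flag iff p below the rounded threshold
  expect_identical(tex$significant_bonferroni,
                   tex$p_raw < s$bonferroni_threshold$rounded)
  # retained set respects the cutoff
  r <- stats::cor(tab[, s$retained])
  diag(r) <- 0
  expect_lte(max(abs(r)), s$config$corr_cutoff)
  # conventional metrics never entered the filter
  expect_false(any(c("vol_met", "met_mean", "met_max") %in%
                     c(s$retained, s$dropped_pairs$dropped)))
})

test_that("null cohorts produce no systematic Bonferroni hits", {
  # identical generating distributions in both arms, 24 features, 20
  # subjects; family-wise error at the rounded 0.002 gate stays small
  set.seed(17)
  n_studies <- 200
  m <- 24
  thr <- bonferroni_threshold(0.05, m)$rounded
  fwer_hits <- 0
  for (i in seq_len(n_studies)) {
    x <- matrix(stats::rnorm(20 * m), 20, m)
    p <- vapply(seq_len(m), function(j)
      suppressWarnings(compare_feature(x[1:10, j], x[11:20, j])$p_raw), 0)
    fwer_hits <- fwer_hits + any(p < thr)
  }
  expect_lte(fwer_hits / n_studies, 0.06)
})
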