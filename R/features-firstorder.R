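# 37 first-order (histogram) features.
#
# Statistics in %ID/g are computed on the raw uptake values; histogram
# descriptors use the Ng-bin quantization (entropy in bits). Moments are
# population moments; kurtosis is excess (normal -> 0). Zero-variance
# degeneracies return 0 rather than NaN.

#' First-order features
#'
#' @param voi a [tumor_voi()].
#' @param q the matching [quantize()]d VOI.
#' @return named numeric vector of 37 features.
#' @export
first_order_features <- function(voi, q) {
  x <- voi$values
  n <- length(x)
  vs3 <- voi$spacing^3
  m <- mean(x)
  mu2 <- mean((x - m)^2)
  s <- sqrt(mu2 * n / max(1, n - 1))
  qs <- stats::quantile(x, c(.05, .1, .25, .5, .75, .9, .95), names = FALSE,
                        type = 7)
  p <- tabulate(q$bin, q$Ng) / n
  pp <- p[p > 0]
  skew <- if (mu2 > 0) mean((x - m)^3) / mu2^1.5 else 0
  kurt <- if (mu2 > 0) mean((x - m)^4) / mu2^2 - 3 else 0
  in_core <- x >= qs[2] & x <= qs[6]
  rmad <- if (any(in_core)) mean(abs(x[in_core] - mean(x[in_core]))) else 0
  mode_bin <- which.max(p)
  ib <- seq_len(q$Ng)
  hb_mean <- sum(p * ib)
  hb_var <- sum(p * (ib - hb_mean)^2)

  c(met_mean = m,
    met_min = min(x),
    met_max = max(x),
    met_median = qs[4],
    met_p05 = qs[1], met_p10 = qs[2], met_p25 = qs[3],
    met_p75 = qs[5], met_p90 = qs[6], met_p95 = qs[7],
    iqr = qs[5] - qs[3],
    interdecile_range = qs[6] - qs[2],
    range = max(x) - min(x),
    sd = s,
    variance = s^2,
    cv = if (m != 0) s / m else 0,
    mean_abs_dev = mean(abs(x - m)),
    median_abs_dev = stats::median(abs(x - qs[4])),
    robust_mean_abs_dev = rmad,
    quartile_disp = if (qs[5] + qs[3] != 0) (qs[5] - qs[3]) / (qs[5] + qs[3]) else 0,
    rms = sqrt(mean(x^2)),
    energy = sum(x^2),
    total_energy = vs3 * sum(x^2),
    entropy = -sum(pp * log2(pp)),
    uniformity = sum(p^2),
    skewness = skew,
    kurtosis_excess = kurt,
    trimmed_mean_10 = mean(x, trim = 0.1),
    hist_mode_bin = as.numeric(mode_bin),
    hist_max_prob = max(p),
    hist_bin_mean = hb_mean,
    hist_bin_variance = hb_var,
    hist_bin_skewness = if (hb_var > 0) sum(p * (ib - hb_mean)^3) / hb_var^1.5 else 0,
    hist_bin_kurtosis = if (hb_var > 0) sum(p * (ib - hb_mean)^4) / hb_var^2 - 3 else 0,
    hist_nonempty_bins = sum(p > 0),
    median_mean_diff = qs[4] - m,
    met_sum = sum(x))
}

first_order_units <- c(
  met_mean = "%ID/g", met_min = "%ID/g", met_max = "%ID/g",
  met_median = "%ID/g", met_p05 = "%ID/g", met_p10 = "%ID/g",
  met_p25 = "%ID/g", met_p75 = "%ID/g", met_p90 = "%ID/g",
  met_p95 = "%ID/g", iqr = "%ID/g", interdecile_range = "%ID/g",
  range = "%ID/g", sd = "%ID/g", variance = "(%ID/g)^2", cv = "",
  mean_abs_dev = "%ID/g", median_abs_dev = "%ID/g",
  robust_mean_abs_dev = "%ID/g", quartile_disp = "", rms = "%ID/g",
  energy = "(%ID/g)^2", total_energy = "mm^3.(%ID/g)^2", entropy = "bit",
  uniformity = "", skewness = "", kurtosis_excess = "",
  trimmed_mean_10 = "%ID/g", hist_mode_bin = "", hist_max_prob = "",
  hist_bin_mean = "", hist_bin_variance = "", hist_bin_skewness = "",
  hist_bin_kurtosis = "", hist_nonempty_bins = "", median_mean_diff = "%ID/g",
  met_sum = "%ID/g")
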