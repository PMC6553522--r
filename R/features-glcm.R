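# 21 second-order (co-occurrence) features, Haralick-style, computed from
# the normalized symmetric direction-aggregated GLCM. Entropies in bits.
# Correlation-type features on zero-variance matrices return the documented
# sentinel 0 (with a warning) instead of NaN.

#' Second-order (GLCM) features
#'
#' @param glcm normalized symmetric co-occurrence matrix from [build_glcm()].
#' @return named numeric vector of 21 features.
#' @export
second_order_features <- function(glcm) {
  P <- glcm
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mu_x <- sum(seq_len(Ng) * px)
  mu_y <- sum(seq_len(Ng) * py)
  sd_x <- sqrt(sum((seq_len(Ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(Ng) - mu_y)^2 * py))

  nz <- P > 0
  ent <- -sum(P[nz] * log2(P[nz]))
  pxs <- px[px > 0]
  pys <- py[py > 0]
  HX <- -sum(pxs * log2(pxs))
  HY <- -sum(pys * log2(pys))
  pxy_prod <- outer(px, py)
  ok1 <- P > 0 & pxy_prod > 0
  HXY1 <- -sum(P[ok1] * log2(pxy_prod[ok1]))
  ok2 <- pxy_prod > 0
  HXY2 <- -sum(pxy_prod[ok2] * log2(pxy_prod[ok2]))

  corr <- if (sd_x > 0 && sd_y > 0)
    (sum(i * j * P) - mu_x * mu_y) / (sd_x * sd_y)
  else { warning("zero-variance GLCM: correlation sentinel 0"); 0 }
  imc1 <- if (max(HX, HY) > 0) (ent - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - ent))))

  # sum (i+j) and difference |i-j| distributions
  k_sum <- 2:(2 * Ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), 0)
  k_dif <- 0:(Ng - 1)
  p_dif <- vapply(k_dif, function(k) sum(P[abs(i - j) == k]), 0)
  sa <- sum(k_sum * p_sum)
  da <- sum(k_dif * p_dif)
  ps_nz <- p_sum[p_sum > 0]
  pd_nz <- p_dif[p_dif > 0]

  offd <- abs(i - j) > 0

  c(contrast = sum(P * (i - j)^2),
    dissimilarity = sum(P * abs(i - j)),
    homogeneity = sum(P / (1 + abs(i - j))),
    inverse_diff_moment = sum(P / (1 + (i - j)^2)),
    glcm_energy = sum(P^2),
    glcm_entropy = ent,
    glcm_correlation = corr,
    autocorrelation = sum(i * j * P),
    cluster_shade = sum((i + j - mu_x - mu_y)^3 * P),
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * P),
    cluster_tendency = sum((i + j - mu_x - mu_y)^2 * P),
    imc1 = imc1,
    imc2 = imc2,
    max_probability = max(P),
    sum_average = sa,
    sum_entropy = -sum(ps_nz * log2(ps_nz)),
    sum_variance = sum((k_sum - sa)^2 * p_sum),
    difference_entropy = -sum(pd_nz * log2(pd_nz)),
    difference_variance = sum((k_dif - da)^2 * p_dif),
    joint_average = mu_x,
    inverse_variance = sum(P[offd] / (i - j)[offd]^2))
}
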