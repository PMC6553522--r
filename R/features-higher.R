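# 35 higher-order features: 16 run-length (GLRLM), 14 size-zone (GLSZM),
# 5 neighborhood gray-tone difference (NGTDM).
#
# The size-zone variability reported under the headline name "szv" is
# config-selectable between two published readings: a zone-size
# non-uniformity sum (szv_nu) and the plain variance of zone sizes
# (szv_var, the default — it directly measures "patches of different
# sizes"). Both are always present in the vector.

#' Higher-order features (GLRLM + GLSZM + NGTDM)
#'
#' @param glrlm run-length count matrix from [build_glrlm()].
#' @param glszm size-zone count matrix from [build_glszm()].
#' @param ngtdm list `s`, `n` from [build_ngtdm()].
#' @param n_voxels number of VOI voxels (for the percentage features).
#' @param n_directions number of run directions aggregated (default 13).
#' @return named numeric vector of 35 features.
#' @export
higher_order_features <- function(glrlm, glszm, ngtdm, n_voxels,
                                  n_directions = 13L) {
  c(glrlm_features(glrlm, n_voxels, n_directions),
    glszm_features(glszm, n_voxels),
    ngtdm_features(ngtdm))
}

glrlm_features <- function(R, n_voxels, n_directions = 13L) {
  if (sum(R) == 0) stop("empty run-length matrix")
  Ng <- nrow(R)
  Nr <- sum(R)
  i <- matrix(seq_len(Ng), Ng, ncol(R))
  r <- matrix(seq_len(ncol(R)), Ng, ncol(R), byrow = TRUE)
  p <- R / Nr
  mu_r <- sum(p * r)
  mu_i <- sum(p * i)
  pnz <- p[p > 0]
  c(glrl_sre = sum(R / r^2) / Nr,
    glrl_lre = sum(R * r^2) / Nr,
    glrl_gln = sum(rowSums(R)^2) / Nr,
    glrl_rln = sum(colSums(R)^2) / Nr,
    glrl_run_percentage = Nr / (n_voxels * n_directions),
    glrl_lgre = sum(R / i^2) / Nr,
    glrl_hgre = sum(R * i^2) / Nr,
    glrl_srlge = sum(R / (i^2 * r^2)) / Nr,
    glrl_srhge = sum(R * i^2 / r^2) / Nr,
    glrl_lrlge = sum(R * r^2 / i^2) / Nr,
    glrl_lrhge = sum(R * r^2 * i^2) / Nr,
    glrl_run_length_variance = sum(p * (r - mu_r)^2),
    glrl_run_entropy = -sum(pnz * log2(pnz)),
    glrl_gl_variance = sum(p * (i - mu_i)^2),
    glrl_run_mean_length = mu_r,
    glrl_gl_mean = mu_i)
}

glszm_features <- function(Z, n_voxels) {
  if (sum(Z) == 0) stop("empty size-zone matrix")
  Ng <- nrow(Z)
  Nz <- sum(Z)
  i <- matrix(seq_len(Ng), Ng, ncol(Z))
  s <- matrix(seq_len(ncol(Z)), Ng, ncol(Z), byrow = TRUE)
  p <- Z / Nz
  mu_i <- sum(p * i)
  pnz <- p[p > 0]
  # expand zone sizes with multiplicity for the dispersion form
  size_counts <- colSums(Z)
  sizes <- rep(seq_along(size_counts), size_counts)
  mu_s <- mean(sizes)
  c(glszm_sze = sum(Z / s^2) / Nz,
    glszm_lze = sum(Z * s^2) / Nz,
    glszm_intensity_variability = sum(rowSums(Z)^2) / Nz,
    glszm_szv_nu = sum(colSums(Z)^2) / Nz,
    glszm_szv_var = mean((sizes - mu_s)^2),
    glszm_zone_percentage = Nz / n_voxels,
    glszm_lize = sum(Z / i^2) / Nz,
    glszm_hize = sum(Z * i^2) / Nz,
    glszm_szlie = sum(Z / (s^2 * i^2)) / Nz,
    glszm_szhie = sum(Z * i^2 / s^2) / Nz,
    glszm_lzhie = sum(Z * s^2 * i^2) / Nz,
    glszm_lzlie = sum(Z * s^2 / i^2) / Nz,
    glszm_zone_entropy = -sum(pnz * log2(pnz)),
    glszm_gl_variance = sum(p * (i - mu_i)^2))
}

ngtdm_features <- function(ngtdm) {
  s <- ngtdm$s
  n <- ngtdm$n
  N <- sum(n)
  if (N == 0)
    return(c(ngtdm_coarseness = 0, ngtdm_contrast = 0, ngtdm_busyness = 0,
             ngtdm_complexity = 0, ngtdm_strength = 0))
  p <- n / N
  act <- which(p > 0)
  Ngp <- length(act)
  ps_dot <- sum(p * s)

  coarseness <- if (ps_dot > 0) 1 / ps_dot else 1e6  # flat-image sentinel
  contrast <- if (Ngp >= 2) {
    acc <- 0
    for (a in act) for (b in act) acc <- acc + p[a] * p[b] * (a - b)^2
    acc / (Ngp * (Ngp - 1)) * sum(s) / N
  } else 0
  bus_den <- 0
  cmp <- 0
  str_num <- 0
  for (a in act) for (b in act) {
    bus_den <- bus_den + abs(a * p[a] - b * p[b])
    if (a != b)
      cmp <- cmp + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    str_num <- str_num + (p[a] + p[b]) * (a - b)^2
  }
  c(ngtdm_coarseness = coarseness,
    ngtdm_contrast = contrast,
    ngtdm_busyness = if (bus_den > 0) ps_dot / bus_den else 0,
    ngtdm_complexity = cmp / N,
    ngtdm_strength = if (sum(s) > 0) str_num / sum(s) else 0)
}
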