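#' The 114-feature manifest
#'
#' Fixed roster of feature names and categories: 15 geometric, 6
#' model-based, 37 first-order, 21 second-order, 35 higher-order.
#'
#' @return data.frame with columns `feature`, `category`, `unit`.
#' @export
feature_manifest <- function() {
  geo <- names(geometric_units)
  frac <- c("fd_mask", "fd_intensity", "fd_local_mean", "fd_local_max",
            "fd_local_std", "lacunarity")
  fo <- names(first_order_units)
  so <- c("contrast", "dissimilarity", "homogeneity", "inverse_diff_moment",
          "glcm_energy", "glcm_entropy", "glcm_correlation", "autocorrelation",
          "cluster_shade", "cluster_prominence", "cluster_tendency",
          "imc1", "imc2", "max_probability", "sum_average", "sum_entropy",
          "sum_variance", "difference_entropy", "difference_variance",
          "joint_average", "inverse_variance")
  ho <- c("glrl_sre", "glrl_lre", "glrl_gln", "glrl_rln",
          "glrl_run_percentage", "glrl_lgre", "glrl_hgre", "glrl_srlge",
          "glrl_srhge", "glrl_lrlge", "glrl_lrhge",
          "glrl_run_length_variance", "glrl_run_entropy", "glrl_gl_variance",
          "glrl_run_mean_length", "glrl_gl_mean",
          "glszm_sze", "glszm_lze", "glszm_intensity_variability",
          "glszm_szv_nu", "glszm_szv_var", "glszm_zone_percentage",
          "glszm_lize", "glszm_hize", "glszm_szlie", "glszm_szhie",
          "glszm_lzhie", "glszm_lzlie", "glszm_zone_entropy",
          "glszm_gl_variance",
          "ngtdm_coarseness", "ngtdm_contrast", "ngtdm_busyness",
          "ngtdm_complexity", "ngtdm_strength")
  data.frame(
    feature = c(geo, frac, fo, so, ho),
    category = rep(c("geometric", "model_based", "first_order",
                     "second_order", "higher_order"),
                   times = c(length(geo), length(frac), length(fo),
                             length(so), length(ho))),
    unit = {
      u <- c(stats::setNames(unname(geometric_units), geo),
             stats::setNames(rep("", length(frac)), frac),
             stats::setNames(unname(first_order_units), fo),
             stats::setNames(rep("", length(so)), so),
             stats::setNames(rep("", length(ho)), ho))
      u[c("glcm_entropy", "sum_entropy", "difference_entropy",
          "glrl_run_entropy", "glszm_zone_entropy")] <- "bit"
      unname(u)
    },
    stringsAsFactors = FALSE)
}

#' Default analysis configuration
#'
#' @return list of tunables: `Ng` (gray levels, 64), `connectivity` (26),
#'   `szv_form` (`"glszm_szv_var"` or `"glszm_szv_nu"`: which formula
#'   carries the reported size-zone-variability name in summaries),
#'   segmentation `max_iter`/`tol`, stats `alpha_family`, `alpha_normality`,
#'   `corr_cutoff`, `fold_change_center`.
#' @export
default_config <- function() {
  list(Ng = 64L, connectivity = 26L, szv_form = "glszm_szv_var",
       max_iter = 100L, tol = 1e-4,
       alpha_family = 0.05, alpha_normality = 0.05, corr_cutoff = 0.8,
       fold_change_center = "mean")
}

#' Extract the full 114-feature vector of one VOI
#'
#' Runs quantization, the four texture-matrix builders, and all five
#' category extractors. Deterministic.
#'
#' @param voi a [tumor_voi()].
#' @param config list as produced by [default_config()].
#' @return object of class `feature_vector`: named numeric `values` (length
#'   114), `category`, `unit` (both aligned with `values`).
#' @export
extract_all <- function(voi, config = default_config()) {
  q <- quantize(voi, config$Ng)
  mats <- build_matrices(q, connectivity = config$connectivity)
  vals <- c(geometric_features(voi),
            fractal_features(voi, q),
            first_order_features(voi, q),
            second_order_features(mats$glcm),
            higher_order_features(mats$glrlm, mats$glszm, mats$ngtdm,
                                  n_voxels = length(voi),
                                  n_directions = mats$provenance$n_directions))
  man <- feature_manifest()
  if (!identical(names(vals), man$feature))
    stop("internal error: feature roster does not match manifest")
  if (any(!is.finite(vals)))
    stop("non-finite feature values: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  structure(list(values = vals,
                 category = stats::setNames(man$category, man$feature),
                 unit = stats::setNames(man$unit, man$feature)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  tal <- table(x$category)[c("geometric", "model_based", "first_order",
                             "second_order", "higher_order")]
  cat(sprintf("<feature_vector> %d features (%s)\n", length(x$values),
              paste(tal, collapse = ", ")))
  invisible(x)
}
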