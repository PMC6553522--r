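# Two-group comparison pipeline: conventional metrics, normality-gated
# tests, greedy correlation-based feature elimination, Bonferroni gate,
# fold-change reporting.

#' Caliper tumor volume
#'
#' The standard xenograft ellipsoid approximation `length * width^2 / 2`.
#' If `width > length` the two are swapped with a warning.
#'
#' @param length,width caliper measurements in mm.
#' @return volume in mm^3.
#' @examples caliper_volume(8, 6)  # 144
#' @export
caliper_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0)) stop("caliper measures must be positive")
  sw <- width > length
  if (any(sw)) {
    warning("width > length; swapping")
    tmp <- length[sw]; length[sw] <- width[sw]; width[sw] <- tmp
  }
  length * width^2 / 2
}

#' Percent volume growth
#'
#' `100 * (final - baseline) / baseline`.
#'
#' @param baseline,final volumes in mm^3; baseline must be positive.
#' @return percent change (may be negative).
#' @export
delta_vol <- function(baseline, final) {
  if (any(baseline <= 0)) stop("baseline volume must be positive")
  100 * (final - baseline) / baseline
}

#' Fold change of treated relative to control
#'
#' `(treated - control) / control`: 0 means no change, +1 doubling,
#' -1 halving.
#'
#' @param treated_value,control_value group summary values; control must be
#'   nonzero.
#' @return dimensionless fold difference.
#' @export
fold_change <- function(treated_value, control_value) {
  if (any(control_value == 0)) stop("undefined fold change (control value 0)")
  (treated_value - control_value) / control_value
}

#' Bonferroni-corrected significance threshold
#'
#' Family alpha divided by the number of tests; also reported rounded to
#' one significant figure, the form used in published summaries
#' (0.05 / 24 = 0.00208 -> 0.002).
#'
#' @param alpha_family family-wise alpha (default 0.05).
#' @param m number of tests (>= 1).
#' @return list with `raw` and `rounded`.
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  raw <- alpha_family / m
  list(raw = raw, rounded = signif(raw, 1))
}

#' Greedy correlation-based feature elimination
#'
#' Computes the pooled-group Pearson correlation matrix; while any
#' off-diagonal absolute correlation exceeds the cutoff, takes the worst
#' pair and drops the member with the larger mean absolute correlation to
#' the remaining features (ties: the lexicographically later name).
#' Zero-variance features are dropped first with a warning.
#'
#' @param x numeric matrix or data.frame, subjects x features.
#' @param cutoff absolute-correlation threshold (default 0.8).
#' @return list: `retained` (names), `dropped_pairs` (data.frame kept /
#'   dropped / r).
#' @export
correlation_filter <- function(x, cutoff = 0.8) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need >= 3 subjects")
  if (ncol(x) < 2) stop("need >= 2 features")
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("all features constant")
  dropped <- data.frame(kept = character(), dropped = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  if (any(sds == 0)) {
    warning("dropping zero-variance features: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  while (ncol(x) >= 2) {
    r <- stats::cor(x)
    diag(r) <- 0
    if (max(abs(r)) <= cutoff) break
    worst <- which(abs(r) == max(abs(r)), arr.ind = TRUE)[1, ]
    a <- colnames(x)[worst[1]]
    b <- colnames(x)[worst[2]]
    mean_abs <- rowMeans(abs(r))        # diagonal already zeroed
    drop <- if (mean_abs[a] > mean_abs[b]) a
            else if (mean_abs[b] > mean_abs[a]) b
            else sort(c(a, b))[2]       # tie: lexicographically later
    keep <- setdiff(c(a, b), drop)
    dropped <- rbind(dropped,
                     data.frame(kept = keep, dropped = drop,
                                r = r[a, b], stringsAsFactors = FALSE))
    x <- x[, colnames(x) != drop, drop = FALSE]
  }
  list(retained = colnames(x), dropped_pairs = dropped)
}

#' Normality-gated two-group comparison of one feature
#'
#' Shapiro-Wilk per group at `alpha_normality`; if both groups look normal
#' the Welch two-sample t-test is used, otherwise the unpaired Wilcoxon
#' rank-sum test (exact when sample sizes permit and there are no ties).
#' The fold change compares group means (or medians, per
#' `fold_change_center`).
#'
#' @param values_treated,values_control numeric vectors.
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @param fold_change_center "mean" (default) or "median".
#' @return list: `test_used`, `p_raw`, `fold_change`, `normality`,
#'   `shapiro_p`, per-group center and SD.
#' @export
compare_feature <- function(values_treated, values_control,
                            alpha_normality = 0.05,
                            fold_change_center = "mean") {
  t_ <- as.numeric(values_treated)
  c_ <- as.numeric(values_control)
  sw <- function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }
  sp <- c(treated = sw(t_), control = sw(c_))
  both_normal <- !any(is.na(sp)) && all(sp > alpha_normality)
  if (any(is.na(sp)))
    warning("group too small or constant for Shapiro-Wilk; using rank test")

  if (stats::sd(c(t_, c_)) == 0) {
    p <- 1                      # identical constant groups: no evidence
    test_used <- "none"
  } else if (both_normal) {
    p <- stats::t.test(t_, c_, var.equal = FALSE)$p.value
    test_used <- "welch_t"
  } else {
    p <- suppressWarnings(stats::wilcox.test(t_, c_, exact = NULL)$p.value)
    test_used <- "rank_test"
  }
  center <- if (fold_change_center == "median") stats::median else mean
  fc <- if (center(c_) == 0) {
    warning("control center is 0; fold change undefined, reporting NA")
    NA_real_
  } else fold_change(center(t_), center(c_))
  list(test_used = test_used,
       p_raw = p,
       fold_change = fc,
       normality = if (both_normal) "both_normal" else "not_normal",
       shapiro_p = sp,
       treated_center = center(t_), treated_sd = stats::sd(t_),
       control_center = center(c_), control_sd = stats::sd(c_))
}

CONVENTIONAL_METRICS <- c("vol_cal", "delta_vol", "vol_met", "met_mean", "met_max")

#' Build a cohort table from phantoms' feature vectors
#'
#' @param phantoms list of `phantom` objects with `group` set.
#' @param features list of matching `feature_vector`s.
#' @return data.frame: subject_id, group, conventional metrics (vol_cal,
#'   delta_vol duplicated from the phantom record; vol_met, met_mean,
#'   met_max from the feature vectors), then all 114 features.
#' @export
cohort_table <- function(phantoms, features) {
  stopifnot(length(phantoms) == length(features))
  fm <- t(vapply(features, function(f) f$values,
                 numeric(length(features[[1]]$values))))
  data.frame(
    subject_id = vapply(phantoms, function(p)
      if (is.null(p$subject_id)) NA_character_ else p$subject_id, ""),
    group = vapply(phantoms, `[[`, "", "group"),
    vol_cal = vapply(phantoms, `[[`, 0, "final_volume"),
    delta_vol = vapply(phantoms, function(p)
      delta_vol(p$baseline_volume, p$final_volume), 0),
    fm,
    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run the full two-group study
#'
#' Conventional metrics (vol_cal, delta_vol, vol_met, met_mean, met_max)
#' are tested and reported separately and never enter the correlation
#' filter. Texture features are filtered at the correlation cutoff, tested,
#' and gated at the Bonferroni threshold computed from the number of
#' retained features.
#'
#' @param table data.frame from [cohort_table()] (or equivalent: `group`
#'   column plus numeric feature columns).
#' @param config list as from [default_config()].
#' @return object of class `study_summary`: `results` (data.frame of
#'   per-feature tests), `retained`, `dropped_pairs`,
#'   `bonferroni_threshold`, `category_tally`.
#' @export
run_study <- function(table, config = default_config()) {
  stopifnot("group" %in% names(table))
  grp <- table$group
  if (length(unique(grp)) != 2L || !all(grp %in% c("treated", "control")))
    stop("group must be 'treated'/'control'")
  if (min(table(grp)) < 2L) stop("need >= 2 subjects per group")

  man <- feature_manifest()
  num_cols <- names(table)[vapply(table, is.numeric, TRUE)]
  conv <- intersect(c(CONVENTIONAL_METRICS,
                      c("vol_met", "met_mean", "met_max")), num_cols)
  texture <- setdiff(intersect(man$feature, num_cols),
                     c("vol_met", "met_mean", "met_max"))
  # the two size-zone-variability formulas are the same quantity under two
  # published readings; only the configured alias enters testing
  szv_other <- setdiff(c("glszm_szv_var", "glszm_szv_nu"), config$szv_form)
  texture <- setdiff(texture, szv_other)

  test_one <- function(feat) {
    r <- compare_feature(table[grp == "treated", feat],
                         table[grp == "control", feat],
                         alpha_normality = config$alpha_normality,
                         fold_change_center = config$fold_change_center)
    data.frame(feature = feat,
               category = if (feat %in% man$feature)
                 man$category[match(feat, man$feature)] else "conventional",
               test_used = r$test_used, p_raw = r$p_raw,
               fold_change = r$fold_change,
               treated_center = r$treated_center, treated_sd = r$treated_sd,
               control_center = r$control_center, control_sd = r$control_sd,
               stringsAsFactors = FALSE)
  }

  # texture branch: filter -> test -> gate
  flt <- tryCatch(
    correlation_filter(table[, texture, drop = FALSE],
                       cutoff = config$corr_cutoff),
    error = function(e) {
      warning("correlation filter failed (", conditionMessage(e),
              "); no texture features retained")
      list(retained = character(),
           dropped_pairs = data.frame(kept = character(),
                                      dropped = character(), r = numeric()))
    })
  retained <- flt$retained
  # the headline size-zone-variability alias: report the configured form
  if (length(retained)) {
    bon <- bonferroni_threshold(config$alpha_family, length(retained))
    tex_res <- do.call(rbind, lapply(retained, test_one))
    tex_res$significant_bonferroni <- tex_res$p_raw < bon$rounded
  } else {
    warning("no texture features retained; reporting conventional metrics only")
    bon <- list(raw = NA_real_, rounded = NA_real_)
    tex_res <- NULL
  }

  conv_res <- do.call(rbind, lapply(conv, test_one))
  conv_res$category <- "conventional"
  conv_res$significant_bonferroni <- NA   # reported separately, ungated

  results <- rbind(conv_res, tex_res)
  rownames(results) <- NULL
  tally <- if (length(retained))
    table(man$category[match(retained, man$feature)]) else table(character())
  structure(list(results = results,
                 retained = retained,
                 dropped_pairs = flt$dropped_pairs,
                 bonferroni_threshold = bon,
                 category_tally = tally,
                 config = config),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("<study_summary> %d features retained of %d tested; Bonferroni P < %s\n",
              length(x$retained),
              length(x$retained) + nrow(x$dropped_pairs),
              format(x$bonferroni_threshold$rounded)))
  sig <- x$results[!is.na(x$results$significant_bonferroni) &
                     x$results$significant_bonferroni, ]
  if (nrow(sig)) {
    cat("significant after Bonferroni:\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %s: fold %+0.2f, P = %.4g (%s)\n", sig$feature[i],
                  sig$fold_change[i], sig$p_raw[i], sig$test_used[i]))
  } else cat("no feature survives the Bonferroni gate\n")
  invisible(x)
}
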