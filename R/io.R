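# Table and configuration I/O.

#' Write feature vectors as a CSV table
#'
#' One row per subject, columns in fixed manifest order, plus a `#units`
#' comment row recording the unit of every feature.
#'
#' @param vectors named list of `feature_vector`s (names = subject ids).
#' @param path output CSV path.
#' @param groups optional character vector of group labels, same length.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(vectors, path, groups = NULL) {
  stopifnot(length(vectors) >= 1)
  man <- feature_manifest()
  for (v in vectors)
    if (!identical(names(v$values), man$feature))
      stop("inconsistent feature manifests across subjects")
  ids <- names(vectors)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(vectors))
  m <- do.call(rbind, lapply(vectors, function(v) v$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#units,", if (!is.null(groups)) "," else "",
                    paste(man$unit, collapse = ",")), con)
  hdr <- c("subject_id", if (!is.null(groups)) "group", man$feature)
  writeLines(paste(hdr, collapse = ","), con)
  for (k in seq_along(vectors)) {
    row <- c(ids[k], if (!is.null(groups)) groups[k],
             sprintf("%.17g", m[k, ]))
    writeLines(paste(row, collapse = ","), con)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return data.frame with subject_id (and group if present) plus the 114
#'   feature columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
}

#' Write a phantom to disk
#'
#' NIfTI image, NIfTI truth mask, and a CSV sidecar with subject id, group,
#' baseline/final caliper volumes and the generating seed.
#'
#' @param phantom a `phantom`.
#' @param dir output directory (created if needed).
#' @param stem file stem; defaults to the subject id or "phantom".
#' @return character vector of the three paths written, invisibly.
#' @export
write_phantom <- function(phantom, dir, stem = NULL) {
  if (is.null(stem))
    stem <- if (!is.null(phantom$subject_id) && !is.na(phantom$subject_id))
      phantom$subject_id else "phantom"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_img <- file.path(dir, paste0(stem, ".nii.gz"))
  p_msk <- file.path(dir, paste0(stem, "_mask.nii.gz"))
  p_csv <- file.path(dir, paste0(stem, ".csv"))
  write_image(phantom$image, p_img)
  write_image(array(as.numeric(phantom$truth_mask), dim(phantom$truth_mask)),
              p_msk, spacing = phantom$image$spacing)
  utils::write.csv(data.frame(subject_id = stem,
                              group = phantom$group,
                              baseline_volume_mm3 = phantom$baseline_volume,
                              final_volume_mm3 = phantom$final_volume,
                              seed = phantom$spec$seed),
                   p_csv, row.names = FALSE)
  invisible(c(p_img, p_msk, p_csv))
}

#' Read, validate and default-fill a study configuration
#'
#' YAML with two arm blocks (`treated`, `control`: any [phantom_spec()]
#' field), arm sizes, a `seed`, and optional analysis overrides (any
#' [default_config()] field). Unknown keys are an error; the effective
#' config round-trips bit-identically through [write_study_config()].
#'
#' @param path YAML file.
#' @return list with `n_treated`, `n_control`, `treated`, `control`
#'   ([phantom_spec()]s), `seed`, `analysis` (full [default_config()]).
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  y <- yaml::read_yaml(path)
  known_top <- c("n_treated", "n_control", "treated", "control", "seed",
                 "analysis")
  bad <- setdiff(names(y), known_top)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (k in c("n_treated", "n_control"))
    if (is.null(y[[k]]) || y[[k]] < 1) stop(k, " must be >= 1")
  if (is.null(y$seed)) stop("config must set a seed")
  arm <- function(block) {
    block <- if (is.null(block)) list() else block
    bad <- setdiff(names(block), names(formals(phantom_spec)))
    if (length(bad)) stop("unknown phantom fields: ", paste(bad, collapse = ", "))
    do.call(phantom_spec, block)
  }
  cfg <- default_config()
  if (!is.null(y$analysis)) {
    bad <- setdiff(names(y$analysis), names(cfg))
    if (length(bad)) stop("unknown analysis keys: ", paste(bad, collapse = ", "))
    cfg[names(y$analysis)] <- y$analysis
  }
  list(n_treated = as.integer(y$n_treated),
       n_control = as.integer(y$n_control),
       treated = arm(y$treated), control = arm(y$control),
       seed = as.integer(y$seed), analysis = cfg)
}

#' Write the effective study configuration
#'
#' @param config list from [read_study_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  strip <- function(sp) {
    sp <- unclass(sp)
    sp[!vapply(sp, is.null, TRUE)]
  }
  yaml::write_yaml(list(n_treated = config$n_treated,
                        n_control = config$n_control,
                        treated = strip(config$treated),
                        control = strip(config$control),
                        seed = config$seed,
                        analysis = config$analysis), path)
  invisible(path)
}

#' Write the Table-1-style study summary
#'
#' @param summary a `study_summary` from [run_study()].
#' @param dir output directory; writes `summary.csv` (per-feature results)
#'   and `foldchange_plotdata.csv` (category-grouped bar data).
#' @return paths written, invisibly.
#' @export
write_study_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "summary.csv")
  p2 <- file.path(dir, "foldchange_plotdata.csv")
  utils::write.csv(summary$results, p1, row.names = FALSE)
  tex <- summary$results[summary$results$category != "conventional", ]
  utils::write.csv(tex[order(tex$category, tex$feature),
                       c("feature", "category", "fold_change",
                         "significant_bonferroni")],
                   p2, row.names = FALSE)
  invisible(c(p1, p2))
}
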