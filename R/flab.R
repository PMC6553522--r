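# Three-class fuzzy Bayesian tumor delineation with a locally adaptive
# spatial prior.
#
# A deterministic EM-style simplification of the fuzzy locally adaptive
# Bayesian family of PET segmentation methods: voxels belong fuzzily to
# background, tumor, or a partial-volume class whose mean is a convex
# combination of the other two. Class means are initialized by Otsu
# thresholding (no random initialization), intensities are modeled as
# Gaussians, and each voxel's class prior is the average membership of its
# 26-neighborhood (plus a small floor that keeps classes alive), which
# regularizes labels spatially. All variance floors are relative to the
# intensity range, making hard labels invariant to positive affine
# intensity rescaling.

#' Bounding volume around a tumor
#'
#' @param grid a [voxel_grid()].
#' @param box inclusive 1-based index ranges, 2 x 3 matrix
#'   (rows lo/hi, columns i/j/k); defaults to the whole grid.
#' @return object of class `bounding_volume`.
#' @export
bounding_volume <- function(grid, box = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$values)
  if (is.null(box)) box <- rbind(c(1L, 1L, 1L), d)
  box <- matrix(as.integer(box), 2, 3)
  if (any(box[1, ] < 1L) || any(box[2, ] > d) || any(box[1, ] > box[2, ]))
    stop("box out of grid bounds")
  if (prod(box[2, ] - box[1, ] + 1L) < 27L)
    stop("bounding volume must enclose at least 27 voxels")
  structure(list(grid = grid, box = box), class = "bounding_volume")
}

bv_values <- function(bv) {
  b <- bv$box
  bv$grid$values[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2], b[1, 3]:b[2, 3], drop = FALSE]
}

#' Fuzzy three-class segmentation of a bounding volume
#'
#' Classifies every voxel of the bounding volume into background, tumor, or
#' partial-volume, with per-voxel fuzzy memberships summing to 1.
#' Deterministic; see the package vignette for the model.
#'
#' @param bv a [bounding_volume()].
#' @param max_iter maximum EM iterations (default 100).
#' @param tol convergence threshold on the largest membership change
#'   (default 1e-4).
#' @return object of class `class_labeling`: `memberships` (n x 3 matrix,
#'   columns background/tumor/partial_volume), `hard_label` (integer array
#'   over the box; 1 background, 2 tumor, 3 partial-volume), `classes`,
#'   `means`, `iterations`.
#' @export
segment_flab <- function(bv, max_iter = 100L, tol = 1e-4) {
  stopifnot(inherits(bv, "bounding_volume"))
  x <- bv_values(bv)
  d <- dim(x)
  rng <- max(x) - min(x)
  if (rng <= 0) stop("degenerate intensity distribution")
  sd_floor <- 1e-3 * rng

  thr <- otsu_threshold(as.numeric(x))
  lo <- x <= thr
  mu <- c(bg = mean(x[lo]), tum = mean(x[!lo]))
  if (!is.finite(mu[2])) mu[2] <- max(x)   # Otsu put everything below thr
  sep <- max(mu[2] - mu[1], sd_floor)
  # class widths are tied to the class separation: floors keep the blur
  # halo from being "infinitely many sigmas" away from a clean class, the
  # cap keeps one class from swallowing the whole histogram, and the
  # partial-volume class has a fixed narrow width so it models only the
  # transition band
  sg_lo <- function(sep) 0.25 * sep
  sg_hi <- function(sep) 0.45 * sep
  sg_pv_of <- function(sep) 0.10 * sep
  sg <- pmin(pmax(c(stats::sd(x[lo]), stats::sd(x[!lo])), sg_lo(sep), na.rm = TRUE),
             sg_hi(sep))
  alpha <- 0.5
  mu_pv <- alpha * mu[1] + (1 - alpha) * mu[2]
  sg_pv <- sg_pv_of(sep)

  # initial memberships: hard from the threshold
  u <- matrix(0, length(x), 3)
  u[cbind(seq_along(x), ifelse(lo, 1L, 2L))] <- 1

  offs <- offsets26()
  prior_floor <- 0.05
  neighbor_mean <- function(uk) {
    a <- array(uk, d)
    acc <- array(0, d)
    cnt <- array(0, d)
    for (m in seq_len(nrow(offs))) {
      b <- shift_array(a, offs[m, ])
      ok <- !is.na(b)
      acc[ok] <- acc[ok] + b[ok]
      cnt[ok] <- cnt[ok] + 1
    }
    as.numeric(acc / cnt)
  }

  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    # M-step: class parameters from memberships
    w <- colSums(u)
    mu[1] <- sum(u[, 1] * x) / max(w[1], 1e-12)
    mu[2] <- sum(u[, 2] * x) / max(w[2], 1e-12)
    if (mu[2] < mu[1]) mu <- rev(mu)
    sep <- max(mu[2] - mu[1], sd_floor)
    sg[1] <- sqrt(sum(u[, 1] * (x - mu[1])^2) / max(w[1], 1e-12))
    sg[2] <- sqrt(sum(u[, 2] * (x - mu[2])^2) / max(w[2], 1e-12))
    sg <- pmin(pmax(sg, sg_lo(sep)), sg_hi(sep))
    mu_pv <- alpha * mu[1] + (1 - alpha) * mu[2]
    sg_pv <- sg_pv_of(sep)

    # locally adaptive prior
    pri <- cbind(neighbor_mean(u[, 1]), neighbor_mean(u[, 2]),
                 neighbor_mean(u[, 3])) + prior_floor
    pri <- pri / rowSums(pri)

    # E-step in log space
    ll <- cbind(stats::dnorm(as.numeric(x), mu[1], sg[1], log = TRUE),
                stats::dnorm(as.numeric(x), mu[2], sg[2], log = TRUE),
                stats::dnorm(as.numeric(x), mu_pv, sg_pv, log = TRUE)) +
      log(pri)
    ll <- ll - apply(ll, 1, max)
    unew <- exp(ll)
    unew <- unew / rowSums(unew)

    delta <- max(abs(unew - u))
    u <- unew
    if (delta < tol) break
  }

  hard <- max.col(u, ties.method = "first")
  mx <- pmax(u[, 1], u[, 2], u[, 3])
  ties <- rowSums(abs(u - mx) < 1e-12) > 1L
  hard[ties] <- 3L                               # ambiguous -> partial volume
  structure(list(memberships = u,
                 hard_label = array(hard, d),
                 classes = c("background", "tumor", "partial_volume"),
                 means = c(background = unname(mu[1]), tumor = unname(mu[2]),
                           partial_volume = unname(mu_pv)),
                 iterations = iterations),
            class = "class_labeling")
}

#' Extract the tumor VOI from a segmentation
#'
#' Keeps voxels labeled tumor or partial-volume (background is discarded;
#' partial-volume voxels are retained with their raw values). If the kept
#' set is disconnected, only the largest 26-connected component survives.
#'
#' @param labeling a `class_labeling` from [segment_flab()].
#' @param bv the [bounding_volume()] the labeling was computed on.
#' @return a [tumor_voi()] with grid-level (1-based) coordinates.
#' @export
extract_voi <- function(labeling, bv) {
  stopifnot(inherits(labeling, "class_labeling"),
            inherits(bv, "bounding_volume"))
  keep <- labeling$hard_label != 1L
  if (!any(keep)) stop("no tumor detected")
  comp <- label_components(keep, 26L)
  main <- which.max(tabulate(comp[comp > 0L]))
  keep <- comp == main
  idx <- which(keep)
  local <- arrayInd(idx, dim(keep))
  coords <- sweep(local, 2, bv$box[1, ] - 1L, "+")
  vals <- bv$grid$values[coords]
  tumor_voi(coords, vals, bv$grid$spacing)
}

#' Dice coefficient between two masks
#'
#' @param a,b logical arrays of identical dimension.
#' @return 2|A∩B| / (|A|+|B|).
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
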