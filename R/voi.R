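#' Tumor volume of interest
#'
#' The delineated voxel set on which all features are computed: 0-based
#' voxel coordinates, one uptake value per voxel, and the lattice spacing.
#'
#' @param coords integer matrix, n x 3, voxel indices (1-based as produced
#'   by `arrayInd`; stored 0-based).
#' @param values numeric length n, uptake in %ID/g.
#' @param spacing isotropic voxel edge, mm.
#' @param zero_based set `TRUE` when `coords` are already 0-based.
#' @return object of class `tumor_voi` with fields `coords` (0-based n x 3),
#'   `values`, `spacing`.
#' @export
tumor_voi <- function(coords, values, spacing, zero_based = FALSE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (!zero_based) coords <- coords - 1L
  if (nrow(coords) == 0L) stop("empty VOI")
  if (ncol(coords) != 3L) stop("`coords` must be n x 3")
  if (length(values) != nrow(coords)) stop("one value per coordinate required")
  if (anyDuplicated(as.data.frame(coords))) stop("duplicate VOI coordinates")
  if (spacing <= 0) stop("spacing must be positive")
  structure(list(coords = coords, values = as.numeric(values),
                 spacing = as.numeric(spacing)),
            class = "tumor_voi")
}

#' @export
print.tumor_voi <- function(x, ...) {
  cat(sprintf("<tumor_voi> %d voxels @ %.3g mm, uptake [%.3g, %.3g] %%ID/g\n",
              nrow(x$coords), x$spacing, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.tumor_voi <- function(x) nrow(x$coords)

# Embed per-voxel values into a tight bounding array, NA outside the VOI.
# Returns list(arr, offset) with coords mapping v -> arr[coord - offset].
voi_embed <- function(voi, values = voi$values) {
  cr <- voi$coords
  lo <- apply(cr, 2, min)
  hi <- apply(cr, 2, max)
  d <- hi - lo + 1L
  arr <- array(NA_real_, d)
  arr[cbind(cr[, 1] - lo[1] + 1L, cr[, 2] - lo[2] + 1L, cr[, 3] - lo[3] + 1L)] <-
    values
  list(arr = arr, offset = lo, dim = d)
}

#' Quantize a VOI into equally sized gray-level bins
#'
#' Maps uptake values onto `Ng` equal-width bins spanning the VOI's own
#' min-max range: `bin(x) = min(Ng, 1 + floor(Ng * (x - min)/(max - min)))`.
#' A constant VOI maps every voxel to bin 1. The min-max range makes the
#' binning invariant to positive affine rescaling of the uptake values.
#'
#' @param voi a [tumor_voi()].
#' @param Ng number of gray levels (default 64, >= 2).
#' @return object of class `quantized_voi`: `bin` (integer per voxel),
#'   `Ng`, `bin_edges` (length Ng+1, %ID/g), plus the VOI's `coords` and
#'   `spacing`, and `arr` (bin indices embedded in a tight bounding array,
#'   NA outside the VOI).
#' @export
quantize <- function(voi, Ng = 64L) {
  stopifnot(inherits(voi, "tumor_voi"))
  Ng <- as.integer(Ng)
  if (Ng < 2L) stop("Ng must be >= 2")
  v <- voi$values
  lo <- min(v); hi <- max(v)
  if (hi > lo) {
    bin <- pmin(Ng, 1L + as.integer(floor(Ng * (v - lo) / (hi - lo))))
    edges <- seq(lo, hi, length.out = Ng + 1L)
  } else {
    bin <- rep(1L, length(v))
    edges <- rep(lo, Ng + 1L)
  }
  emb <- voi_embed(voi, as.numeric(bin))
  structure(list(bin = bin, Ng = Ng, bin_edges = edges,
                 coords = voi$coords, spacing = voi$spacing,
                 arr = emb$arr),
            class = "quantized_voi")
}
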