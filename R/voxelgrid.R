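#' 3D uptake image container
#'
#' A `voxel_grid` holds a 3D array of PET uptake values in %ID/g on an
#' isotropic lattice. It is the common currency between the phantom
#' generator, the segmentation stage and the I/O layer.
#'
#' @param values numeric 3D array, uptake in %ID/g; all values must be >= 0.
#' @param spacing isotropic voxel edge length in mm (> 0).
#' @param origin numeric length-3, mm offset of the first voxel corner.
#' @return An object of class `voxel_grid` with fields `values`, `spacing`,
#'   `origin`.
#' @examples
#' g <- voxel_grid(array(1, c(4, 4, 4)), spacing = 0.6)
#' dim(g$values)
#' @export
voxel_grid <- function(values, spacing = 0.6, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive number (mm)")
  if (any(values < 0))
    stop("uptake values must be non-negative (%ID/g)")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels @ %.3g mm, range [%.3g, %.3g] %%ID/g\n",
              d[1], d[2], d[3], x$spacing, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

# voxel volume in mm^3
voxel_volume <- function(grid_or_spacing) {
  s <- if (inherits(grid_or_spacing, "voxel_grid")) grid_or_spacing$spacing
       else grid_or_spacing
  s^3
}
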