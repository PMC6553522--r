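# 15 geometric (morphology) features of the VOI.
#
# Surface area is exposed-voxel-face counting: crude relative to meshed
# surfaces, but exactly reproducible and adequate for between-group
# contrasts. Axis lengths are 4*sqrt(eigenvalue) of the voxel-coordinate
# covariance, the convention used for ellipsoid semi-axes from second
# moments.

#' Geometric features
#'
#' @param voi a [tumor_voi()].
#' @return named numeric vector of the 15 morphology features.
#' @export
geometric_features <- function(voi) {
  vs <- voi$spacing
  cr <- voi$coords
  n <- nrow(cr)
  V <- n * vs^3

  emb <- voi_embed(voi, rep(1, n))
  a <- !is.na(emb$arr)
  faces <- 0L
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    nb <- shift_array(a, o, fill = FALSE)
    faces <- faces + sum(a & !nb)
  }
  A <- faces * vs^2

  R_eq <- (3 * V / (4 * pi))^(1 / 3)
  # surface voxels: at least one exposed face
  surf <- a
  inner <- a
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    inner <- inner & shift_array(a, o, fill = FALSE)
  surf <- a & !inner
  sidx <- which(surf)
  scoord <- arrayInd(sidx, dim(a))

  # max 3D diameter over surface voxels (all pairs; surface is small)
  if (nrow(scoord) >= 2) {
    dmat <- as.matrix(stats::dist(scoord))
    max_diam <- max(dmat) * vs
  } else max_diam <- 0
  centroid <- colMeans(cr)
  ctr_local <- centroid - emb$offset + 1
  cdist <- sqrt(rowSums((scoord - matrix(ctr_local, nrow(scoord), 3,
                                         byrow = TRUE))^2)) * vs

  if (n >= 2) {
    ev <- sort(eigen(stats::cov(cr), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev) * vs
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1  # isotropic degenerate
  flat  <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  c(vol_met = V,
    surface_area = A,
    surface_to_volume_ratio = A / V,
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    compactness1 = V / (sqrt(pi) * A^(3 / 2)),
    compactness2 = 36 * pi * V^2 / A^3,
    spherical_disproportion = A / (4 * pi * R_eq^2),
    max_diameter_3d = max_diam,
    equiv_sphere_diameter = 2 * R_eq,
    major_axis_length = axes[1],
    minor_axis_length = axes[2],
    least_axis_length = axes[3],
    elongation = elong,
    flatness = flat,
    centroid_surface_dist_mean = mean(cdist))
}

geometric_units <- c(
  vol_met = "mm^3", surface_area = "mm^2", surface_to_volume_ratio = "mm^-1",
  sphericity = "", compactness1 = "", compactness2 = "",
  spherical_disproportion = "", max_diameter_3d = "mm",
  equiv_sphere_diameter = "mm", major_axis_length = "mm",
  minor_axis_length = "mm", least_axis_length = "mm", elongation = "",
  flatness = "", centroid_surface_dist_mean = "mm")
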