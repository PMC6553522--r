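# 6 model-based (fractal) features.
#
# Mask complexity by classical box counting over box edges {1,2,4,8}
# (log-log least-squares slope: ~3 for a solid object, ~2 for a sheet).
# Intensity complexity by differential box counting (DBC) on the 64-level
# quantized VOI, globally and in sliding 5^3 windows; the window FD map is
# summarized by its mean, max and SD. Windows with zero intensity range
# carry no roughness information and are assigned local FD 0 (documented
# sentinel), so a constant VOI has FD_std = 0. Lacunarity is the gliding
# 2^3-box second-moment ratio E[m^2]/E[m]^2 of the occupancy counts.

#' Fractal features
#'
#' @param voi a [tumor_voi()].
#' @param q the matching [quantize()]d VOI.
#' @return named numeric vector of the 6 model-based features. VOIs
#'   spanning fewer than 4 voxels on any axis return all-zero sentinels.
#' @export
fractal_features <- function(voi, q) {
  emb <- voi_embed(voi, rep(1, length(voi$values)))
  mask <- !is.na(emb$arr)
  d <- dim(mask)
  if (max(d) < 4L)                # too small on every axis for any scaling
    return(c(fd_mask = 0, fd_intensity = 0, fd_local_mean = 0,
             fd_local_max = 0, fd_local_std = 0, lacunarity = 0))

  sizes <- c(1L, 2L, 4L, 8L)
  sizes <- sizes[sizes <= max(d)]
  Nbox <- vapply(sizes, function(s) count_boxes(mask, s), 0)
  fd_mask <- -unname(stats::lm(log(Nbox) ~ log(sizes))$coefficients[2])

  g <- q$arr                      # gray-level array, NA outside VOI
  dbc_sizes <- c(2L, 4L, 8L)
  dbc_sizes <- dbc_sizes[dbc_sizes <= min(max(d), 8L)]
  Ndbc <- vapply(dbc_sizes, function(s) dbc_count(g, s, q$Ng), 0)
  fd_int <- if (length(dbc_sizes) >= 2 && all(Ndbc > 0))
    -unname(stats::lm(log(Ndbc) ~ log(dbc_sizes))$coefficients[2]) else 0

  # local FD in sliding 5^3 windows centered on VOI voxels
  half <- 2L
  idx <- which(!is.na(g))
  ci <- arrayInd(idx, d)
  fds <- rep(NA_real_, length(idx))
  for (v in seq_along(idx)) {
    lo <- pmax(ci[v, ] - half, 1L)
    hi <- pmin(ci[v, ] + half, d)
    w <- g[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    wv <- w[!is.na(w)]
    if (length(wv) < 8L) next
    if (max(wv) == min(wv)) { fds[v] <- 0; next }
    n2 <- dbc_count(w, 2L, q$Ng)
    n4 <- dbc_count(w, 4L, q$Ng)
    if (n2 > 0 && n4 > 0) fds[v] <- log(n2 / n4) / log(2)
  }
  fds <- fds[!is.na(fds)]
  if (!length(fds)) fds <- 0

  c(fd_mask = fd_mask,
    fd_intensity = fd_int,
    fd_local_mean = mean(fds),
    fd_local_max = max(fds),
    fd_local_std = stats::sd(c(fds, if (length(fds) == 1L) fds)),
    lacunarity = gliding_lacunarity(mask, 2L))
}

# number of s^3 boxes containing at least one TRUE voxel, minimized over
# grid offsets (the offset-optimized count removes the alignment bias that
# otherwise flattens the log-log slope on small objects)
count_boxes <- function(mask, s) {
  if (s == 1L) return(sum(mask))
  idx <- which(mask)
  ci <- arrayInd(idx, dim(mask))
  best <- Inf
  for (oi in 0:(s - 1)) for (oj in 0:(s - 1)) for (ok in 0:(s - 1)) {
    boxes <- cbind((ci[, 1] - 1L + oi) %/% s,
                   (ci[, 2] - 1L + oj) %/% s,
                   (ci[, 3] - 1L + ok) %/% s)
    key <- boxes[, 1] + 64L * boxes[, 2] + 4096L * boxes[, 3]
    best <- min(best, length(unique(key)))
  }
  best
}

# differential box counting: per occupied s^3 spatial box, the number of
# gray-level cells of height h = s * Ng / max(dim) spanned by the box's
# intensity range
dbc_count <- function(g, s, Ng) {
  d <- dim(g)
  idx <- which(!is.na(g))
  if (!length(idx)) return(0)
  ci <- arrayInd(idx, d)
  box <- (ci - 1L) %/% s
  key <- box[, 1] + (max(box[, 1]) + 1L) * (box[, 2] + (max(box[, 2]) + 1L) * box[, 3])
  vals <- g[idx]
  h <- s * Ng / max(d)
  rng <- tapply(vals, key, function(x) max(x) - min(x))
  sum(floor(rng / h) + 1)
}

# gliding-box lacunarity of the occupancy counts at box edge r
gliding_lacunarity <- function(mask, r) {
  d <- dim(mask)
  if (any(d < r)) return(0)
  m <- array(as.numeric(mask), d)
  # sum over r^3 windows via cumulative shifts
  acc <- array(0, d - r + 1L)
  for (di in 0:(r - 1)) for (dj in 0:(r - 1)) for (dk in 0:(r - 1))
    acc <- acc + m[(1 + di):(d[1] - r + 1 + di),
                   (1 + dj):(d[2] - r + 1 + dj),
                   (1 + dk):(d[3] - r + 1 + dk), drop = FALSE]
  mu <- mean(acc)
  if (mu == 0) return(0)
  mean(acc^2) / mu^2
}
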