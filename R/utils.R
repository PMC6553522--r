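# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# The 26-neighborhood offsets as a 26 x 3 integer matrix (excludes 0,0,0).
offsets26 <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(g != 0) > 0, , drop = FALSE]
}

# The 13 unique lattice directions at Chebyshev distance 1 (half of the
# 26-neighborhood, one per +/- pair), used by GLCM and GLRLM.
directions13 <- function() {
  o <- offsets26()
  keep <- o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
    (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0)
  o[keep, , drop = FALSE]
}

# Shift a 3D array by integer offset (di,dj,dk), filling exposed planes
# with `fill`. shift_array(a, off)[i,j,k] == a[i-di, j-dj, k-dk].
shift_array <- function(a, off, fill = NA) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) { dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o) }
    else        { dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Separable Gaussian blur of a 3D array; sigma in voxels. Edge handling by
# kernel renormalization (each output voxel averages only in-grid support).
gaussian_blur3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  blur_axis <- function(m, n) {
    # m: n x q matrix, blur along rows
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- i + x
      ok <- idx >= 1 & idx <= n
      K[i, idx[ok]] <- k[ok] / sum(k[ok])
    }
    K %*% m
  }
  a <- array(blur_axis(matrix(a, d[1]), d[1]), d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(blur_axis(matrix(a, d[2]), d[2]), c(d[2], d[1], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 2, 1))
  a <- array(blur_axis(matrix(a, d[3]), d[3]), c(d[3], d[2], d[1]))
  aperm(a, c(3, 2, 1))
}

# Label connected components of a logical 3D array (26- or 6-connectivity).
# Returns an integer array, 0 outside, labels 1..n inside, by BFS.
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- if (connectivity == 26L) offsets26()
          else matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
                      ncol = 3, byrow = TRUE)
  labels <- array(0L, d)
  idx_all <- which(mask)
  n <- length(idx_all)
  if (n == 0L) return(labels)
  lin_off <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  # pad one voxel on every face so neighbor indexing never leaves the array
  dp <- d + 2L
  pm <- array(FALSE, dp)
  pm[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  pl <- array(0L, dp)
  plin_off <- offs[, 1] + offs[, 2] * dp[1] + offs[, 3] * dp[1] * dp[2]
  pidx <- which(pm)
  stack <- integer(n)
  lab <- 0L
  for (start in pidx) {
    if (pl[start] != 0L) next
    lab <- lab + 1L
    pl[start] <- lab
    stack[1L] <- start
    top <- 1L
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      nb <- v + plin_off
      nb <- nb[pm[nb] & pl[nb] == 0L]
      if (length(nb)) {
        pl[nb] <- lab
        stack[(top + 1L):(top + length(nb))] <- nb
        top <- top + length(nb)
      }
    }
  }
  labels[,,] <- pl[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  labels
}

# Otsu threshold on a numeric vector (relative 256-bin histogram); returns
# the threshold value. Affine-equivariant because binning is min-max based.
otsu_threshold <- function(x, nbins = 256L) {
  r <- range(x)
  if (r[2] <= r[1]) stop("degenerate intensity distribution")
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-length(br)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b)]
}
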