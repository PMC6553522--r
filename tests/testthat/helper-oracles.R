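# Brute-force oracles: naive enumerations, independent of the package's
# vectorized builders. Used for exact-equality checks on tiny VOIs.

# all 26 neighbor offsets / 13 unique direction vectors, written out plainly
oracle_offsets26 <- function() {
  out <- NULL
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1)
    if (di != 0 || dj != 0 || dk != 0) out <- rbind(out, c(di, dj, dk))
  out
}
oracle_dirs13 <- function() {
  o <- oracle_offsets26()
  o[o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
      (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0), , drop = FALSE]
}

# VOI as a plain lookup: list(coords = n x 3 (1-based), bin = n)
oracle_lookup <- function(coords, bin) {
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  f <- as.list(bin)
  names(f) <- key
  f
}
oracle_get <- function(lk, p) {
  v <- lk[[paste(p[1], p[2], p[3])]]
  if (is.null(v)) NA_integer_ else v
}

# GLCM: count every ordered pair over all 26 offsets (equals symmetrized
# 13-direction counting), normalize.
oracle_glcm <- function(coords, bin, Ng) {
  lk <- oracle_lookup(coords, bin)
  offs <- oracle_offsets26()
  m <- matrix(0, Ng, Ng)
  for (v in seq_len(nrow(coords))) for (m2 in seq_len(nrow(offs))) {
    nb <- oracle_get(lk, coords[v, ] + offs[m2, ])
    if (!is.na(nb)) m[bin[v], nb] <- m[bin[v], nb] + 1
  }
  if (sum(m) == 0) stop("no co-occurrences")
  m / sum(m)
}

# GLRLM: walk every maximal run explicitly, one direction at a time.
oracle_glrlm <- function(coords, bin, Ng) {
  lk <- oracle_lookup(coords, bin)
  dirs <- oracle_dirs13()
  runs <- list()
  for (m in seq_len(nrow(dirs))) {
    o <- dirs[m, ]
    for (v in seq_len(nrow(coords))) {
      p <- coords[v, ]
      prev <- oracle_get(lk, p - o)
      if (!is.na(prev) && prev == bin[v]) next   # not a run head
      len <- 1L
      nxt <- p + o
      while (!is.na(oracle_get(lk, nxt)) && oracle_get(lk, nxt) == bin[v]) {
        len <- len + 1L
        nxt <- nxt + o
      }
      runs[[length(runs) + 1L]] <- c(bin[v], len)
    }
  }
  rmax <- max(vapply(runs, `[`, 0L, 2L))
  out <- matrix(0, Ng, rmax)
  for (r in runs) out[r[1], r[2]] <- out[r[1], r[2]] + 1
  out
}

# GLSZM: grow each zone by repeated O(n^2) set expansion.
oracle_glszm <- function(coords, bin, Ng) {
  n <- nrow(coords)
  visited <- rep(FALSE, n)
  zones <- list()
  cheb_adj <- function(a, b) max(abs(a - b)) == 1
  for (v in seq_len(n)) {
    if (visited[v]) next
    members <- v
    visited[v] <- TRUE
    repeat {
      grew <- FALSE
      for (w in seq_len(n)) {
        if (visited[w] || bin[w] != bin[v]) next
        if (any(vapply(members, function(u)
          cheb_adj(coords[u, ], coords[w, ]), TRUE))) {
          members <- c(members, w)
          visited[w] <- TRUE
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    zones[[length(zones) + 1L]] <- c(bin[v], length(members))
  }
  smax <- max(vapply(zones, `[`, 0L, 2L))
  out <- matrix(0, Ng, smax)
  for (z in zones) out[z[1], z[2]] <- out[z[1], z[2]] + 1
  out
}

# NGTDM: per-voxel neighbor loop.
oracle_ngtdm <- function(coords, bin, Ng) {
  lk <- oracle_lookup(coords, bin)
  offs <- oracle_offsets26()
  s <- rep(0, Ng)
  n <- rep(0, Ng)
  for (v in seq_len(nrow(coords))) {
    nb <- c()
    for (m in seq_len(nrow(offs))) {
      x <- oracle_get(lk, coords[v, ] + offs[m, ])
      if (!is.na(x)) nb <- c(nb, x)
    }
    if (length(nb)) {
      i <- bin[v]
      s[i] <- s[i] + abs(i - mean(nb))
      n[i] <- n[i] + 1
    }
  }
  list(s = s, n = n)
}

# Random small VOI on a grid up to max_dim^3, bins in 1..Ng, guaranteed to
# contain at least one adjacent pair (so GLCM is defined).
random_small_voi <- function(max_dim = 6L, Ng = 8L) {
  repeat {
    d <- sample(2:max_dim, 3, replace = TRUE)
    n_total <- prod(d)
    n <- sample(2:min(n_total, 40L), 1)
    idx <- sort(sample(n_total, n))
    coords <- arrayInd(idx, d)
    # adjacency check (Chebyshev distance 1 somewhere)
    ok <- FALSE
    for (v in seq_len(n - 1)) {
      dd <- abs(coords[-seq_len(v), , drop = FALSE] -
                  matrix(coords[v, ], n - v, 3, byrow = TRUE))
      if (any(apply(dd, 1, max) == 1)) { ok <- TRUE; break }
    }
    if (!ok) next
    vals <- sample.int(Ng, n, replace = TRUE) + stats::runif(n, -0.2, 0.2)
    voi <- tumor_voi(coords, values = vals, spacing = 1)
    q <- quantize(voi, Ng)
    # the oracles consume the same bin assignment the quantizer produced;
    # the quantizer itself is checked by its own closed-form tests
    return(list(voi = voi, q = q, coords = coords, bin = q$bin, Ng = Ng))
  }
}
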