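# The four locoregional texture matrices on the 3D voxel lattice.
#
# Conventions (config-overridable where noted, chosen because the standard
# 3D radiomics literature uses them): GLCM and GLRLM use the 13 unique
# lattice directions at Chebyshev distance 1 and are aggregated by summing
# over directions before feature computation; GLSZM zones and NGTDM
# neighborhoods are 26-connected; neighbors outside the VOI are excluded,
# never padded.

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of gray levels at Chebyshev distance 1 over the 13 unique
#' 3D directions, restricted to voxel pairs both inside the VOI,
#' symmetrized (both orderings), aggregated over directions, and normalized
#' to sum 1.
#'
#' @param q a [quantize()]d VOI.
#' @param directions integer matrix of direction vectors (default the 13
#'   unique Chebyshev-1 directions).
#' @return Ng x Ng matrix summing to 1.
#' @export
build_glcm <- function(q, directions = directions13()) {
  stopifnot(inherits(q, "quantized_voi"))
  Ng <- q$Ng
  a <- q$arr
  counts <- matrix(0, Ng, Ng)
  for (m in seq_len(nrow(directions))) {
    b <- shift_array(a, directions[m, ])
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = 1:Ng), factor(b[ok], levels = 1:Ng))
    counts <- counts + tab + t(tab)     # symmetrize: count both orderings
  }
  tot <- sum(counts)
  if (tot == 0) stop("no co-occurrences (single-voxel VOI?)")
  unname(counts / tot)
}

#' Gray-level run-length matrix
#'
#' For each of the 13 unique Chebyshev-1 directions, counts maximal
#' collinear runs of equal gray level within the VOI; gaps (out-of-VOI
#' voxels) terminate runs. Counts are summed over directions.
#'
#' @inheritParams build_glcm
#' @return Ng x Rmax count matrix; column r holds runs of length r.
#' @export
build_glrlm <- function(q, directions = directions13()) {
  stopifnot(inherits(q, "quantized_voi"))
  Ng <- q$Ng
  a <- q$arr
  d <- dim(a)
  counts <- matrix(0, Ng, max(d))
  for (m in seq_len(nrow(directions))) {
    o <- directions[m, ]
    step <- o[1] + o[2] * d[1] + o[3] * d[1] * d[2]
    nxt <- shift_array(a, -o)                   # nxt[p] = a[p + o]
    prv <- shift_array(a, o)                    # prv[p] = a[p - o]
    same_next <- !is.na(a) & !is.na(nxt) & a == nxt
    same_prev <- !is.na(a) & !is.na(prv) & a == prv
    starts <- which(!is.na(a) & !same_prev)     # run heads along o
    len <- rep(1L, length(starts))
    cur <- starts
    alive <- same_next[cur]
    while (any(alive)) {                        # chase each run to its end
      cur[alive] <- cur[alive] + step
      len[alive] <- len[alive] + 1L
      alive[alive] <- same_next[cur[alive]]
    }
    counts <- counts + table(factor(a[starts], levels = 1:Ng),
                             factor(len, levels = seq_len(ncol(counts))))
  }
  rmax <- max(which(colSums(counts) > 0))
  counts[, seq_len(rmax), drop = FALSE]
}

#' Gray-level size-zone matrix
#'
#' Zones are maximal 26-connected components of equal gray level within the
#' VOI; entry `[i, s]` counts zones of level `i` and size `s` voxels.
#'
#' @inheritParams build_glcm
#' @param connectivity 26 (default) or 6.
#' @return Ng x Smax count matrix.
#' @export
build_glszm <- function(q, connectivity = 26L) {
  stopifnot(inherits(q, "quantized_voi"))
  Ng <- q$Ng
  a <- q$arr
  zone_sizes <- vector("list", Ng)
  for (i in sort(unique(q$bin))) {
    lab <- label_components(!is.na(a) & a == i, connectivity)
    if (max(lab) > 0L) zone_sizes[[i]] <- tabulate(lab[lab > 0L])
  }
  smax <- max(unlist(zone_sizes))
  m <- matrix(0, Ng, smax)
  for (i in seq_len(Ng))
    for (s in zone_sizes[[i]])
      m[i, s] <- m[i, s] + 1
  m
}

#' Neighborhood gray-tone difference vectors
#'
#' For every voxel with at least one in-VOI 26-neighbor, accumulates the
#' absolute difference between its gray level and the mean level of its
#' in-VOI neighbors into `s[i]`; `n[i]` counts the contributing voxels of
#' level `i`.
#'
#' @inheritParams build_glcm
#' @return list with numeric vectors `s` and `n`, each length Ng.
#' @export
build_ngtdm <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  Ng <- q$Ng
  a <- q$arr
  offs <- offsets26()
  nb_sum <- array(0, dim(a))
  nb_cnt <- array(0, dim(a))
  for (m in seq_len(nrow(offs))) {
    b <- shift_array(a, offs[m, ])
    ok <- !is.na(b)
    nb_sum[ok] <- nb_sum[ok] + b[ok]
    nb_cnt[ok] <- nb_cnt[ok] + 1
  }
  use <- !is.na(a) & nb_cnt > 0
  lev <- a[use]
  diffs <- abs(lev - nb_sum[use] / nb_cnt[use])
  s <- as.numeric(tapply(diffs, factor(lev, levels = 1:Ng), sum))
  n <- as.numeric(table(factor(lev, levels = 1:Ng)))
  s[is.na(s)] <- 0
  list(s = s, n = n)
}

#' Build all four texture matrices
#'
#' @inheritParams build_glcm
#' @param connectivity zone/neighborhood connectivity for GLSZM.
#' @return list with elements `glcm`, `glrlm`, `glszm`, `ngtdm`, and a
#'   `provenance` record of the conventions used.
#' @export
build_matrices <- function(q, directions = directions13(), connectivity = 26L) {
  list(glcm = build_glcm(q, directions),
       glrlm = build_glrlm(q, directions),
       glszm = build_glszm(q, connectivity),
       ngtdm = build_ngtdm(q),
       provenance = list(n_directions = nrow(directions), distance = 1L,
                         connectivity = connectivity, aggregated = TRUE))
}
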