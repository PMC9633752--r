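# Independent brute-force oracles for the texture-matrix builders. These
# deliberately avoid the array-shift / line-scan / stack-based algorithms of
# the implementation: pair enumeration with a closed-form offset test,
# graph-component zone decomposition, per-voxel walking for runs, and
# explicit neighbour loops for the NGTDM.

# All ordered co-occurring level pairs: (a, b) co-occur at Chebyshev
# distance d iff every coordinate difference is in {-d, 0, d} and not all 0.
oracle_glcm_counts <- function(coords, levels, ng, distance = 1) {
  n <- nrow(coords)
  pr <- expand.grid(a = seq_len(n), b = seq_len(n))
  d1 <- coords[pr$b, 1] - coords[pr$a, 1]
  d2 <- coords[pr$b, 2] - coords[pr$a, 2]
  d3 <- coords[pr$b, 3] - coords[pr$a, 3]
  ok <- d1 %in% c(-distance, 0, distance) &
    d2 %in% c(-distance, 0, distance) &
    d3 %in% c(-distance, 0, distance) &
    !(d1 == 0 & d2 == 0 & d3 == 0)
  counts <- matrix(0, ng, ng)
  if (any(ok)) {
    tb <- table(factor(levels[pr$a[ok]], levels = 1:ng),
                factor(levels[pr$b[ok]], levels = 1:ng))
    counts <- matrix(as.numeric(tb), ng, ng)
  }
  counts
}

# Zone decomposition via graph components: vertices = ROI voxels, edges =
# 26-adjacent pairs of equal level.
oracle_zones <- function(coords, levels) {
  n <- nrow(coords)
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) {
    dd <- abs(sweep(coords, 2, coords[a, ]))
    nb <- which(apply(dd, 1, max) == 1 & levels == levels[a])
    adj[a, nb] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(g)
  data.frame(level = tapply(levels, comp$membership, function(x) x[1]),
             size = as.integer(comp$csize))
}

oracle_glszm_counts <- function(coords, levels, ng) {
  z <- oracle_zones(coords, levels)
  counts <- matrix(0, ng, max(z$size))
  for (r in seq_len(nrow(z)))
    counts[z$level[r], z$size[r]] <- counts[z$level[r], z$size[r]] + 1
  counts
}

# Runs by walking: a voxel starts a run in direction `dir` iff its
# predecessor is outside the ROI or has a different level; walk forward to
# measure the length.
oracle_glrlm_counts <- function(coords, levels, ng, dirs) {
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  keys <- key(coords)
  lev_of <- stats::setNames(levels, keys)
  out <- matrix(0, ng, 1)
  for (kdir in seq_len(nrow(dirs))) {
    dir <- dirs[kdir, ]
    for (v in seq_len(nrow(coords))) {
      prev <- paste(coords[v, 1] - dir[1], coords[v, 2] - dir[2],
                    coords[v, 3] - dir[3])
      if (prev %in% keys && lev_of[[prev]] == levels[v]) next
      len <- 1L
      cur <- coords[v, ]
      repeat {
        nxt <- paste(cur[1] + dir[1], cur[2] + dir[2], cur[3] + dir[3])
        if (!(nxt %in% keys) || lev_of[[nxt]] != levels[v]) break
        len <- len + 1L
        cur <- cur + dir
      }
      if (len > ncol(out)) out <- cbind(out, matrix(0, ng, len - ncol(out)))
      out[levels[v], len] <- out[levels[v], len] + 1
    }
  }
  out
}

oracle_ngtdm <- function(coords, levels, ng) {
  n <- nrow(coords)
  s <- numeric(ng); cnt <- integer(ng)
  for (v in seq_len(n)) {
    dd <- abs(sweep(coords, 2, coords[v, ]))
    nb <- which(apply(dd, 1, max) == 1)
    if (length(nb) == 0) next
    s[levels[v]] <- s[levels[v]] + abs(levels[v] - mean(levels[nb]))
    cnt[levels[v]] <- cnt[levels[v]] + 1L
  }
  list(s = s, n = cnt)
}

# Random small ROI: a random subset of a grid with random levels.
random_roi <- function(grid = c(8, 8, 4), ng = 8, fill = 0.5) {
  all_coords <- as.matrix(expand.grid(seq_len(grid[1]), seq_len(grid[2]),
                                      seq_len(grid[3])))
  n <- max(2L, rbinom(1, nrow(all_coords), fill))
  sel <- sort(sample.int(nrow(all_coords), n))
  coords <- all_coords[sel, , drop = FALSE]
  levels <- sample.int(ng, n, replace = TRUE)
  list(coords = coords, levels = levels, ng = ng,
       q = quantized_roi_from_levels(levels, coords, ng))
}

# Build a quantized ROI directly from a full rectangular block of levels.
roi_from_array <- function(lev_array, ng = max(lev_array)) {
  coords <- as.matrix(expand.grid(seq_len(dim(lev_array)[1]),
                                  seq_len(dim(lev_array)[2]),
                                  seq_len(dim(lev_array)[3])))
  quantized_roi_from_levels(as.integer(lev_array[coords]), coords, ng)
}
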