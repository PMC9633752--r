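# 3D second-order texture matrices and the 39-feature registry.
#
# All matrices are built on the voxel lattice: offsets are in voxel units,
# anisotropic spacing is carried along for provenance but does not reweight
# directions. Computation happens on the mask bounding box; results are
# identical to full-grid computation because voxels outside the ROI are NA
# and never pair, run, zone or neighbour with ROI voxels.

# The 13 unique 3D directions (one per +/- pair of the 26 neighbours).
.directions_3d <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  # keep one of each +/- pair: first nonzero component positive
  keep <- apply(d, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  unname(d[keep, , drop = FALSE])
}

# Ordered level pairs (a, b) co-occurring at `off` (voxel offset) inside the
# ROI; pairs with either voxel outside the ROI are dropped.
.offset_pairs <- function(arr, off) {
  d <- dim(arr)
  if (any(abs(off) >= d)) return(matrix(integer(), ncol = 2))
  rng <- lapply(1:3, function(ax) {
    o <- off[ax]
    if (o >= 0) seq_len(d[ax] - o) else seq.int(1 - o, d[ax])
  })
  a <- arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  b <- arr[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3],
           drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  cbind(a[keep], b[keep])
}

#' Build a 3D gray level co-occurrence matrix
#'
#' Counts pairs of gray levels separated by each of the 13 unique 3D
#' direction offsets at the given Chebyshev distance, in both orderings, so
#' the matrix is symmetric by construction. Under `"merged"` aggregation a
#' single matrix is summed over all directions and normalized once; under
#' `"averaged"` the per-direction matrices are kept and GLCM features are
#' averaged over directions.
#'
#' @param q A [quantize_roi()] result.
#' @param distance Offset magnitude in voxels (default 1).
#' @param aggregation `"merged"` (default) or `"averaged"`.
#' @return Object of class `glcm`: `counts`, normalized `p` (sums to 1),
#'   `distance`, `directions`, `aggregation`, and for `"averaged"` a list
#'   `p_dir` of per-direction probability matrices.
#' @export
build_glcm <- function(q, distance = 1, aggregation = c("merged", "averaged")) {
  stopifnot(inherits(q, "quantized_roi"))
  aggregation <- match.arg(aggregation)
  if (distance < 1) stop("`distance` must be >= 1", call. = FALSE)
  ng <- q$ng
  dirs <- .directions_3d() * as.integer(distance)
  counts <- matrix(0, ng, ng)
  p_dir <- vector("list", nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    pr <- .offset_pairs(q$array, dirs[k, ])
    ck <- matrix(0, ng, ng)
    if (nrow(pr) > 0) {
      tb <- tabulate(pr[, 1] + (pr[, 2] - 1L) * ng, nbins = ng * ng)
      ck <- matrix(tb, ng, ng)
      ck <- ck + t(ck)                       # symmetrize: both orderings
    }
    counts <- counts + ck
    p_dir[[k]] <- if (sum(ck) > 0) ck / sum(ck) else ck
  }
  p <- if (sum(counts) > 0) counts / sum(counts) else counts
  structure(list(counts = counts, p = p, distance = distance,
                 directions = dirs, aggregation = aggregation,
                 p_dir = if (aggregation == "averaged") p_dir else NULL),
            class = "glcm")
}

# The 8 GLCM features from one probability matrix.
.glcm_feature_set <- function(p) {
  ng <- nrow(p)
  if (sum(p) == 0)     # no co-occurring pairs (e.g. singleton ROI)
    return(c(energy = 0, contrast = 0, correlation = 0, homogeneity = 0,
             variance = 0, sum_average = 0, entropy = 0, dissimilarity = 0))
  ii <- matrix(seq_len(ng), ng, ng)
  jj <- t(ii)
  px <- rowSums(p)
  mu <- sum(seq_len(ng) * px)
  v <- sum((seq_len(ng) - mu)^2 * px)
  corr <- if (v > 0) (sum(ii * jj * p) - mu^2) / v else 1
  nz <- p[p > 0]
  c(energy        = sum(p^2),
    contrast      = sum((ii - jj)^2 * p),
    correlation   = corr,
    homogeneity   = sum(p / (1 + abs(ii - jj))),
    variance      = sum((ii - mu)^2 * p),
    sum_average   = sum((ii + jj) * p),
    entropy       = -sum(nz * log2(nz)),
    dissimilarity = sum(abs(ii - jj) * p))
}

.glcm_features <- function(g) {
  if (g$aggregation == "averaged" && !is.null(g$p_dir)) {
    used <- Filter(function(p) sum(p) > 0, g$p_dir)
    if (length(used) == 0) return(.glcm_feature_set(g$p))
    fs <- vapply(used, .glcm_feature_set, numeric(8))
    rowMeans(fs)
  } else {
    .glcm_feature_set(g$p)
  }
}

#' GLCM energy (angular second moment)
#'
#' `sum_ij p(i,j)^2`; lies in (0, 1], equal to 1 exactly when a single
#' co-occurrence cell carries all mass (a perfectly uniform lesion). Higher
#' energy means a more homogeneous, orderly texture.
#'
#' @param g A [build_glcm()] result.
#' @return Scalar energy.
#' @export
glcm_energy <- function(g) {
  stopifnot(inherits(g, "glcm"))
  unname(.glcm_features(g)["energy"])
}

# --- GLRLM ------------------------------------------------------------------

# Maximal runs of equal level along one direction; runs break at ROI
# boundaries (NA or line gaps) and level changes. Returns cbind(level, length).
.runs_along <- function(arr, dir) {
  sel <- which(!is.na(arr))
  if (length(sel) == 0L) return(cbind(integer(), integer()))
  idx <- which(!is.na(arr), arr.ind = TRUE)
  lev <- arr[sel]
  tpos <- as.vector(idx %*% dir)
  # cross product with dir is constant exactly along a line in direction dir
  cx <- idx[, 2] * dir[3] - idx[, 3] * dir[2]
  cy <- idx[, 3] * dir[1] - idx[, 1] * dir[3]
  cz <- idx[, 1] * dir[2] - idx[, 2] * dir[1]
  o <- order(cx, cy, cz, tpos)
  step <- sum(dir^2)        # t advances by |dir|^2 per voxel step
  lo <- lev[o]
  newrun <- c(TRUE,
              diff(cx[o]) != 0 | diff(cy[o]) != 0 | diff(cz[o]) != 0 |
              diff(tpos[o]) != step | diff(lo) != 0L)
  rid <- cumsum(newrun)
  cbind(lo[newrun], tabulate(rid))
}

#' Build a 3D gray level run length matrix
#'
#' Counts maximal collinear runs of equal gray level along each of the 13
#' unit directions; a run is broken by a level change or by leaving the ROI.
#' `"merged"` sums run counts over directions into one matrix; `"averaged"`
#' keeps per-direction matrices and averages features over directions.
#'
#' @param q A [quantize_roi()] result.
#' @param aggregation `"merged"` (default) or `"averaged"`.
#' @return Object of class `glrlm`: `counts` (Ng x max run length),
#'   `aggregation`, optional `counts_dir`, and `n_voxels`.
#' @export
build_glrlm <- function(q, aggregation = c("merged", "averaged")) {
  stopifnot(inherits(q, "quantized_roi"))
  aggregation <- match.arg(aggregation)
  dirs <- .directions_3d()
  per <- lapply(seq_len(nrow(dirs)), function(k) .runs_along(q$array, dirs[k, ]))
  rmax <- max(1L, vapply(per, function(m) if (nrow(m)) max(m[, 2]) else 1L,
                         integer(1)))
  tomat <- function(m) {
    out <- matrix(0, q$ng, rmax)
    if (nrow(m))
      for (r in seq_len(nrow(m))) out[m[r, 1], m[r, 2]] <- out[m[r, 1], m[r, 2]] + 1
    out
  }
  counts_dir <- lapply(per, tomat)
  counts <- Reduce(`+`, counts_dir)
  structure(list(counts = counts, aggregation = aggregation,
                 counts_dir = if (aggregation == "averaged") counts_dir else NULL,
                 n_voxels = length(q$levels)),
            class = "glrlm")
}

# 13 run-length features from a count matrix (levels x run lengths).
.rl_feature_set <- function(R) {
  ns <- sum(R)
  if (ns == 0) return(stats::setNames(numeric(13), .rl_feature_suffixes))
  ng <- nrow(R); rmax <- ncol(R)
  i <- matrix(seq_len(ng), ng, rmax)
  r <- matrix(seq_len(rmax), ng, rmax, byrow = TRUE)
  nv <- sum(R * r)
  p <- R / ns
  mu_i <- sum(i * p); mu_r <- sum(r * p)
  stats::setNames(c(
    sum(R / r^2) / ns,                 # short run emphasis
    sum(R * r^2) / ns,                 # long run emphasis
    sum(rowSums(R)^2) / ns,            # gray level non-uniformity
    sum(colSums(R)^2) / ns,            # run length non-uniformity
    ns / nv,                           # run percentage
    sum(R / i^2) / ns,                 # low gray level run emphasis
    sum(R * i^2) / ns,                 # high gray level run emphasis
    sum(R / (i^2 * r^2)) / ns,         # short run low gray level emphasis
    sum(R * i^2 / r^2) / ns,           # short run high gray level emphasis
    sum(R * r^2 / i^2) / ns,           # long run low gray level emphasis
    sum(R * i^2 * r^2) / ns,           # long run high gray level emphasis
    sum(p * (i - mu_i)^2),             # gray level variance
    sum(p * (r - mu_r)^2)              # run length variance
  ), .rl_feature_suffixes)
}

.rl_feature_suffixes <- c(
  "short_run_emphasis", "long_run_emphasis", "gray_level_nonuniformity",
  "run_length_nonuniformity", "run_percentage",
  "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
  "short_run_low_gray_emphasis", "short_run_high_gray_emphasis",
  "long_run_low_gray_emphasis", "long_run_high_gray_emphasis",
  "gray_level_variance", "run_length_variance")

.glrlm_features <- function(g) {
  if (g$aggregation == "averaged" && !is.null(g$counts_dir)) {
    fs <- vapply(g$counts_dir, .rl_feature_set, numeric(13))
    rowMeans(fs)
  } else .rl_feature_set(g$counts)
}

# --- GLSZM ------------------------------------------------------------------

.neighbor_offsets_26 <- function(pd) {
  noff <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  noff <- noff[rowSums(abs(noff)) > 0, , drop = FALSE]
  noff[, 1] + noff[, 2] * pd[1] + noff[, 3] * pd[1] * pd[2]
}

.pad_na <- function(arr) {
  d <- dim(arr)
  P <- array(NA_integer_, d + 2L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  P
}

# Maximal 26-connected components of equal level: cbind(level, size).
.zone_decomposition <- function(arr) {
  P <- .pad_na(arr)
  loff <- .neighbor_offsets_26(dim(P))
  cells <- which(!is.na(P))
  visited <- logical(length(P))
  zlev <- integer(); zsize <- integer()
  stack <- integer(1024L)
  for (c0 in cells) {
    if (visited[c0]) next
    levc <- P[c0]
    visited[c0] <- TRUE
    stack[1L] <- c0; top <- 1L; size <- 0L
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L; size <- size + 1L
      nb <- v + loff
      pn <- P[nb]
      nb <- nb[which(!visited[nb] & !is.na(pn) & pn == levc)]
      if (length(nb)) {
        visited[nb] <- TRUE
        if (top + length(nb) > length(stack))
          stack <- c(stack, integer(length(stack) + length(nb)))
        stack[(top + 1L):(top + length(nb))] <- nb
        top <- top + length(nb)
      }
    }
    zlev <- c(zlev, levc); zsize <- c(zsize, size)
  }
  cbind(zlev, zsize)
}

#' Build a 3D gray level size zone matrix
#'
#' Zones are maximal 26-connected components of equal-level ROI voxels;
#' `P(i, s)` counts zones of level `i` and size `s` voxels. The total zone
#' mass satisfies `sum_i sum_s s * P(i, s) =` ROI voxel count.
#'
#' @param q A [quantize_roi()] result.
#' @return Object of class `glszm`: `counts` (Ng x max zone size),
#'   `n_zones`, `n_voxels`.
#' @export
build_glszm <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  z <- .zone_decomposition(q$array)
  smax <- max(z[, 2])
  counts <- matrix(0, q$ng, smax)
  for (r in seq_len(nrow(z)))
    counts[z[r, 1], z[r, 2]] <- counts[z[r, 1], z[r, 2]] + 1
  structure(list(counts = counts, n_zones = nrow(z),
                 n_voxels = length(q$levels)),
            class = "glszm")
}

.sz_feature_suffixes <- c(
  "small_zone_emphasis", "large_zone_emphasis", "gray_level_nonuniformity",
  "zone_size_nonuniformity", "zone_percentage",
  "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
  "small_zone_low_gray_emphasis", "small_zone_high_gray_emphasis",
  "large_zone_low_gray_emphasis", "large_zone_high_gray_emphasis",
  "gray_level_variance", "zone_size_variance")

.glszm_features <- function(z) {
  R <- z$counts
  ns <- sum(R)
  ng <- nrow(R); smax <- ncol(R)
  i <- matrix(seq_len(ng), ng, smax)
  s <- matrix(seq_len(smax), ng, smax, byrow = TRUE)
  p <- R / ns
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  stats::setNames(c(
    sum(R / s^2) / ns,
    sum(R * s^2) / ns,
    sum(rowSums(R)^2) / ns,
    sum(colSums(R)^2) / ns,
    ns / z$n_voxels,
    sum(R / i^2) / ns,
    sum(R * i^2) / ns,
    sum(R / (i^2 * s^2)) / ns,
    sum(R * i^2 / s^2) / ns,
    sum(R * s^2 / i^2) / ns,
    sum(R * i^2 * s^2) / ns,
    sum(p * (i - mu_i)^2),
    sum(p * (s - mu_s)^2)
  ), .sz_feature_suffixes)
}

#' GLSZM large zone emphasis
#'
#' `(1 / N_zones) * sum_i sum_s P(i, s) * s^2`. Always at least 1, with
#' equality exactly when every zone is a single voxel; large uniform regions
#' inflate it quadratically, making it a direct readout of texture
#' coarseness.
#'
#' @param z A [build_glszm()] result.
#' @return Scalar large zone emphasis.
#' @export
glszm_large_zone_emphasis <- function(z) {
  stopifnot(inherits(z, "glszm"))
  if (z$n_zones < 1) stop("GLSZM has no zones", call. = FALSE)
  unname(.glszm_features(z)["large_zone_emphasis"])
}

# --- NGTDM ------------------------------------------------------------------

#' Build a 3D neighborhood gray tone difference matrix
#'
#' For each ROI voxel with at least one of its 26 neighbours inside the ROI,
#' accumulates `|level - mean(neighbour levels)|` into `s[level]`; `n[level]`
#' counts contributing voxels. An isolated voxel contributes nothing and all
#' NGTDM features are 0 by convention in that degenerate case.
#'
#' @param q A [quantize_roi()] result.
#' @return Object of class `ngtdm`: vectors `s` and `n` of length Ng.
#' @export
build_ngtdm <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  P <- .pad_na(q$array)
  loff <- .neighbor_offsets_26(dim(P))
  cells <- which(!is.na(P))
  nbsum <- numeric(length(cells))
  nbcnt <- integer(length(cells))
  for (o in loff) {
    pn <- P[cells + o]
    ok <- !is.na(pn)
    nbsum[ok] <- nbsum[ok] + pn[ok]
    nbcnt <- nbcnt + ok
  }
  lev <- P[cells]
  has <- nbcnt > 0L
  s <- numeric(q$ng)
  n <- integer(q$ng)
  if (any(has)) {
    diffs <- abs(lev[has] - nbsum[has] / nbcnt[has])
    agg <- rowsum(diffs, lev[has])
    s[as.integer(rownames(agg))] <- agg[, 1]
    n <- tabulate(lev[has], nbins = q$ng)
  }
  structure(list(s = s, n = n), class = "ngtdm")
}

# Amadasun-King features. Degenerate conventions: no contributing voxels ->
# all 0; flat texture (total difference 0) -> coarseness capped at 1e6,
# busyness/strength 0.
.ngtdm_features <- function(m) {
  out <- stats::setNames(numeric(5),
                         c("coarseness", "contrast", "busyness",
                           "complexity", "strength"))
  nvc <- sum(m$n)
  if (nvc == 0) return(out)
  occ <- which(m$n > 0L)
  p <- m$n / nvc
  s <- m$s
  ngp <- length(occ)
  den <- sum(p[occ] * s[occ])
  out["coarseness"] <- if (den > 0) 1 / den else 1e6
  if (ngp > 1) {
    pi_ <- p[occ]; si_ <- s[occ]; gi <- occ
    d2 <- outer(gi, gi, function(a, b) (a - b)^2)
    out["contrast"] <- (sum(outer(pi_, pi_) * d2) / (ngp * (ngp - 1))) *
      (sum(s) / nvc)
    bden <- sum(abs(outer(gi * pi_, gi * pi_, `-`)))
    out["busyness"] <- if (bden > 0) den / bden else 0
    dd <- abs(outer(gi, gi, `-`))
    psum <- outer(pi_, pi_, `+`)
    out["complexity"] <- sum(dd * (outer(pi_ * si_, pi_ * si_, `+`)) / psum) / nvc
    ssum <- sum(si_)
    out["strength"] <- if (ssum > 0) sum(psum * d2) / ssum else 0
  }
  out
}

# --- Registry and extraction ------------------------------------------------

#' Canonical registry of the 39 second-order texture features
#'
#' Fixed, documented ordering: 8 GLCM, 13 GLRLM, 13 GLSZM, 5 NGTDM, with
#' family-prefixed names. Feature vectors are always emitted in this order.
#'
#' @return Character vector of 39 feature names.
#' @export
feature_registry <- function() {
  c(paste0("glcm_", c("energy", "contrast", "correlation", "homogeneity",
                      "variance", "sum_average", "entropy", "dissimilarity")),
    paste0("glrlm_", .rl_feature_suffixes),
    paste0("glszm_", .sz_feature_suffixes),
    paste0("ngtdm_", c("coarseness", "contrast", "busyness", "complexity",
                       "strength")))
}

#' Texture extraction configuration
#'
#' @param glcm_distance Co-occurrence offset magnitude in voxels (default 1).
#' @param glcm_aggregation,glrlm_aggregation `"merged"` (single matrix summed
#'   over the 13 directions, the default) or `"averaged"` (features averaged
#'   over per-direction matrices).
#' @return A list of class `texture_config`.
#' @export
texture_config <- function(glcm_distance = 1,
                           glcm_aggregation = "merged",
                           glrlm_aggregation = "merged") {
  structure(list(glcm_distance = glcm_distance,
                 glcm_aggregation = glcm_aggregation,
                 glrlm_aggregation = glrlm_aggregation),
            class = "texture_config")
}

#' Extract the 39 second-order texture features from a quantized ROI
#'
#' Deterministic: the same ROI always yields a bit-identical vector, in the
#' fixed [feature_registry()] order. Degenerate ROIs (single voxel, single
#' level) return defined values rather than erroring, so a longitudinal
#' cohort never crashes mid-extraction.
#'
#' @param q A [quantize_roi()] result.
#' @param config A [texture_config()].
#' @return Named numeric vector of length 39, all finite.
#' @export
extract_features <- function(q, config = texture_config()) {
  stopifnot(inherits(q, "quantized_roi"))
  g <- build_glcm(q, distance = config$glcm_distance,
                  aggregation = config$glcm_aggregation)
  r <- build_glrlm(q, aggregation = config$glrlm_aggregation)
  z <- build_glszm(q)
  m <- build_ngtdm(q)
  out <- c(stats::setNames(.glcm_features(g),
                           paste0("glcm_", names(.glcm_feature_set(g$p)))),
           stats::setNames(.glrlm_features(r),
                           paste0("glrlm_", .rl_feature_suffixes)),
           stats::setNames(.glszm_features(z),
                           paste0("glszm_", .sz_feature_suffixes)),
           stats::setNames(.ngtdm_features(m),
                           paste0("ngtdm_", names(.ngtdm_features(m)))))
  out <- out[feature_registry()]
  stopifnot(length(out) == 39L, all(is.finite(out)))
  out
}
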