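line_roi <- function(levels, ng = max(levels)) {
  roi_from_array(array(as.integer(levels), c(1, 1, length(levels))), ng)
}

test_that("GLCM handles constant and hand-enumerated ROIs", {
  q <- roi_from_array(array(1L, c(3, 2, 2)), ng = 4)
  g <- build_glcm(q)
  expect_equal(sum(g$p), 1)
  expect_equal(g$p[1, 1], 1)
  expect_equal(glcm_energy(g), 1)

  # 1x1x4 line (1,2,1,2): 3 adjacent pairs, symmetrized
  g2 <- build_glcm(line_roi(c(1, 2, 1, 2)))
  expect_equal(g2$p[1, 2], 0.5)
  expect_equal(g2$p[2, 1], 0.5)
  expect_equal(sum(g2$p), 1)
  expect_equal(glcm_energy(g2), 0.5)     # uniform p over 2 cells -> 1/2

  expect_error(build_glcm(q, distance = 0), "distance")
})

test_that("GLCM is symmetric, normalized, and energy maximal iff one cell", {
  set.seed(101)
  for (i in 1:10) {
    r <- random_roi()
    g <- build_glcm(r$q)
    expect_equal(g$p, t(g$p))
    expect_equal(sum(g$p), 1)
    e <- glcm_energy(g)
    expect_true(e > 0 && e <= 1)
    expect_identical(e == 1, sum(g$p > 0) == 1L)
  }
})

test_that("GLSZM closed forms: single zone N^2, singleton zones 1", {
  q <- roi_from_array(array(2L, c(3, 3, 2)), ng = 4)
  z <- build_glszm(q)
  expect_identical(z$n_zones, 1L)
  expect_equal(glszm_large_zone_emphasis(z), 18^2)

  # every voxel a distinct level -> N singleton zones
  q2 <- line_roi(1:6)
  z2 <- build_glszm(q2)
  expect_identical(z2$n_zones, 6L)
  expect_equal(glszm_large_zone_emphasis(z2), 1)

  # zones of sizes 1, 2, 3 -> (1 + 4 + 9)/3
  z3 <- build_glszm(line_roi(c(1, 2, 2, 3, 3, 3)))
  expect_equal(glszm_large_zone_emphasis(z3), 14 / 3)
})

test_that("GLRLM counts runs per direction with boundary breaks", {
  # 1x1x5 constant: one axial run of 5; the 12 other directions see 5
  # singleton runs each
  r <- build_glrlm(line_roi(rep(3, 5), ng = 4))
  expect_equal(r$counts[3, 5], 1)
  expect_equal(r$counts[3, 1], 60)
  expect_equal(sum(r$counts[, 5]), 1)

  # alternating levels: every run has length 1
  r2 <- build_glrlm(line_roi(c(1, 2, 1, 2)))
  expect_equal(sum(r2$counts[, 1]), 52)   # 13 directions x 4 voxels
  expect_true(all(r2$counts[, -1] == 0))
})

test_that("NGTDM degenerate conventions hold", {
  m <- build_ngtdm(roi_from_array(array(2L, c(3, 3, 3)), ng = 4))
  expect_true(all(m$s == 0))
  expect_equal(sum(m$n), 27)

  # isolated voxel: no valid neighbours, features 0 by convention
  q1 <- quantized_roi_from_levels(2L, matrix(c(1L, 1L, 1L), 1), ng = 4)
  m1 <- build_ngtdm(q1)
  expect_true(all(m1$n == 0))
  f1 <- extract_features(q1)
  expect_true(all(f1[paste0("ngtdm_", c("coarseness", "contrast", "busyness",
                                        "complexity", "strength"))] == 0))
})

test_that("matrix builders match independent brute-force oracles", {
  dirs13 <- deltarad:::.directions_3d()
  set.seed(202)
  n_checked <- 0
  for (i in 1:52) {
    r <- random_roi(grid = c(sample(3:8, 1), sample(3:8, 1), sample(2:4, 1)),
                    ng = sample(3:8, 1), fill = runif(1, 0.3, 0.9))
    dist <- if (i %% 10 == 0) 2 else 1
    g <- build_glcm(r$q, distance = dist)
    expect_equal(g$counts,
                 oracle_glcm_counts(r$coords, r$levels, r$ng, dist))
    z <- build_glszm(r$q)
    oz <- oracle_glszm_counts(r$coords, r$levels, r$ng)
    expect_equal(z$counts[, seq_len(ncol(oz)), drop = FALSE], oz,
                 ignore_attr = TRUE)
    expect_identical(z$n_zones, as.integer(sum(oz)))
    rl <- build_glrlm(r$q)
    orl <- oracle_glrlm_counts(r$coords, r$levels, r$ng, dirs13)
    expect_equal(rl$counts[, seq_len(ncol(orl)), drop = FALSE], orl,
                 ignore_attr = TRUE)
    ng_ <- build_ngtdm(r$q)
    ong <- oracle_ngtdm(r$coords, r$levels, r$ng)
    expect_equal(ng_$s, ong$s)
    expect_identical(as.integer(ng_$n), ong$n)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 50)
})

test_that("mass-conservation invariants hold on random ROIs", {
  set.seed(303)
  for (i in 1:15) {
    r <- random_roi()
    n_vox <- length(r$q$levels)
    z <- build_glszm(r$q)
    s <- matrix(seq_len(ncol(z$counts)), nrow(z$counts), ncol(z$counts),
                byrow = TRUE)
    expect_equal(sum(z$counts * s), n_vox)      # zone mass = voxel count
    lze <- glszm_large_zone_emphasis(z)
    expect_gte(lze, 1)
    if (all(z$counts[, -1] == 0)) expect_equal(lze, 1)
    rl <- build_glrlm(r$q)
    rr <- matrix(seq_len(ncol(rl$counts)), nrow(rl$counts), ncol(rl$counts),
                 byrow = TRUE)
    expect_equal(sum(rl$counts * rr), 13 * n_vox)  # 13 merged directions
    m <- build_ngtdm(r$q)
    expect_true(all(m$s >= 0))
  }
})

test_that("energy and LZE are invariant to label permutation and translation", {
  set.seed(404)
  for (i in 1:10) {
    r <- random_roi(ng = 6)
    perm <- sample(6)
    q_perm <- quantized_roi_from_levels(perm[r$levels], r$coords, 6)
    expect_equal(glcm_energy(build_glcm(q_perm)),
                 glcm_energy(build_glcm(r$q)))
    expect_equal(glszm_large_zone_emphasis(build_glszm(q_perm)),
                 glszm_large_zone_emphasis(build_glszm(r$q)))
    shift <- sample(0:7, 3, replace = TRUE)
    q_shift <- quantized_roi_from_levels(
      r$levels, sweep(r$coords, 2, shift, `+`), r$ng)
    expect_equal(extract_features(q_shift), extract_features(r$q))
  }
})

test_that("coarser equal-level blocks strictly increase LZE", {
  d <- c(8, 8, 8)
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  fine <- array(((idx[, 1] + 2 * idx[, 2] + 4 * idx[, 3]) %% 8) + 1L, d)
  coarse <- array(((idx[, 1] %/% 2 + 2 * (idx[, 2] %/% 2) +
                      4 * (idx[, 3] %/% 2)) %% 8) + 1L, d)
  lze_fine <- glszm_large_zone_emphasis(build_glszm(roi_from_array(fine, 8)))
  lze_coarse <- glszm_large_zone_emphasis(build_glszm(roi_from_array(coarse, 8)))
  expect_equal(lze_fine, 1)     # every voxel its own zone by construction
  expect_equal(lze_coarse, 64)  # 2x2x2 blocks: all zones of size 8
  expect_gt(lze_coarse, lze_fine)
})

test_that("extract_features returns the 39-feature contract deterministically", {
  expect_length(feature_registry(), 39)
  expect_true(all(c("glcm_energy", "glszm_large_zone_emphasis") %in%
                    feature_registry()))
  q <- roi_from_array(array(1L, c(4, 3, 2)), ng = 64)
  f <- extract_features(q)
  expect_identical(names(f), feature_registry())
  expect_true(all(is.finite(f)))
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glszm_large_zone_emphasis"]), 24^2)

  set.seed(7)
  r <- random_roi()
  expect_identical(extract_features(r$q), extract_features(r$q))
  # averaged aggregation is a valid configuration too
  f_avg <- extract_features(r$q, texture_config(glcm_aggregation = "averaged",
                                                glrlm_aggregation = "averaged"))
  expect_true(all(is.finite(f_avg)))
})
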