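test_that("baseline screening applies Bonferroni over 39 features", {
  # raw p of 0.002 over 39 tests is not significant (0.078)
  set.seed(1)
  X <- matrix(rnorm(22 * 39), 22, 39, dimnames = list(NULL, feature_registry()))
  y <- c(rep(TRUE, 7), rep(FALSE, 15))
  rep1 <- screen_baseline_features(X, y)
  expect_equal(rep1$p_bonferroni, pmin(1, rep1$p_raw * 39))
  expect_identical(rep1$significant, rep1$p_bonferroni <= 0.05)

  # permuted labels: null behaviour, nothing significant
  set.seed(2)
  rep0 <- screen_baseline_features(X, sample(y))
  expect_false(any(rep0$significant))

  # a 10-pooled-SD shift with n = 11 + 11 survives correction
  X2 <- matrix(rnorm(22 * 39), 22, 39, dimnames = list(NULL, feature_registry()))
  y2 <- rep(c(TRUE, FALSE), each = 11)
  X2[y2, "glcm_energy"] <- X2[y2, "glcm_energy"] + 10
  rep2 <- screen_baseline_features(X2, y2)
  expect_true(rep2$significant[rep2$feature == "glcm_energy"])
  expect_identical(sum(rep2$significant), 1L)

  expect_error(screen_baseline_features(X, rep(TRUE, 22)), "2 patients")
})

test_that("AUC follows the Mann-Whitney tie convention and its identities", {
  y <- c(rep(TRUE, 3), rep(FALSE, 4))
  expect_equal(auc(c(4, 5, 6, 1, 2, 3, 3.5), y), 1)
  expect_equal(auc(c(1, 2, 3, 4, 5, 6, 7), c(rep(FALSE, 3), rep(TRUE, 4))), 1)
  expect_equal(auc(-c(4, 5, 6, 1, 2, 3, 3.5), y), 0)
  expect_equal(auc(rep(2, 7), y), 0.5)
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(10)
  for (i in 1:10) {
    sc <- rnorm(20)            # tie-free
    yy <- sample(c(TRUE, FALSE), 20, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(yy) || all(yy)) next
    expect_equal(auc(sc, yy) + auc(-sc, yy), 1)
    expect_equal(auc(exp(sc / 3), yy), auc(sc, yy))  # monotone invariance
  }
})

test_that("Gini ranking recovers a planted separator and zeroes constants", {
  # one perfectly separating feature among 38 noise features
  hits <- 0
  for (s in 1:50) {
    tab <- generate_feature_table(n = 22, class_counts = c(15, 7),
                                  planted_features = "glcm_energy",
                                  effect_size = 4, seed = s)
    g <- rank_features_gini(tab$X, tab$y, seed = s)
    hits <- hits + (g$ranking[1] == "glcm_energy")
  }
  expect_gte(hits, 45)    # >= 90% of 50 seeded runs

  # a zero-variance feature can never split and gets importance 0
  tab <- generate_feature_table(seed = 3)
  X <- tab$X; X[, "ngtdm_busyness"] <- 5
  g <- rank_features_gini(X, tab$y, seed = 3)
  expect_equal(unname(g$importance["ngtdm_busyness"]), 0)

  # fixed seed => bit-reproducible
  g1 <- rank_features_gini(tab$X, tab$y, seed = 11)
  g2 <- rank_features_gini(tab$X, tab$y, seed = 11)
  expect_identical(g1$importance, g2$importance)
  expect_identical(g1$top2, g2$top2)

  expect_error(rank_features_gini(tab$X, rep(FALSE, 22)), "single class")
})

test_that("bootstrap AUC report is sound on separable and null data", {
  # perfectly separable features
  tab <- generate_feature_table(planted_features = c("glcm_energy",
                                                     "glszm_large_zone_emphasis"),
                                effect_size = 6, seed = 2)
  b <- bootstrap_lr_auc(tab$X[, c("glcm_energy", "glszm_large_zone_emphasis")],
                        tab$y, n_iter = 300, seed = 2)
  expect_equal(b$mean_auc, 1)
  expect_length(b$aucs, 300)
  expect_true(all(b$aucs >= 0 & b$aucs <= 1))
  expect_true(b$p2.5 <= b$mean_auc && b$mean_auc <= b$p97.5)

  # null: label-independent features; the per-cohort mean is noisy at
  # n = 22, so average over cohorts to estimate the regime
  means <- sapply(1:12, function(s) {
    nt <- generate_feature_table(effect_size = 0, seed = 100 + s)
    bootstrap_lr_auc(nt$X[, 1:2], nt$y, n_iter = 150, seed = s)$mean_auc
  })
  expect_gt(mean(means), 0.40)
  expect_lt(mean(means), 0.60)

  # determinism in the seed; percentile bracketing
  b1 <- bootstrap_lr_auc(tab$X[, 1:2], tab$y, n_iter = 50, seed = 5)
  b2 <- bootstrap_lr_auc(tab$X[, 1:2], tab$y, n_iter = 50, seed = 5)
  expect_identical(b1$aucs, b2$aucs)

  expect_error(bootstrap_lr_auc(tab$X[1:3, 1:2], tab$y[1:3]), "2 patients")
})

test_that("logistic scores stay finite under complete separation", {
  X <- cbind(c(rnorm(10, -3), rnorm(10, 3)), rnorm(20))
  y <- rep(c(FALSE, TRUE), each = 10)
  sc <- deltarad:::.lr_score(X, y, X)
  expect_true(all(is.finite(sc)))
  expect_equal(auc(sc, y), 1)    # training AUC 1 on separated data
})

test_that("clinical and combined forests rank planted signal first", {
  tab <- generate_feature_table(planted_features = c("glcm_energy",
                                                     "glszm_large_zone_emphasis"),
                                effect_size = 3, seed = 4)
  cov <- generate_clinical_covariates(22, seed = 4, informative = FALSE)
  cov$poor_response <- tab$y

  fits <- fit_clinical_and_combined(
    cov, top2_deltas = tab$X[, c("glcm_energy", "glszm_large_zone_emphasis")],
    seed = 4)
  expect_s3_class(fits, "clinical_models")
  # combined model: the two delta features outrank every covariate
  expect_setequal(fits$combined$ranking[1:2],
                  c("glcm_energy", "glszm_large_zone_emphasis"))
  expect_true(fits$combined$oob_auc > fits$clinical$oob_auc)

  # constant covariates have no importance
  cov2 <- cov
  cov2$age <- 60; cov2$total_bed <- 100; cov2$bed_per_fx <- 20
  cov2$tumor_size <- 3
  f2 <- fit_clinical_and_combined(cov2, seed = 4)
  expect_true(all(f2$clinical$importance == 0))

  # a single perfectly predictive covariate ranks first
  cov3 <- cov
  cov3$tumor_size <- ifelse(tab$y, 8, 2)
  f3 <- fit_clinical_and_combined(cov3, seed = 4)
  expect_identical(f3$clinical$ranking[1], "tumor_size")

  expect_error(fit_clinical_and_combined(cov, covariates = c("age", "nope")),
               "absent")
})
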