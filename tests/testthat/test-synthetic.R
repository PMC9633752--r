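small_spec <- function(...) {
  cohort_spec(grid = c(24, 24, 10),
              semi_axes_mm = list(xy = c(7, 9), z = c(5, 7)), ...)
}

test_that("lesion image generation is seed-deterministic", {
  spec <- small_spec()
  a <- generate_lesion_image(spec, 3, 20, TRUE, seed = 5)
  b <- generate_lesion_image(spec, 3, 20, TRUE, seed = 5)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  c_ <- generate_lesion_image(spec, 3, 20, TRUE, seed = 6)
  expect_false(identical(a$volume$data, c_$volume$data))
  expect_error(
    generate_lesion_image(spec, 1, 0, seed = 1, semi_axes = c(50, 50, 50)),
    "larger than")
})

test_that("zero noise and unit multiplier reproduce the baseline image", {
  spec <- small_spec(noise_sd = 0, responder_mult = c(1, 1),
                     nonresponder_mult = c(1, 1))
  base <- generate_lesion_image(spec, 2, 0, FALSE, seed = 8)
  at20 <- generate_lesion_image(spec, 2, 20, FALSE, seed = 8)
  expect_identical(base$volume$data, at20$volume$data)
  f0 <- extract_features(quantize_roi(base$volume, base$mask))
  f1 <- extract_features(quantize_roi(at20$volume, at20$mask))
  expect_equal(delta_features(f0, f1), setNames(rep(0, 39), feature_registry()))
})

test_that("responders' homogeneity features rise at BED 20", {
  spec <- small_spec()
  deltas <- sapply(1:5, function(p) {
    b <- generate_lesion_image(spec, p, 0, FALSE, seed = 13)
    a <- generate_lesion_image(spec, p, 20, FALSE, seed = 13)
    fb <- extract_features(quantize_roi(b$volume, b$mask))
    fa <- extract_features(quantize_roi(a$volume, a$mask))
    (fa - fb)[c("glcm_energy", "glszm_large_zone_emphasis")]
  })
  expect_true(all(deltas["glcm_energy", ] > 0))
  expect_true(all(deltas["glszm_large_zone_emphasis", ] > 0))
})

test_that("feature tables plant effects only where requested", {
  tab <- generate_feature_table(n = 22, class_counts = c(15, 7),
                                planted_features = c("glcm_energy",
                                                     "glszm_large_zone_emphasis"),
                                effect_size = 3, seed = 1)
  expect_identical(dim(tab$X), c(22L, 39L))
  expect_identical(colnames(tab$X), feature_registry())
  expect_identical(sum(tab$y), 7L)
  # planted opposition: responders up, poor responders down
  expect_gt(mean(tab$X[!tab$y, "glcm_energy"]),
            mean(tab$X[tab$y, "glcm_energy"]))

  expect_error(generate_feature_table(planted_features = "not_a_feature"),
               "unknown feature")
  t0 <- generate_feature_table(effect_size = 0, seed = 2)
  expect_identical(t0$X, generate_feature_table(effect_size = 0, seed = 2)$X)

  # planted 2-feature signal lands in the Gini top-2 almost always
  hits <- 0
  for (s in 1:50) {
    tt <- generate_feature_table(planted_features = c("glcm_energy",
                                                      "glszm_large_zone_emphasis"),
                                 effect_size = 3, seed = s)
    g <- rank_features_gini(tt$X, tt$y, seed = s)
    hits <- hits + setequal(g$top2, c("glcm_energy",
                                      "glszm_large_zone_emphasis"))
  }
  expect_gte(hits, 45)
})

test_that("clinical covariates look like the packaged cohort", {
  cov <- generate_clinical_covariates(40, seed = 6)
  expect_identical(nrow(cov), 40L)
  expect_true(all(cov$age >= 49 & cov$age <= 94))
  expect_true(all(cov$tumor_size >= 1.3 & cov$tumor_size <= 8))
  expect_equal(cov$total_bed, compute_bed(cov$rx_dose, cov$n_fractions))
  expect_identical(nrow(generate_clinical_covariates(0)), 0L)

  # every schedule in the menu reaches BED 20 before its last image
  menu <- default_schedule_menu()
  reach <- sapply(seq_len(nrow(menu)), function(i)
    align_checkpoint(treatment_course("x", menu$rx_dose[i],
                                      menu$n_fractions[i]), 20)$reachable)
  expect_true(all(reach))
})

test_that("generated cohorts are reproducible and well formed", {
  spec <- small_spec(n_patients = 6, n_poor_responders = 2)
  co <- generate_cohort(spec, seed = 3)
  expect_length(co$courses, 6)
  expect_identical(sum(co$cohort$poor_response), 2L)
  for (course in co$courses)
    expect_length(course$images, course$n_fractions)
  co2 <- generate_cohort(spec, seed = 3)
  expect_identical(co$courses[[1]]$images[[1]]$volume$data,
                   co2$courses[[1]]$images[[1]]$volume$data)
  expect_identical(co$cohort, co2$cohort)

  # written cohorts carry provenance and round-trip
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "provenance.txt")))
  v <- load_volume(file.path(dir, "pt1_fx01_img.nii.gz"))
  expect_equal(v$data, co$courses[[1]]$images[[1]]$volume$data,
               tolerance = 1e-6, ignore_attr = TRUE)
})
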