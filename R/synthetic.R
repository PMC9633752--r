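# Synthetic longitudinal cohorts. The texture knob is the correlation length
# of a Gaussian random field: smoothing white noise with a wider kernel makes
# larger uniform regions after quantization, which raises GLCM energy and
# GLSZM large zone emphasis together. Response classes differ only in how
# that correlation length evolves with delivered BED — an engineered
# surrogate for treatment-induced texture change, not a biological claim.

#' Specification of a synthetic longitudinal cohort
#'
#' Defaults mirror the shape of the 22-patient MR-guided liver SBRT cohort:
#' 22 patients with a 15/7 responder/poor-responder split, fractionation
#' schedules drawn from the packaged treatment menu, anisotropic
#' 1.5 x 1.5 x 3.0 mm voxels, and feature trajectories in which responders'
#' texture homogeneity rises from baseline to BED 20 Gy then falls toward
#' BED 40 Gy while poor responders show the opposite course.
#'
#' @param n_patients Cohort size (default 22).
#' @param n_poor_responders Patients with local failure (default 7).
#' @param grid Image grid dimensions (default `c(48, 48, 16)`).
#' @param spacing Voxel spacing in mm (default `c(1.5, 1.5, 3.0)`).
#' @param semi_axes_mm Ranges for the ellipsoidal lesion semi-axes, a list
#'   with `xy = c(min, max)` in-plane and `z = c(min, max)` through-plane
#'   (mm). Defaults keep every lesion above ~200 voxels so zone statistics
#'   are non-degenerate.
#' @param schedule_menu Data.frame of `(rx_dose, n_fractions)` rows sampled
#'   per patient; defaults to the packaged cohort's schedules.
#' @param ell0_mm Baseline correlation length of the texture field (mm).
#' @param responder_mult,nonresponder_mult Length-2 multipliers `(m20, m40)`
#'   applied to `ell0_mm` at delivered BED 20 and 40 Gy; values at other BEDs
#'   are piecewise-linear in BED and constant past 40 Gy.
#' @param noise_sd White-noise standard deviation added on top of the
#'   smoothed field, as a fraction of the field's ROI standard deviation.
#' @param alpha_beta Alpha/beta ratio used for scheduling (Gy).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 22, n_poor_responders = 7,
                        grid = c(48, 48, 16), spacing = c(1.5, 1.5, 3.0),
                        semi_axes_mm = list(xy = c(8, 18), z = c(6, 12)),
                        schedule_menu = default_schedule_menu(),
                        ell0_mm = 3,
                        responder_mult = c(1.8, 1.2),
                        nonresponder_mult = c(1 / 1.8, 1 / 1.2),
                        noise_sd = 0.2, alpha_beta = 10) {
  stopifnot(n_poor_responders > 0, n_poor_responders < n_patients,
            ell0_mm > 0, all(responder_mult > 0),
            all(nonresponder_mult > 0), noise_sd >= 0)
  structure(list(n_patients = n_patients,
                 n_poor_responders = n_poor_responders,
                 grid = as.integer(grid), spacing = as.numeric(spacing),
                 semi_axes_mm = semi_axes_mm,
                 schedule_menu = schedule_menu, ell0_mm = ell0_mm,
                 responder_mult = responder_mult,
                 nonresponder_mult = nonresponder_mult,
                 noise_sd = noise_sd, alpha_beta = alpha_beta),
            class = "cohort_spec")
}

#' Fractionation menu of the packaged cohort
#'
#' The distinct `(rx_dose, n_fractions)` schedules occurring in the packaged
#' 22-patient table. Every schedule reaches a cumulative BED of 20 Gy before
#' its last setup image; 30 Gy in 5 never reaches 40 Gy (maximum 38.4 Gy
#' before the final image), exercising the exclusion path.
#'
#' @return Data.frame with columns `rx_dose`, `n_fractions`.
#' @export
default_schedule_menu <- function() {
  data.frame(rx_dose = c(50, 45, 40, 30, 60, 54, 30),
             n_fractions = c(5L, 5L, 4L, 5L, 5L, 3L, 3L))
}

# Correlation-length multiplier at delivered BED b: piecewise linear through
# (0, 1), (20, m[1]), (40, m[2]), constant beyond.
.trajectory_mult <- function(bed, mult) {
  stats::approx(x = c(0, 20, 40), y = c(1, mult[1], mult[2]),
                xout = pmin(bed, 40), rule = 2)$y
}

# Separable Gaussian smoothing with edge renormalization.
.smooth3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-8) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (off in seq(-r, r)) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[off + r + 1]
    }
    K <- K / rowSums(K)
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- array(K %*% matrix(a, da[1], da[2] * da[3]), da)
    arr <- aperm(a, order(perm))
  }
  arr
}

.ellipsoid_mask <- function(grid, spacing, semi_axes) {
  ctr <- (grid + 1) / 2
  x <- ((seq_len(grid[1]) - ctr[1]) * spacing[1] / semi_axes[1])^2
  y <- ((seq_len(grid[2]) - ctr[2]) * spacing[2] / semi_axes[2])^2
  z <- ((seq_len(grid[3]) - ctr[3]) * spacing[3] / semi_axes[3])^2
  outer(outer(x, y, `+`), z, `+`) <= 1
}

# Deterministic per-(seed, patient, timepoint) sub-seed below 2^31.
.sub_seed <- function(seed, patient, timepoint = 0) {
  as.integer((as.numeric(seed) * 7919 + patient * 6211 +
                round(timepoint * 100) * 13) %% 2147483629)
}

#' Generate one synthetic lesion image at a treatment timepoint
#'
#' The lesion is an ellipsoid filled with a smoothed Gaussian random field.
#' Each patient owns one fixed white-noise base field (so images at
#' different timepoints are longitudinally linked); the delivered BED only
#' changes the smoothing length via the class trajectory, plus fresh
#' timepoint-specific acquisition noise. With `noise_sd = 0` and a
#' multiplier of 1 the baseline and checkpoint images are bit-identical.
#'
#' @param spec A [cohort_spec()].
#' @param patient Integer patient index (drives the per-patient base field).
#' @param bed_delivered Cumulative BED (Gy) delivered before this image.
#' @param poor_response Logical: use the non-responder trajectory?
#' @param seed Integer cohort seed.
#' @param semi_axes Optional length-3 lesion semi-axes in mm; defaults to
#'   mid-range.
#' @return List with elements `volume` ([image_volume()]) and `mask`
#'   ([roi_mask()]).
#' @export
generate_lesion_image <- function(spec, patient, bed_delivered,
                                  poor_response = FALSE, seed = 1,
                                  semi_axes = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(semi_axes))
    semi_axes <- c(mean(spec$semi_axes_mm$xy), mean(spec$semi_axes_mm$xy),
                   mean(spec$semi_axes_mm$z))
  if (any(2 * semi_axes > spec$grid * spec$spacing))
    stop("lesion larger than the image grid", call. = FALSE)
  mult <- .trajectory_mult(bed_delivered,
                           if (poor_response) spec$nonresponder_mult
                           else spec$responder_mult)
  ell <- spec$ell0_mm * mult
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.sub_seed(seed, patient))
  base <- array(stats::rnorm(prod(spec$grid)), spec$grid)
  field <- .smooth3d(base, ell / spec$spacing)
  mask <- .ellipsoid_mask(spec$grid, spec$spacing, semi_axes)
  roi_sd <- stats::sd(field[mask])
  if (roi_sd > 0) field <- field / roi_sd
  if (spec$noise_sd > 0) {
    set.seed(.sub_seed(seed, patient, bed_delivered + 1))
    field <- field + array(stats::rnorm(prod(spec$grid), sd = spec$noise_sd),
                           spec$grid)
  }
  vol <- image_volume(500 + 100 * field, spec$spacing)
  list(volume = vol, mask = roi_mask(mask, spec$spacing))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a full longitudinal synthetic cohort
#'
#' Draws per-patient response labels, fractionation schedules, lesion sizes
#' and clinical covariates, then realizes the setup image acquired before
#' every fraction. Output feeds directly into [build_delta_table()].
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @param informative_covariates Should clinical covariates carry signal
#'   about the label (default `FALSE`)?
#' @return A list of class `synthetic_cohort`: `courses` (list of
#'   [treatment_course()] with images), `cohort` (clinical covariate
#'   data.frame including `poor_response`), `spec`, `seed`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1,
                            informative_covariates = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.sub_seed(seed, 0))
  n <- spec$n_patients
  labels <- sample(rep(c(TRUE, FALSE),
                       c(spec$n_poor_responders, n - spec$n_poor_responders)))
  sched_idx <- sample.int(nrow(spec$schedule_menu), n, replace = TRUE)
  ax_xy <- stats::runif(n, spec$semi_axes_mm$xy[1], spec$semi_axes_mm$xy[2])
  ax_xy2 <- stats::runif(n, spec$semi_axes_mm$xy[1], spec$semi_axes_mm$xy[2])
  ax_z <- stats::runif(n, spec$semi_axes_mm$z[1], spec$semi_axes_mm$z[2])
  cohort <- generate_clinical_covariates(n, seed = .sub_seed(seed, 1),
                                         informative = informative_covariates,
                                         labels = labels,
                                         schedule_menu = spec$schedule_menu,
                                         schedule_idx = sched_idx,
                                         alpha_beta = spec$alpha_beta)
  cohort$poor_response <- labels
  courses <- vector("list", n)
  for (i in seq_len(n)) {
    rx <- cohort$rx_dose[i]; nf <- cohort$n_fractions[i]
    course <- treatment_course(cohort$patient_id[i], rx, nf,
                               alpha_beta = spec$alpha_beta)
    axes <- c(ax_xy[i], ax_xy2[i], ax_z[i])
    imgs <- vector("list", nf)
    for (k in seq_len(nf)) {
      bed_k <- (k - 1) * course$bed_per_fx
      imgs[[k]] <- generate_lesion_image(spec, i, bed_k, labels[i],
                                         seed = seed, semi_axes = axes)
    }
    course$images <- imgs
    courses[[i]] <- course
  }
  structure(list(courses = courses, cohort = cohort, spec = spec,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients (%d poor responders), seed %d\n",
              length(x$courses), sum(x$cohort$poor_response), x$seed))
  invisible(x)
}

#' Generate a delta-feature table with planted class effects
#'
#' A table-level surrogate that bypasses image synthesis: 39 columns of
#' standard-normal noise with the planted columns shifted by
#' `+effect_size` for responders and `-effect_size` for poor responders
#' (responders' homogeneity features rise to BED 20 Gy, poor responders'
#' fall — so the planted class separation is `2 * effect_size` standard
#' deviations).
#'
#' @param n Number of patients.
#' @param class_counts Length-2 vector `(n_responders, n_poor)`; must sum to
#'   `n`.
#' @param planted_features Character vector of feature names from
#'   [feature_registry()] to carry signal (may be empty).
#' @param effect_size Per-class shift in SD units (>= 0).
#' @param seed Integer seed.
#' @return List: `X` (n x 39 matrix, canonical column order), `y` (logical,
#'   `TRUE` = poor response).
#' @export
generate_feature_table <- function(n = 22, class_counts = c(15, 7),
                                   planted_features = character(),
                                   effect_size = 0, seed = 1) {
  stopifnot(sum(class_counts) == n, effect_size >= 0)
  reg <- feature_registry()
  unknown <- setdiff(planted_features, reg)
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  y <- sample(rep(c(FALSE, TRUE), class_counts))
  X <- matrix(stats::rnorm(n * 39), n, 39, dimnames = list(NULL, reg))
  for (f in planted_features)
    X[, f] <- X[, f] + ifelse(y, -effect_size, effect_size)
  list(X = X, y = y)
}

#' Generate a clinical covariate table
#'
#' Covariate distributions follow the packaged cohort: ages 49-94,
#' schedules from the packaged fractionation menu (with derived total BED
#' and BED per fraction), tumour sizes 1.3-8 cm, plus sex, ethnicity,
#' Karnofsky performance status and cirrhosis. With `informative = FALSE`
#' (default) every covariate is independent of the response label; with
#' `informative = TRUE` poor responders receive systematically larger
#' tumours.
#'
#' @param n Number of patients (0 gives an empty table).
#' @param seed Integer seed.
#' @param informative Couple `tumor_size` to `labels`?
#' @param labels Logical response labels, required when `informative = TRUE`.
#' @param schedule_menu,schedule_idx Optional externally fixed schedules.
#' @param alpha_beta Alpha/beta for the derived BED columns.
#' @return Data.frame with columns `patient_id`, `age`, `rx_dose`,
#'   `n_fractions`, `total_bed`, `bed_per_fx`, `tumor_size`, `sex`,
#'   `ethnicity`, `kps`, `cirrhosis`.
#' @export
generate_clinical_covariates <- function(n, seed = 1, informative = FALSE,
                                         labels = NULL,
                                         schedule_menu = default_schedule_menu(),
                                         schedule_idx = NULL,
                                         alpha_beta = 10) {
  cols <- c("patient_id", "age", "rx_dose", "n_fractions", "total_bed",
            "bed_per_fx", "tumor_size", "sex", "ethnicity", "kps",
            "cirrhosis")
  if (n == 0)
    return(stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))),
                           cols))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (is.null(schedule_idx))
    schedule_idx <- sample.int(nrow(schedule_menu), n, replace = TRUE)
  rx <- schedule_menu$rx_dose[schedule_idx]
  nf <- schedule_menu$n_fractions[schedule_idx]
  size <- round(stats::runif(n, 1.3, 8), 1)
  if (informative) {
    if (is.null(labels)) stop("informative covariates need labels",
                              call. = FALSE)
    size <- size + ifelse(labels, 2, 0)
  }
  data.frame(
    patient_id = as.character(seq_len(n)),
    age = round(stats::runif(n, 49, 94)),
    rx_dose = rx, n_fractions = nf,
    total_bed = compute_bed(rx, nf, alpha_beta),
    bed_per_fx = compute_bed(rx, nf, alpha_beta) / nf,
    tumor_size = size,
    sex = sample(c("M", "F"), n, replace = TRUE),
    ethnicity = sample(c("Hispanic", "NonHispanic"), n, replace = TRUE),
    kps = sample(c(70, 80, 90, 100), n, replace = TRUE),
    cirrhosis = sample(c(TRUE, FALSE), n, replace = TRUE))
}

#' Write a synthetic cohort to disk
#'
#' Emits NIfTI volumes/masks per (patient, fraction), the clinical covariate
#' CSV, and a provenance JSON-free text file recording spec and seed, so a
#' written cohort is fully reproducible.
#'
#' @param x A [generate_cohort()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (course in x$courses) {
    for (k in seq_along(course$images)) {
      base <- sprintf("pt%s_fx%02d", course$patient_id, k)
      write_volume(course$images[[k]]$volume,
                   file.path(dir, paste0(base, "_img.nii.gz")))
      write_volume(course$images[[k]]$mask,
                   file.path(dir, paste0(base, "_mask.nii.gz")))
    }
  }
  utils::write.csv(x$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  prov <- c(sprintf("seed: %d", x$seed),
            sprintf("n_patients: %d", x$spec$n_patients),
            sprintf("n_poor_responders: %d", x$spec$n_poor_responders),
            sprintf("grid: %s", paste(x$spec$grid, collapse = "x")),
            sprintf("spacing_mm: %s", paste(x$spec$spacing, collapse = "x")),
            sprintf("ell0_mm: %g", x$spec$ell0_mm),
            sprintf("responder_mult: %s",
                    paste(x$spec$responder_mult, collapse = ",")),
            sprintf("nonresponder_mult: %s",
                    paste(x$spec$nonresponder_mult, collapse = ",")),
            sprintf("noise_sd: %g", x$spec$noise_sd))
  writeLines(prov, file.path(dir, "provenance.txt"))
  invisible(dir)
}
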