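#' Biologically effective dose (linear-quadratic model)
#'
#' `BED = n * d * (1 + d / (alpha/beta))` with `d = total_dose / n_fractions`.
#' The default `alpha_beta = 10` Gy is the conventional tumour value for
#' early-responding tissue. As `alpha_beta -> Inf` the BED tends to the
#' physical dose.
#'
#' @param total_dose Total prescription dose in Gy (>= 0).
#' @param n_fractions Number of fractions (integer >= 1).
#' @param alpha_beta Alpha/beta ratio in Gy (> 0, default 10).
#' @return BED in Gy. Vectorized over `total_dose`/`n_fractions`.
#' @export
compute_bed <- function(total_dose, n_fractions, alpha_beta = 10) {
  if (any(n_fractions < 1)) stop("n_fractions must be >= 1", call. = FALSE)
  if (any(alpha_beta <= 0)) stop("alpha_beta must be > 0", call. = FALSE)
  if (any(total_dose < 0)) stop("total_dose must be >= 0", call. = FALSE)
  d <- total_dose / n_fractions
  n_fractions * d * (1 + d / alpha_beta)
}

#' Define a treatment course with its longitudinal setup images
#'
#' Fractions are assumed delivered in prescription order with equal dose per
#' fraction. Image `k` is the setup scan acquired *before* delivering
#' fraction `k`, so the cumulative BED already delivered when image `k` is
#' taken is `(k - 1) * d * (1 + d / alpha_beta)`.
#'
#' @param patient_id Identifier.
#' @param rx_dose Total prescription dose in Gy.
#' @param n_fractions Number of fractions.
#' @param images Optional ordered list of per-fraction entries, each a list
#'   with elements `volume` ([image_volume()]) and `mask` ([roi_mask()]);
#'   element `k` is the pre-fraction-`k` image. May be shorter than
#'   `n_fractions` if later scans are missing.
#' @param alpha_beta Alpha/beta ratio in Gy (default 10).
#' @return An object of class `treatment_course`.
#' @export
treatment_course <- function(patient_id, rx_dose, n_fractions, images = NULL,
                             alpha_beta = 10) {
  stopifnot(rx_dose > 0, n_fractions >= 1, alpha_beta > 0)
  n_fractions <- as.integer(n_fractions)
  d <- rx_dose / n_fractions
  bed_per_fx <- d * (1 + d / alpha_beta)
  if (is.null(images)) images <- vector("list", 0L)
  structure(list(patient_id = as.character(patient_id), rx_dose = rx_dose,
                 n_fractions = n_fractions, alpha_beta = alpha_beta,
                 dose_per_fraction = d, bed_per_fx = bed_per_fx,
                 images = images),
            class = "treatment_course")
}

#' @export
print.treatment_course <- function(x, ...) {
  cat(sprintf("<treatment_course> patient %s: %g Gy / %d fx (BED/fx %.3g Gy), %d image(s)\n",
              x$patient_id, x$rx_dose, x$n_fractions, x$bed_per_fx,
              length(x$images)))
  invisible(x)
}

#' Align a BED checkpoint to a setup image
#'
#' Finds the first setup image acquired at-or-after the target cumulative BED
#' (ceiling rule): the smallest `k` with `(k - 1) * BED_per_fx >= target`.
#' With BED/fx = 20 Gy (50 Gy in 5), the 20 Gy checkpoint falls on the
#' fraction-2 setup image — one fraction delivered. If no image within the
#' course reaches the target, the checkpoint is flagged unreachable rather
#' than raising an error: exclusion is a reported cohort state, not a
#' failure.
#'
#' @param course A [treatment_course()].
#' @param target_bed Target cumulative BED in Gy (20 or 40 in the standard
#'   analysis).
#' @param n_images Number of setup images available; defaults to
#'   `length(course$images)` if images are attached, otherwise
#'   `course$n_fractions`.
#' @return A list of class `bed_checkpoint`: `target_bed`, `reachable`,
#'   `image_index` (NA if unreachable), `realized_bed` (the cumulative BED
#'   actually delivered before that image, recorded so the ceiling
#'   approximation stays auditable).
#' @export
align_checkpoint <- function(course, target_bed, n_images = NULL) {
  stopifnot(inherits(course, "treatment_course"), target_bed > 0)
  if (is.null(n_images))
    n_images <- if (length(course$images)) length(course$images)
                else course$n_fractions
  k <- ceiling(target_bed / course$bed_per_fx) + 1
  reachable <- k <= n_images
  structure(list(target_bed = target_bed,
                 reachable = reachable,
                 image_index = if (reachable) as.integer(k) else NA_integer_,
                 realized_bed = if (reachable) (k - 1) * course$bed_per_fx
                                else NA_real_),
            class = "bed_checkpoint")
}

#' Delta between two texture feature vectors
#'
#' Sign convention: `delta = checkpoint - baseline`, so a feature that rises
#' under treatment has a positive delta. Downstream rankings and AUCs are
#' invariant to a global sign flip.
#'
#' @param baseline,at_checkpoint Named feature vectors of length 39 in
#'   [feature_registry()] order.
#' @return Named delta vector of length 39.
#' @export
delta_features <- function(baseline, at_checkpoint) {
  if (length(baseline) != 39L || length(at_checkpoint) != 39L)
    stop("feature vectors must have length 39", call. = FALSE)
  if (!identical(names(baseline), names(at_checkpoint)))
    stop("feature vectors must share the same feature order", call. = FALSE)
  at_checkpoint - baseline
}

#' Build delta-feature tables at BED checkpoints
#'
#' Runs the full image pipeline for a cohort of treatment courses: quantizes
#' the baseline (pre-fraction-1) ROI and each checkpoint ROI, extracts the 39
#' features, and tabulates `checkpoint - baseline` deltas. One feature
#' library is produced per target BED; a patient whose course never reaches a
#' checkpoint is excluded from that library only and listed in the exclusion
#' report.
#'
#' @param courses List of [treatment_course()] objects, each with attached
#'   images; every course must include the baseline (fraction-1) image.
#' @param target_beds Numeric vector of checkpoint BEDs (default `c(20, 40)`).
#' @param ng,config Quantization and texture settings, passed to
#'   [quantize_roi()] / [extract_features()].
#' @return A list of class `delta_feature_tables`:
#'   \describe{
#'     \item{tables}{named list (one per checkpoint, e.g. `"BED20"`) of
#'       data.frames with `patient_id`, `checkpoint`, `image_index`,
#'       `realized_bed` and the 39 delta columns}
#'     \item{exclusions}{data.frame of (patient_id, checkpoint) pairs whose
#'       target BED was unreachable}
#'     \item{baseline}{matrix of baseline feature vectors (patients x 39)}
#'   }
#' @export
build_delta_table <- function(courses, target_beds = c(20, 40), ng = 64,
                              config = texture_config()) {
  feat_names <- feature_registry()
  cp_names <- paste0("BED", target_beds)
  empty_tab <- function() {
    df <- cbind(data.frame(patient_id = character(), checkpoint = character(),
                           image_index = integer(), realized_bed = numeric()),
                as.data.frame(matrix(numeric(), 0, 39,
                                     dimnames = list(NULL, feat_names))))
    df
  }
  tabs <- stats::setNames(lapply(cp_names, function(x) empty_tab()), cp_names)
  excl <- data.frame(patient_id = character(), checkpoint = character(),
                     max_bed_before_last_image = numeric())
  base_mat <- matrix(numeric(), 0, 39, dimnames = list(NULL, feat_names))
  for (course in courses) {
    stopifnot(inherits(course, "treatment_course"))
    if (length(course$images) < 1L)
      stop("patient ", course$patient_id, " has no baseline image",
           call. = FALSE)
    feat_cache <- list()
    feats_at <- function(k) {
      key <- as.character(k)
      if (is.null(feat_cache[[key]])) {
        im <- course$images[[k]]
        q <- quantize_roi(im$volume, im$mask, ng = ng)
        feat_cache[[key]] <<- extract_features(q, config = config)
      }
      feat_cache[[key]]
    }
    baseline <- feats_at(1L)
    base_mat <- rbind(base_mat, matrix(baseline, 1,
                                       dimnames = list(course$patient_id,
                                                       feat_names)))
    for (j in seq_along(target_beds)) {
      cp <- align_checkpoint(course, target_beds[j])
      if (!cp$reachable) {
        excl <- rbind(excl, data.frame(
          patient_id = course$patient_id, checkpoint = cp_names[j],
          max_bed_before_last_image =
            (length(course$images) - 1) * course$bed_per_fx))
        next
      }
      if (cp$image_index > length(course$images))
        stop("patient ", course$patient_id, " is missing setup image ",
             cp$image_index, call. = FALSE)
      delta <- delta_features(baseline, feats_at(cp$image_index))
      row <- cbind(data.frame(patient_id = course$patient_id,
                              checkpoint = cp_names[j],
                              image_index = cp$image_index,
                              realized_bed = cp$realized_bed),
                   as.data.frame(matrix(delta, 1,
                                        dimnames = list(NULL, feat_names))))
      tabs[[cp_names[j]]] <- rbind(tabs[[cp_names[j]]], row)
    }
  }
  structure(list(tables = tabs, exclusions = excl, baseline = base_mat),
            class = "delta_feature_tables")
}

#' @export
print.delta_feature_tables <- function(x, ...) {
  cat("<delta_feature_tables>\n")
  for (nm in names(x$tables))
    cat(sprintf("  %s: %d patient(s)\n", nm, nrow(x$tables[[nm]])))
  if (nrow(x$exclusions))
    cat(sprintf("  exclusions: %d (unreachable checkpoints)\n",
                nrow(x$exclusions)))
  invisible(x)
}

#' Write delta tables and exclusion report to CSV
#'
#' @param x A [build_delta_table()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_delta_tables <- function(x, dir) {
  stopifnot(inherits(x, "delta_feature_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(x$tables)) {
    p <- file.path(dir, paste0("delta_", tolower(nm), ".csv"))
    utils::write.csv(x$tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "exclusions.csv")
  utils::write.csv(x$exclusions, p, row.names = FALSE)
  invisible(c(paths, p))
}
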