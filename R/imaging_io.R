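#' Construct an image volume
#'
#' A minimal container for a 3D scalar image: the voxel array plus the voxel
#' spacing in millimetres. All intensities must be finite; spacing components
#' must be positive. Index order is (x, y, z) and no resampling is ever
#' performed, so a volume and its mask must live on identical grids.
#'
#' @param data 3D numeric array of intensities (arbitrary MR units).
#' @param spacing Numeric length-3 vector `(dx, dy, dz)` in mm.
#' @return An object of class `image_volume` with elements `data` and
#'   `spacing`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  if (any(!is.finite(data)))
    stop("volume contains non-finite intensities", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels @ %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' @param data 3D logical (or 0/1 numeric) array; `TRUE` marks lesion voxels.
#' @param spacing Voxel spacing in mm, as for [image_volume()].
#' @return An object of class `roi_mask` with elements `data` (logical array)
#'   and `spacing`.
#' @export
roi_mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask contains missing values", call. = FALSE)
  if (!any(data)) stop("mask is empty (no voxels selected)", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<roi_mask> %d x %d x %d grid, %d voxels selected\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 image (`.nii` / `.nii.gz`) and returns an
#' [image_volume()] carrying the voxel spacing from the header. Loading fails
#' if the file holds anything but a 3D grid of finite scalars: non-finite
#' voxels almost always indicate a corrupted export and would silently poison
#' every downstream texture matrix.
#'
#' @param path Path to a NIfTI file.
#' @return An `image_volume`.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), " dimensions",
         call. = FALSE)
  if (any(!is.finite(arr)))
    stop("volume contains non-finite voxel values: ", path, call. = FALSE)
  image_volume(arr, RNifti::pixdim(img)[1:3])
}

#' Write a volume or mask to NIfTI
#'
#' @param x An `image_volume` or `roi_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "image_volume") || inherits(x, "roi_mask"))
  arr <- x$data
  if (is.logical(arr)) storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a lesion mask aligned to a reference volume
#'
#' @param path Path to a NIfTI mask (nonzero = inside ROI).
#' @param reference The `image_volume` the mask annotates; grids must match
#'   exactly (no resampling is attempted).
#' @return An `roi_mask`.
#' @export
load_mask <- function(path, reference) {
  stopifnot(inherits(reference, "image_volume"))
  vol <- load_volume(path)
  if (!identical(dim(vol$data), dim(reference$data)))
    stop("mask grid ", paste(dim(vol$data), collapse = "x"),
         " does not match reference ", paste(dim(reference$data), collapse = "x"),
         call. = FALSE)
  roi_mask(vol$data != 0, reference$spacing)
}

.cohort_required_cols <- c("patient_id", "poor_response", "age", "rx_dose",
                           "n_fractions", "tumor_size", "diagnosis")
.cohort_optional_cols <- c("sex", "ethnicity", "kps", "cirrhosis",
                           "total_bed", "bed_per_fx")

#' Load a treatment/clinical cohort table
#'
#' Reads the per-patient CSV feeding the clinical and combined models:
#' prescription dose, fraction count, binary response label, tumour size and
#' diagnosis, plus any optional covariates present. The response column
#' accepts `Yes`/`No` or logical values; `poor_response = TRUE` means
#' progressive disease of the treated lesion.
#'
#' @param path CSV path with header
#'   `patient_id,poor_response,age,rx_dose,n_fractions,tumor_size,diagnosis`
#'   and optional `sex,ethnicity,kps,cirrhosis,total_bed,bed_per_fx`.
#' @return A `data.frame` of class `cohort_table`, one validated row per
#'   patient; `poor_response` is logical.
#' @seealso [example_cohort_path()] for the packaged 22-patient table.
#' @export
load_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("cohort table is empty: ", path, call. = FALSE)
  missing <- setdiff(.cohort_required_cols, names(df))
  if (length(missing))
    stop("cohort table missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  if (is.character(df$poor_response)) {
    pr <- toupper(trimws(df$poor_response))
    if (!all(pr %in% c("YES", "NO", "TRUE", "FALSE")))
      stop("poor_response must be Yes/No or TRUE/FALSE", call. = FALSE)
    df$poor_response <- pr %in% c("YES", "TRUE")
  } else df$poor_response <- as.logical(df$poor_response)
  for (col in c("age", "rx_dose", "n_fractions", "tumor_size")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stop("non-numeric values in column ", col, call. = FALSE)
    df[[col]] <- v
  }
  if (any(df$rx_dose <= 0)) stop("rx_dose must be > 0", call. = FALSE)
  if (any(df$n_fractions < 1 | df$n_fractions != round(df$n_fractions)))
    stop("n_fractions must be a positive integer", call. = FALSE)
  df$n_fractions <- as.integer(df$n_fractions)
  if (any(df$tumor_size <= 0)) stop("tumor_size must be > 0", call. = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Path to the packaged 22-patient cohort fixture
#'
#' The treatment and clinical characteristics of the 22-patient MR-guided
#' liver SBRT cohort (prescription, fractions, total BED, BED per fraction,
#' response label, tumour size, diagnosis), shipped as plain CSV.
#'
#' @return File path usable with [load_cohort_table()].
#' @export
example_cohort_path <- function() {
  system.file("extdata", "table1_cohort.csv", package = "deltarad",
              mustWork = TRUE)
}
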