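#' Collewet +/- 3 sigma intensity normalization
#'
#' Constrains the dynamic range of ROI intensities by clipping to
#' `mean +/- k_sigma * sd`, computed over the ROI voxels only. MR intensities
#' have no absolute scale; restricting the range before quantization stops a
#' handful of extreme voxels from compressing the gray levels available to the
#' bulk of the lesion.
#'
#' @param values Numeric vector of ROI intensities (all finite, length >= 1).
#' @param k_sigma Clip width in standard deviations (default 3).
#' @param sigma_divisor `"n"` for the population standard deviation (default)
#'   or `"n-1"` for the sample estimator. The two differ only for voxels
#'   sitting within O(sigma/n) of the clip boundary.
#' @return Numeric vector of the same length, clipped into
#'   `[mu - k*sigma, mu + k*sigma]`.
#' @export
collewet_normalize <- function(values, k_sigma = 3,
                               sigma_divisor = c("n", "n-1")) {
  sigma_divisor <- match.arg(sigma_divisor)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("no ROI intensities supplied", call. = FALSE)
  if (any(!is.finite(values)))
    stop("ROI intensities must be finite", call. = FALSE)
  mu <- mean(values)
  n <- length(values)
  s2 <- sum((values - mu)^2) / if (sigma_divisor == "n") n else max(1, n - 1)
  s <- sqrt(s2)
  pmin(pmax(values, mu - k_sigma * s), mu + k_sigma * s)
}

#' Histogram-equalization quantization to Ng gray levels
#'
#' Maps intensities to integer levels `1..ng` through the right-continuous
#' empirical CDF of the ROI values: `level(x) = max(1, ceiling(ng * F(x)))`.
#' Tied intensities always share a level, the mapping is monotone, and for
#' continuous inputs the occupied levels are (near-)equally populated — the
#' flat-histogram property that makes texture matrices comparable across
#' patients with different raw intensity scales.
#'
#' @param values Numeric vector of (normalized) ROI intensities.
#' @param ng Number of gray levels (default 64, minimum 2).
#' @return Integer vector of levels in `1..ng`.
#' @export
quantize_equalize <- function(values, ng = 64) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("no ROI intensities supplied", call. = FALSE)
  if (any(!is.finite(values)))
    stop("ROI intensities must be finite", call. = FALSE)
  if (length(ng) != 1L || !is.finite(ng) || ng < 2)
    stop("`ng` must be an integer >= 2", call. = FALSE)
  ng <- as.integer(ng)
  n <- length(values)
  # degenerate ROI (zero variance): all voxels share level 1 by convention
  if (length(unique(values)) == 1L) return(rep(1L, n))
  # F(x) = #(values <= x)/n without an O(n^2) comparison: rank with ties.method
  # "max" counts, for each x, all values <= x.
  f <- rank(values, ties.method = "max") / n
  lev <- as.integer(pmax(1, ceiling(ng * f)))
  lev
}

#' Quantize the ROI voxels of a volume
#'
#' Applies the fixed preprocessing order — Collewet clipping, then
#' histogram-equalization quantization — to the voxels a mask selects, and
#' packages the result for the texture-matrix builders. Statistics never see
#' voxels outside the ROI, so background cannot influence the lesion's
#' dynamic range.
#'
#' @param volume An [image_volume()].
#' @param mask An [roi_mask()] on the identical grid.
#' @param ng Number of gray levels (default 64).
#' @param k_sigma,sigma_divisor Passed to [collewet_normalize()].
#' @return An object of class `quantized_roi`:
#'   \describe{
#'     \item{levels}{integer vector of gray levels, one per ROI voxel}
#'     \item{array}{3D integer array cropped to the mask bounding box, `NA`
#'       outside the ROI}
#'     \item{ng}{number of gray levels}
#'     \item{voxel_coords}{matrix of (x, y, z) indices on the original grid}
#'     \item{spacing}{voxel spacing in mm}
#'   }
#' @export
quantize_roi <- function(volume, mask, ng = 64, k_sigma = 3,
                         sigma_divisor = "n") {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("mask and volume grids differ", call. = FALSE)
  coords <- which(mask$data, arr.ind = TRUE)
  vals <- volume$data[mask$data]
  norm <- collewet_normalize(vals, k_sigma = k_sigma,
                             sigma_divisor = sigma_divisor)
  lev <- quantize_equalize(norm, ng = ng)
  quantized_roi_from_levels(lev, coords, ng = ng, spacing = volume$spacing)
}

#' Assemble a quantized ROI from levels and voxel coordinates
#'
#' Low-level constructor used by [quantize_roi()] and by the synthetic-data
#' and testing code. Crops to the bounding box of the coordinates.
#'
#' @param levels Integer gray levels in `1..ng`, one per voxel.
#' @param coords Integer matrix with 3 columns of voxel indices (1-based).
#' @param ng Number of gray levels.
#' @param spacing Voxel spacing in mm.
#' @return A `quantized_roi`.
#' @export
quantized_roi_from_levels <- function(levels, coords, ng,
                                      spacing = c(1, 1, 1)) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  levels <- as.integer(levels)
  if (nrow(coords) != length(levels))
    stop("one level per voxel required", call. = FALSE)
  if (length(levels) == 0L) stop("empty ROI", call. = FALSE)
  if (min(levels) < 1L || max(levels) > ng)
    stop("levels must lie in 1..ng", call. = FALSE)
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  arr <- array(NA_integer_, hi - lo + 1L)
  arr[cbind(coords[, 1] - lo[1] + 1L,
            coords[, 2] - lo[2] + 1L,
            coords[, 3] - lo[3] + 1L)] <- levels
  structure(list(levels = levels, array = arr, ng = as.integer(ng),
                 voxel_coords = coords, spacing = as.numeric(spacing)),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %d voxels, Ng = %d (%d levels occupied)\n",
              length(x$levels), x$ng, length(unique(x$levels))))
  invisible(x)
}
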