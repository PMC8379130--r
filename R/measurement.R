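#' Specify an elliptical region of interest
#'
#' An ROI is an axis-aligned ellipse on a 2-D attenuation raster, described in
#' pixel units with 0-based row/column indices and pixel centers at integer
#' coordinates. A pixel belongs to the ROI iff its center lies inside or on
#' the ellipse boundary.
#'
#' @param center_row,center_col Ellipse center in pixel coordinates (0-based).
#' @param semi_axis_a,semi_axis_b Semi-axes along rows and columns, in pixels;
#'   both must be strictly positive.
#' @param phase Acquisition phase the ROI is traced on: `"UE"` (unenhanced),
#'   `"ART"` (arterial), `"PV"` (portal venous) or `"DEL"` (delayed). The
#'   portal venous phase may be carried in data but no index uses it.
#' @param target `"lesion"` or `"liver"`.
#'
#' @return A `roi_spec` list.
#' @examples
#' roi_spec(32, 32, 10, 8, phase = "ART", target = "lesion")
#' @export
roi_spec <- function(center_row, center_col, semi_axis_a, semi_axis_b,
                     phase = c("UE", "ART", "PV", "DEL"),
                     target = c("lesion", "liver")) {
  phase <- match.arg(phase)
  target <- match.arg(target)
  if (!is.finite(semi_axis_a) || !is.finite(semi_axis_b) ||
      semi_axis_a <= 0 || semi_axis_b <= 0) {
    stop("semi_axis_a and semi_axis_b must be strictly positive", call. = FALSE)
  }
  structure(
    list(center_row = center_row, center_col = center_col,
         semi_axis_a = semi_axis_a, semi_axis_b = semi_axis_b,
         phase = phase, target = target),
    class = "roi_spec"
  )
}

#' Mean attenuation inside an elliptical ROI
#'
#' Computes the arithmetic mean of all pixels whose centers fall inside or on
#' the ellipse of an [roi_spec()], mirroring how mean HU is read off a
#' manually traced elliptic ROI on a CT slice.
#'
#' @param image Numeric matrix of attenuation values (HU); rows/columns are
#'   indexed 0-based for ROI geometry.
#' @param roi An [roi_spec()].
#'
#' @return A one-row tibble with `mean_hu`, `n_pixels`, and `area_px`
#'   (identical to `n_pixels`; pixel-unit area of the discrete ROI).
#' @examples
#' img <- matrix(70, 32, 32)
#' roi_mean(img, roi_spec(15, 15, 5, 5))
#' @export
roi_mean <- function(image, roi) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!inherits(roi, "roi_spec")) stop("roi must be an roi_spec", call. = FALSE)
  if (any(!is.finite(image))) stop("image contains non-finite values", call. = FALSE)

  nr <- nrow(image); nc <- ncol(image)
  # candidate rows/cols restricted to the ellipse bounding box within bounds
  r_lo <- max(0, ceiling(roi$center_row - roi$semi_axis_a))
  r_hi <- min(nr - 1, floor(roi$center_row + roi$semi_axis_a))
  c_lo <- max(0, ceiling(roi$center_col - roi$semi_axis_b))
  c_hi <- min(nc - 1, floor(roi$center_col + roi$semi_axis_b))
  outside <- roi$center_row + roi$semi_axis_a < 0 ||
    roi$center_row - roi$semi_axis_a > nr - 1 ||
    roi$center_col + roi$semi_axis_b < 0 ||
    roi$center_col - roi$semi_axis_b > nc - 1
  if (outside) stop("ROI ellipse lies outside the image", call. = FALSE)
  if (r_lo > r_hi || c_lo > c_hi) {
    stop("empty ROI: no pixel centers inside the ellipse", call. = FALSE)
  }
  rows <- seq(r_lo, r_hi)
  cols <- seq(c_lo, c_hi)
  rr <- ((rows - roi$center_row) / roi$semi_axis_a)^2
  cc <- ((cols - roi$center_col) / roi$semi_axis_b)^2
  inside <- outer(rr, cc, `+`) <= 1 + 1e-12
  n <- sum(inside)
  if (n == 0L) stop("empty ROI: no pixel centers inside the ellipse", call. = FALSE)
  vals <- image[cbind(rep(rows + 1L, times = length(cols))[inside],
                      rep(cols + 1L, each = length(rows))[inside])]
  tibble::tibble(mean_hu = mean(vals), n_pixels = n, area_px = n)
}

#' Average the two adjacent-liver ROI means
#'
#' The measurement protocol places exactly two ROIs on healthy liver adjacent
#' to the lesion in each contrast phase; the liver reference attenuation is
#' their average.
#'
#' @param mean1,mean2 Mean HU of the two liver ROIs. Both are required.
#' @return The reference HU, `(mean1 + mean2) / 2`. Vectorized.
#' @examples
#' liver_reference(66.2, 67.8)
#' @export
liver_reference <- function(mean1, mean2) {
  if (missing(mean1) || missing(mean2) ||
      anyNA(mean1) || anyNA(mean2)) {
    stop("protocol requires two liver ROIs", call. = FALSE)
  }
  if (any(!is.finite(mean1)) || any(!is.finite(mean2))) {
    stop("liver ROI means must be finite", call. = FALSE)
  }
  (mean1 + mean2) / 2
}

#' ROI bookkeeping for the measurement protocol
#'
#' Per lesion and reader the protocol traces 3 lesion ROIs (unenhanced,
#' arterial, delayed) and 4 liver ROIs (2 per contrast phase), i.e. 7 in
#' total; no ROI is traced on the portal venous phase.
#'
#' @param n_lesions Number of lesions (>= 0).
#' @param n_readers Number of readers (>= 1).
#' @return A one-row tibble with `lesion_rois`, `liver_rois`,
#'   `total_per_reader` and `grand_total`.
#' @examples
#' count_protocol_rois(129, 2)
#' @export
count_protocol_rois <- function(n_lesions, n_readers = 1L) {
  if (n_lesions < 0 || n_readers < 1) {
    stop("n_lesions must be >= 0 and n_readers >= 1", call. = FALSE)
  }
  lesion <- 3L * as.integer(n_lesions)
  liver <- 4L * as.integer(n_lesions)
  tibble::tibble(
    lesion_rois = lesion,
    liver_rois = liver,
    total_per_reader = lesion + liver,
    grand_total = (lesion + liver) * as.integer(n_readers)
  )
}

#' Extract a full attenuation profile from a phantom series
#'
#' Applies [roi_mean()] to the lesion ellipse on the unenhanced, arterial and
#' delayed rasters, and to the two liver ROIs on the arterial and delayed
#' rasters, returning the five-value profile the enhancement indices need.
#'
#' @param series A `phantom_series` from [generate_phantom_series()].
#' @param lesion_roi,liver_roi_1,liver_roi_2 Optional [roi_spec()] overrides;
#'   defaults are the ground-truth lesion ellipse and the series' stored
#'   liver ROI positions.
#' @return A one-row tibble with columns `hu_lesion_ue`, `hu_lesion_art`,
#'   `hu_lesion_del`, `hu_liver_art`, `hu_liver_del` (liver values are the
#'   average of the two liver ROIs, tagged with `n_liver_rois = 2`).
#' @export
extract_profile <- function(series, lesion_roi = NULL,
                            liver_roi_1 = NULL, liver_roi_2 = NULL) {
  stopifnot(inherits(series, "phantom_series"))
  lesion_roi <- lesion_roi %||% series$truth$lesion_roi
  liver_roi_1 <- liver_roi_1 %||% series$truth$liver_roi_1
  liver_roi_2 <- liver_roi_2 %||% series$truth$liver_roi_2

  m <- function(img, roi) roi_mean(img, roi)$mean_hu
  tibble::tibble(
    hu_lesion_ue = m(series$images$UE, lesion_roi),
    hu_lesion_art = m(series$images$ART, lesion_roi),
    hu_lesion_del = m(series$images$DEL, lesion_roi),
    hu_liver_art = liver_reference(m(series$images$ART, liver_roi_1),
                                   m(series$images$ART, liver_roi_2)),
    hu_liver_del = liver_reference(m(series$images$DEL, liver_roi_1),
                                   m(series$images$DEL, liver_roi_2)),
    n_liver_rois = 2L
  )
}
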