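#' Generate a synthetic three-phase phantom series
#'
#' Builds three co-registered 2-D HU rasters (unenhanced, arterial, delayed)
#' containing a uniform liver background and one elliptical lesion whose
#' phase-wise attenuation is obtained by inverting the requested enhancement
#' indices around a UE anchor (see [reconstruct_profile()]). Optional additive
#' Gaussian noise is applied per phase. With zero noise, [roi_mean()] on the
#' ground-truth ellipse recovers the true HU exactly, so the full
#' measurement-to-index chain reproduces the requested indices.
#'
#' @param cer,llc,wo_rel,dpar Target enhancement indices for the lesion.
#' @param ue_anchor Lesion unenhanced HU (scale anchor), default 50.
#' @param liver_ue Liver background HU in the unenhanced phase, default 55.
#' @param size Image side length in pixels (square raster).
#' @param lesion_center Length-2 vector, 0-based (row, col) of lesion center.
#' @param lesion_axes Length-2 vector, semi-axes in pixels.
#' @param noise_sigma Length-3 vector of per-phase Gaussian noise SDs
#'   (UE, ART, DEL); default all zero.
#' @param seed Optional integer seed for the noise.
#' @return A `phantom_series`: list with `images` (named list of matrices
#'   `UE`, `ART`, `DEL`) and `truth` (true HU per tissue and phase, lesion
#'   geometry, default liver ROI placements, noise, seed).
#' @examples
#' ph <- generate_phantom_series(cer = 109.4, llc = 56.3, wo_rel = 24.3,
#'                               dpar = 123.2)
#' extract_profile(ph)
#' @export
generate_phantom_series <- function(cer, llc, wo_rel, dpar,
                                    ue_anchor = 50, liver_ue = 55,
                                    size = 128L,
                                    lesion_center = c(size / 2, size / 2),
                                    lesion_axes = c(12, 10),
                                    noise_sigma = c(0, 0, 0),
                                    seed = NULL) {
  prof <- reconstruct_profile(cer = cer, llc = llc, wo_rel = wo_rel,
                              dpar = dpar, ue_anchor = ue_anchor)
  if (any(lesion_axes >= size / 2)) {
    stop("lesion ellipse larger than image", call. = FALSE)
  }
  if (any(noise_sigma < 0) || length(noise_sigma) != 3L) {
    stop("noise_sigma must be three non-negative values (UE, ART, DEL)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  r <- matrix(0:(size - 1L), size, size)
  c_ <- t(r)
  inside <- ((r - lesion_center[1]) / lesion_axes[1])^2 +
    ((c_ - lesion_center[2]) / lesion_axes[2])^2 <= 1 + 1e-12

  make_phase <- function(liver_hu, lesion_hu, sigma) {
    img <- matrix(liver_hu, size, size)
    img[inside] <- lesion_hu
    if (sigma > 0) img <- img + matrix(rnorm(size^2, 0, sigma), size, size)
    img
  }
  images <- list(
    UE = make_phase(liver_ue, prof$hu_lesion_ue, noise_sigma[1]),
    ART = make_phase(prof$hu_liver_art, prof$hu_lesion_art, noise_sigma[2]),
    DEL = make_phase(prof$hu_liver_del, prof$hu_lesion_del, noise_sigma[3])
  )

  lesion_roi <- roi_spec(lesion_center[1], lesion_center[2],
                         lesion_axes[1], lesion_axes[2], target = "lesion")
  # two liver ROIs placed left and right of the lesion, clear of the ellipse
  off <- lesion_axes[2] + max(6, round(size / 10))
  liver_axes <- pmin(lesion_axes, size / 10)
  liver_roi_1 <- roi_spec(lesion_center[1], max(lesion_center[2] - off, liver_axes[2] + 1),
                          liver_axes[1], liver_axes[2], target = "liver")
  liver_roi_2 <- roi_spec(lesion_center[1], min(lesion_center[2] + off, size - liver_axes[2] - 2),
                          liver_axes[1], liver_axes[2], target = "liver")

  structure(
    list(
      images = images,
      truth = list(
        hu = prof, liver_ue = liver_ue,
        lesion_roi = lesion_roi, liver_roi_1 = liver_roi_1,
        liver_roi_2 = liver_roi_2,
        noise_sigma = stats::setNames(noise_sigma, c("UE", "ART", "DEL")),
        seed = seed,
        indices = tibble::tibble(cer = cer, llc = llc, wo_rel = wo_rel, dpar = dpar)
      )
    ),
    class = "phantom_series"
  )
}

#' @export
print.phantom_series <- function(x, ...) {
  cat("<phantom_series> ", nrow(x$images$UE), "x", ncol(x$images$UE),
      " px, phases UE/ART/DEL\n", sep = "")
  cat("  lesion HU (UE/ART/DEL): ",
      paste(fmt1(c(x$truth$hu$hu_lesion_ue, x$truth$hu$hu_lesion_art,
                   x$truth$hu$hu_lesion_del)), collapse = " / "), "\n", sep = "")
  cat("  target indices: CER ", fmt1(x$truth$indices$cer),
      ", LLC ", fmt1(x$truth$indices$llc),
      ", WO_rel ", fmt1(x$truth$indices$wo_rel),
      ", DPAR ", fmt1(x$truth$indices$dpar), "\n", sep = "")
  invisible(x)
}

#' Write a phantom series to disk
#'
#' Writes each phase raster as a 16-bit single-channel TIFF (values stored as
#' `HU + offset`, offset declared in the JSON truth sidecar) or as NIfTI, plus
#' a JSON sidecar with the ground truth and provenance.
#'
#' @param series A `phantom_series`.
#' @param path Output path prefix; files `<path>_UE.tif` etc. and
#'   `<path>_truth.json` are created.
#' @param format `"tiff"` (requires the tiff package) or `"nifti"`
#'   (requires RNifti).
#' @param hu_offset Integer added to HU before 16-bit storage (TIFF only).
#' @return Invisibly, the vector of file paths written.
#' @export
write_phantom_series <- function(series, path, format = c("tiff", "nifti"),
                                 hu_offset = 1024L) {
  stopifnot(inherits(series, "phantom_series"))
  format <- match.arg(format)
  files <- character(0)
  for (ph in names(series$images)) {
    img <- series$images[[ph]]
    if (format == "tiff") {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("TIFF output requires the 'tiff' package", call. = FALSE)
      }
      f <- paste0(path, "_", ph, ".tif")
      # 16-bit TIFF stores [0,1]; scale offset HU into that range
      tiff::writeTIFF(pmin(pmax((img + hu_offset) / 65535, 0), 1), f,
                      bits.per.sample = 16L)
    } else {
      if (!requireNamespace("RNifti", quietly = TRUE)) {
        stop("NIfTI output requires the 'RNifti' package", call. = FALSE)
      }
      f <- paste0(path, "_", ph, ".nii")
      RNifti::writeNifti(img, f)
    }
    files <- c(files, f)
  }
  truth_file <- paste0(path, "_truth.json")
  truth <- series$truth
  truth$lesion_roi <- unclass(truth$lesion_roi)
  truth$liver_roi_1 <- unclass(truth$liver_roi_1)
  truth$liver_roi_2 <- unclass(truth$liver_roi_2)
  truth$hu_offset <- if (format == "tiff") hu_offset else 0L
  truth$format <- format
  jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, digits = NA)
  invisible(c(files, truth_file))
}

#' Read a phantom series written by [write_phantom_series()]
#'
#' @param path The path prefix used when writing.
#' @return A `phantom_series` (images restored to HU scale).
#' @export
read_phantom_series <- function(path) {
  truth <- jsonlite::read_json(paste0(path, "_truth.json"), simplifyVector = TRUE)
  fmt <- truth$format
  images <- lapply(stats::setNames(nm = c("UE", "ART", "DEL")), function(ph) {
    if (fmt == "tiff") {
      img <- tiff::readTIFF(paste0(path, "_", ph, ".tif"))
      img * 65535 - truth$hu_offset
    } else {
      img <- RNifti::readNifti(paste0(path, "_", ph, ".nii"))
      matrix(as.numeric(img), nrow = dim(img)[1])
    }
  })
  respec <- function(r) roi_spec(r$center_row, r$center_col, r$semi_axis_a,
                                 r$semi_axis_b, phase = r$phase, target = r$target)
  truth$lesion_roi <- respec(truth$lesion_roi)
  truth$liver_roi_1 <- respec(truth$liver_roi_1)
  truth$liver_roi_2 <- respec(truth$liver_roi_2)
  truth$hu <- tibble::as_tibble(truth$hu)
  structure(list(images = images, truth = truth), class = "phantom_series")
}
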