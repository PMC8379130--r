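#' Enhancement indices from a five-value attenuation profile
#'
#' Computes the five quantitative wash-in/wash-out indices from mean ROI
#' attenuation (HU) of the lesion in the unenhanced (UE), arterial (ART) and
#' delayed (DEL) phases and of adjacent liver in the arterial and delayed
#' phases:
#'
#' * `cer`     = (ART - UE) / UE x 100 (contrast enhancement ratio, wash-in)
#' * `llc`     = (ART - LIVART) / LIVART x 100 (lesion-to-liver contrast)
#' * `wo_abs`  = (ART - DEL) / (ART - UE) x 100 (absolute wash-out)
#' * `wo_rel`  = (ART - DEL) / ART x 100 (relative wash-out)
#' * `dpar`    = LIVDEL / DEL x 100 (delayed percentage attenuation ratio)
#'
#' DPAR > 100 means the lesion is hypoattenuating relative to liver in the
#' delayed phase, i.e. visibly washed out. Each index is defined only when
#' its denominator is strictly positive (HU can legitimately be <= 0); a
#' failed domain rule yields `NA` for that index rather than an error.
#'
#' @param ue,art,del Lesion mean HU per phase. Vectorized.
#' @param liver_art,liver_del Adjacent-liver reference HU per contrast phase
#'   (each the average of two liver ROIs, see [liver_reference()]).
#' @return A tibble with columns `cer`, `llc`, `wo_abs`, `wo_rel`, `dpar`,
#'   one row per input element, full precision (round only for display).
#' @examples
#' enhancement_indices(50, 104.7, 79.26, 66.99, 97.65)
#' @export
enhancement_indices <- function(ue, art, del, liver_art, liver_del) {
  safe_div <- function(num, den) ifelse(is.finite(den) & den > 0, num / den, NA_real_)
  out <- tibble::tibble(
    cer = safe_div(art - ue, ue) * 100,
    llc = safe_div(art - liver_art, liver_art) * 100,
    wo_abs = safe_div(art - del, art - ue) * 100,
    wo_rel = safe_div(art - del, art) * 100,
    dpar = safe_div(liver_del, del) * 100
  )
  all_na <- rowSums(!is.na(out)) == 0L
  if (any(all_na)) {
    warning(sprintf("%d profile(s) have no evaluable index (all denominators fail)",
                    sum(all_na)), call. = FALSE)
  }
  out
}

#' Add enhancement indices to a lesion table
#'
#' Pipe-friendly wrapper around [enhancement_indices()] for the standard
#' lesion table: one row per lesion with columns `hu_lesion_ue`,
#' `hu_lesion_art`, `hu_lesion_del` and either the averaged references
#' `hu_liver_art`/`hu_liver_del` or the raw pairs `hu_liver_art_1`,
#' `hu_liver_art_2`, `hu_liver_del_1`, `hu_liver_del_2` (averaged here per
#' protocol).
#'
#' @param data Lesion table (data frame).
#' @return `data` as a tibble with `cer`, `llc`, `wo_abs`, `wo_rel`, `dpar`
#'   columns appended; non-evaluable indices are `NA`.
#' @export
add_enhancement_indices <- function(data) {
  data <- tibble::as_tibble(data)
  assert_cols(data, c("hu_lesion_ue", "hu_lesion_art", "hu_lesion_del"),
              "lesion table")
  if (!"hu_liver_art" %in% names(data)) {
    assert_cols(data, c("hu_liver_art_1", "hu_liver_art_2",
                        "hu_liver_del_1", "hu_liver_del_2"), "lesion table")
    data <- dplyr::mutate(
      data,
      hu_liver_art = liver_reference(.data$hu_liver_art_1, .data$hu_liver_art_2),
      hu_liver_del = liver_reference(.data$hu_liver_del_1, .data$hu_liver_del_2)
    )
  }
  dplyr::bind_cols(
    data,
    enhancement_indices(data$hu_lesion_ue, data$hu_lesion_art,
                        data$hu_lesion_del, data$hu_liver_art,
                        data$hu_liver_del)
  )
}

#' Absolute wash-out implied by CER and relative wash-out
#'
#' The three indices built on the lesion's own attenuation satisfy the exact
#' identity `wo_abs = wo_rel * (cer + 100) / cer`, useful to cross-check
#' reported index triples.
#'
#' @param cer,wo_rel Index values (percent-style scale). Vectorized.
#' @return Implied `wo_abs`; `NA` where `cer <= 0`.
#' @examples
#' wo_abs_from_identity(109.4, 24.3) # 46.5 at one decimal
#' @export
wo_abs_from_identity <- function(cer, wo_rel) {
  ifelse(is.finite(cer) & cer > 0, wo_rel * (cer + 100) / cer, NA_real_)
}

#' Reconstruct an attenuation profile from index values
#'
#' The index system is scale-invariant, so a profile is recovered from
#' (`cer`, `llc`, `wo_rel`, `dpar`) once one HU value is anchored; the
#' unenhanced lesion attenuation serves as the anchor. If `wo_abs` is also
#' supplied it is checked against the identity implied by `cer` and `wo_rel`
#' and a warning reports the residual when it exceeds `tol`.
#'
#' @param cer,llc,wo_rel,dpar Index values; require `cer > -100`,
#'   `llc > -100`, `dpar > 0`.
#' @param ue_anchor Unenhanced lesion HU to anchor the scale (> 0).
#' @param wo_abs Optional printed `wo_abs` to validate against the identity.
#' @param tol Rounding tolerance for the `wo_abs` consistency check; default
#'   0.15 absorbs one-decimal display rounding of the inputs.
#' @return A one-row tibble with `hu_lesion_ue`, `hu_lesion_art`,
#'   `hu_lesion_del`, `hu_liver_art`, `hu_liver_del`.
#' @examples
#' reconstruct_profile(cer = 109.4, llc = 56.3, wo_rel = 24.3, dpar = 123.2,
#'                     ue_anchor = 50)
#' @export
reconstruct_profile <- function(cer, llc, wo_rel, dpar, ue_anchor = 50,
                                wo_abs = NULL, tol = 0.15) {
  if (ue_anchor <= 0) stop("ue_anchor must be > 0", call. = FALSE)
  if (cer <= -100 || llc <= -100 || dpar <= 0) {
    stop("require cer > -100, llc > -100, dpar > 0", call. = FALSE)
  }
  art <- ue_anchor * (1 + cer / 100)
  liver_art <- art / (1 + llc / 100)
  del <- art * (1 - wo_rel / 100)
  liver_del <- del * dpar / 100
  if (!is.null(wo_abs)) {
    implied <- wo_abs_from_identity(cer, wo_rel)
    if (is.na(implied) || abs(implied - wo_abs) > tol) {
      warning(sprintf(
        "wo_abs inconsistent with (cer, wo_rel): supplied %.2f, implied %.2f (residual %.3f)",
        wo_abs, implied, abs(implied - wo_abs)), call. = FALSE)
    }
  }
  tibble::tibble(
    hu_lesion_ue = ue_anchor, hu_lesion_art = art, hu_lesion_del = del,
    hu_liver_art = liver_art, hu_liver_del = liver_del
  )
}

#' Dichotomize DPAR at a threshold
#'
#' Classifies lesions as `"high"` when `dpar >= threshold` (boundary
#' inclusive) and `"low"` otherwise; `NA` (non-evaluable) propagates.
#'
#' @param dpar DPAR values. Vectorized.
#' @param threshold Cut point; default 120, the value associated with
#'   complete response after DEB-TACE.
#' @return Factor with levels `high`, `low`; `NA` preserved.
#' @examples
#' dichotomize_dpar(c(123.2, 120, 102.9, NA))
#' @export
dichotomize_dpar <- function(dpar, threshold = 120) {
  factor(ifelse(is.na(dpar), NA_character_,
                ifelse(dpar >= threshold, "high", "low")),
         levels = c("high", "low"))
}

#' Dichotomize an mRECIST response category
#'
#' Early radiological response is dichotomized as complete response versus
#' all others: `CR` maps to `"CR+"`; `PR`, `SD`, `PD` map to `"CR-"`.
#'
#' @param response Character/factor of mRECIST categories.
#' @return Factor with levels `CR+`, `CR-`.
#' @examples
#' dichotomize_response(c("CR", "PR", "SD", "PD"))
#' @export
dichotomize_response <- function(response) {
  response <- as.character(response)
  bad <- setdiff(unique(response[!is.na(response)]), c("CR", "PR", "SD", "PD"))
  if (length(bad) > 0L) {
    stop("unknown mRECIST category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(ifelse(response == "CR", "CR+", "CR-"), levels = c("CR+", "CR-"))
}
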