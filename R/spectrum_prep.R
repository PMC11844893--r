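# Spectrum cleanup and descriptive metrics.

#' Spectrum-preparation configuration
#'
#' @param pfmd_trigger_min_rel minimum relative abundance (fraction of the
#'   base peak) required on all four perfluoromethyldecalin masses for
#'   [remove_pfmd()] to fire. Default 0.01 (1%).
#' @param min_rel_abundance default thresholding floor for
#'   [threshold_peaks()], as a fraction of the base peak.
#' @param mw_peak_min_rel minimum relative abundance (fraction of the base
#'   peak) for molecular-mass candidate peaks; default 0.05 (the 5% floor
#'   used for the `[M-15]+` peak and the highest-mass fallback).
#' @param tms_min_rel minimum relative abundance of the 73 Da fragment for
#'   a spectrum to count as trimethylsilyl-derivatized; default 0.10.
#' @return A list of class `prep_config`. The PFMD characteristic masses
#'   (69, 131, 243, 293 Da) are fixed.
#' @export
prep_config <- function(pfmd_trigger_min_rel = 0.01,
                        min_rel_abundance = 0.05,
                        mw_peak_min_rel = 0.05,
                        tms_min_rel = 0.10) {
  stopifnot(pfmd_trigger_min_rel > 0, pfmd_trigger_min_rel < 1,
            min_rel_abundance >= 0, min_rel_abundance < 1,
            mw_peak_min_rel > 0, mw_peak_min_rel < 1,
            tms_min_rel > 0, tms_min_rel < 1)
  structure(list(pfmd_masses = c(69L, 131L, 243L, 293L),
                 pfmd_trigger_min_rel = pfmd_trigger_min_rel,
                 min_rel_abundance = min_rel_abundance,
                 mw_peak_min_rel = mw_peak_min_rel,
                 tms_indicator_mz = 73L,
                 tms_min_rel = tms_min_rel),
            class = "prep_config")
}

#' Normalize a spectrum to a 999 base peak
#'
#' Rescales intensities so the most intense peak equals 999, preserving
#' relative proportions. Idempotent.
#'
#' @param s a [spectrum()].
#' @return The normalized spectrum.
#' @export
normalize_base_peak <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (nrow(s$peaks) == 0L) stop("cannot normalize an empty spectrum")
  s$peaks$intensity <- s$peaks$intensity * (999 / max(s$peaks$intensity))
  s
}

#' Remove perfluoromethyldecalin calibrant peaks
#'
#' Perfluoromethyldecalin (PFMD), a common internal standard, produces
#' characteristic fragments at 69, 131, 243 and 293 Da. When all four are
#' present at or above `pfmd_trigger_min_rel` of the base peak, the four
#' peaks are deleted and the spectrum renormalized; otherwise the spectrum
#' is returned unchanged. Requiring the full pattern avoids deleting
#' genuine CF3+ (69 Da) or other fragments. Idempotent.
#'
#' @param s a normalized [spectrum()].
#' @param cfg a [prep_config()].
#' @return The (possibly) cleaned spectrum.
#' @export
remove_pfmd <- function(s, cfg = prep_config()) {
  stopifnot(inherits(s, "spectrum"))
  rel <- s$peaks$intensity / max(s$peaks$intensity)
  hit <- s$peaks$mz %in% cfg$pfmd_masses & rel >= cfg$pfmd_trigger_min_rel
  if (sum(unique(s$peaks$mz[hit]) %in% cfg$pfmd_masses) < 4L) return(s)
  keep <- !(s$peaks$mz %in% cfg$pfmd_masses)
  if (!any(keep))
    stop("removing PFMD peaks would empty the spectrum")
  out <- spectrum(s$peaks$mz[keep], s$peaks$intensity[keep], id = s$id,
                  ri = s$ri, mw = s$mw, name = s$name)
  normalize_base_peak(out)
}

#' Remove peaks below an abundance floor
#'
#' Deletes peaks whose intensity is below `floor` times the base peak.
#' Useful for spectra with pervasive low-abundance noise, but note that
#' thresholding can discard the weak high-mass ions needed to distinguish
#' isomers and establish the molecular mass (a message warns of this).
#'
#' @param s a [spectrum()].
#' @param floor abundance floor as a fraction of the base peak, in
#'   `[0, 1)`. `0` is the identity.
#' @return The thresholded spectrum.
#' @export
threshold_peaks <- function(s, floor) {
  stopifnot(inherits(s, "spectrum"), floor >= 0, floor < 1)
  if (floor == 0) return(s)
  rel <- s$peaks$intensity / max(s$peaks$intensity)
  keep <- rel >= floor
  if (!any(keep)) stop("thresholding removed every peak")
  message("abundance thresholding can remove low-abundance high-mass ions")
  out <- s
  out$peaks <- s$peaks[keep, , drop = FALSE]
  rownames(out$peaks) <- NULL
  out
}

#' Estimate the nominal molecular mass of an EI spectrum
#'
#' For trimethylsilyl-derivatized spectra (73 Da fragment at or above
#' `tms_min_rel` of the base peak) the estimate looks for a
#' `[M]+`/`[M-15]+` pair: the methyl-loss peak must be above
#' `mw_peak_min_rel` (5%) relative abundance while the molecular ion need
#' only be present; the largest such `M` is returned. Otherwise (or when no
#' pair exists) the estimate falls back to the highest non-isotopic mass
#' with relative abundance above 5%. A peak at `m` is flagged as an isotope
#' when a peak at `m - 1` exists and the `m` peak is below 25% of it.
#' The result is invariant under intensity rescaling.
#'
#' @param s a [spectrum()].
#' @param cfg a [prep_config()].
#' @return `NULL` when no peak clears the 5% floor; otherwise a list with
#'   `mw` (Da) and `method` (`"tms_pair"` or `"highest_mass"`).
#' @export
estimate_molecular_mass <- function(s, cfg = prep_config()) {
  stopifnot(inherits(s, "spectrum"))
  mz <- s$peaks$mz
  rel <- s$peaks$intensity / max(s$peaks$intensity)
  tms_i <- match(cfg$tms_indicator_mz, mz)
  if (!is.na(tms_i) && rel[tms_i] >= cfg$tms_min_rel) {
    loss_ok <- rel >= cfg$mw_peak_min_rel & (mz + 15L) %in% mz
    if (any(loss_ok)) {
      m <- max(mz[loss_ok]) + 15L
      return(list(mw = as.numeric(m), method = "tms_pair"))
    }
  }
  prev <- match(mz - 1L, mz)
  is_isotope <- !is.na(prev) & s$peaks$intensity <
    0.25 * s$peaks$intensity[ifelse(is.na(prev), 1L, prev)]
  cand <- rel >= cfg$mw_peak_min_rel & !is_isotope
  if (!any(cand)) return(NULL)
  list(mw = as.numeric(max(mz[cand])), method = "highest_mass")
}

#' Median relative abundance of a spectrum
#'
#' The median peak intensity expressed as a percent of the base peak (for
#' an even number of peaks, the mean of the two central values). Low values
#' indicate high dynamic range and correlate with spectrum
#' identifiability; spectra dominated by near-detection-limit contaminant
#' peaks have high medians. Used by [triage()].
#'
#' @param s a [spectrum()].
#' @return Median relative abundance in percent of the base peak.
#' @export
median_relative_abundance <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (nrow(s$peaks) == 0L) stop("empty spectrum")
  100 * stats::median(s$peaks$intensity) / max(s$peaks$intensity)
}
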