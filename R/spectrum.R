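#' Construct an EI mass spectrum
#'
#' A spectrum is a unit-resolution (nominal mass) peak list with relative
#' intensities on the usual 0--999 base-peak scale, plus optional metadata:
#' a Kovats retention index, a nominal molecular mass and a name. Peaks are
#' stored sorted by m/z; duplicate m/z values are merged by summing their
#' intensities.
#'
#' @param mz integer m/z values in Da (unit resolution, >= 1).
#' @param intensity positive relative abundances. Use
#'   [normalize_base_peak()] to put them on the 0--999 scale; most scoring
#'   functions expect normalized input.
#' @param id text identifier (e.g. `"UNK_2737"`).
#' @param ri optional Kovats retention index (dimensionless).
#' @param mw optional nominal molecular mass in Da.
#' @param name optional compound name.
#' @return An object of class `spectrum`: a list with elements `id`,
#'   `peaks` (data.frame with columns `mz`, `intensity`), `ri`, `mw`,
#'   `name`.
#' @examples
#' s <- spectrum(c(73, 285, 300), c(999, 80, 30), id = "EX_1", mw = 300)
#' s
#' @export
spectrum <- function(mz, intensity, id = NULL, ri = NULL, mw = NULL,
                     name = NULL) {
  if (length(mz) != length(intensity))
    stop("'mz' and 'intensity' must have the same length")
  if (length(mz) == 0L)
    stop("a spectrum must contain at least one peak")
  mz <- as.integer(round(mz))
  intensity <- as.numeric(intensity)
  if (any(mz < 1L)) stop("all m/z values must be >= 1")
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("all intensities must be finite and > 0")
  if (anyDuplicated(mz)) {
    agg <- rowsum(intensity, mz)
    mz <- as.integer(rownames(agg))
    intensity <- as.numeric(agg[, 1L])
  }
  o <- order(mz)
  structure(
    list(id = id, peaks = data.frame(mz = mz[o], intensity = intensity[o]),
         ri = if (is.null(ri)) NULL else as.numeric(ri),
         mw = if (is.null(mw)) NULL else as.numeric(mw),
         name = name),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum", if (!is.null(x$id)) paste0("'", x$id, "'"), ">",
      nrow(x$peaks), "peaks, base peak m/z",
      x$peaks$mz[which.max(x$peaks$intensity)], "\n")
  if (!is.null(x$mw)) cat("  MW:", x$mw, "Da\n")
  if (!is.null(x$ri)) cat("  RI:", x$ri, "\n")
  invisible(x)
}

#' Construct a reference-library entry
#'
#' Wraps a [spectrum()] with the compound metadata used by the confidence
#' corrections: the Compound Ubiquity Index (CUI, the number out of 58
#' diverse chemical collections that cite the compound), derivatization
#' flags used by hit filtering, and the provenance of the retention index
#' (measured, or machine-estimated for compounds without measured values).
#'
#' @param spectrum a [spectrum()].
#' @param compound_name compound name; defaults to the spectrum name or id.
#' @param formula optional chemical formula string.
#' @param cui integer Compound Ubiquity Index in 0--58. `CUI = 1` is the
#'   neutral value (no score correction); `CUI = 0` is an active penalty.
#' @param ri_source one of `"experimental"`, `"AIRI"`, `"absent"`. Must be
#'   `"absent"` if and only if the spectrum carries no RI.
#' @param has_free_polar_H does the compound retain an underivatized
#'   hydroxy or amino group?
#' @param has_tms does the compound carry at least one trimethylsilyl
#'   group?
#' @param extra named character list of pass-through MSP header fields.
#' @return An object of class `library_entry`.
#' @seealso [read_msp()], [filter_underivatized()], [cui_correction()]
#' @export
library_entry <- function(spectrum, compound_name = NULL, formula = NULL,
                          cui = 1L,
                          ri_source = c("experimental", "AIRI", "absent"),
                          has_free_polar_H = FALSE, has_tms = FALSE,
                          extra = list()) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (is.null(compound_name))
    compound_name <- if (!is.null(spectrum$name)) spectrum$name else spectrum$id
  if (is.null(compound_name)) stop("entry needs a compound name or id")
  cui <- as.integer(cui)
  if (is.na(cui) || cui < 0L || cui > 58L)
    stop("'cui' must be an integer in 0..58")
  if (is.null(spectrum$ri)) {
    ri_source <- "absent"
  } else {
    ri_source <- match.arg(ri_source)
    if (ri_source == "absent")
      stop("ri_source = 'absent' but the spectrum carries an RI")
  }
  structure(
    list(spectrum = spectrum, compound_name = compound_name,
         formula = formula, cui = cui, ri_source = ri_source,
         has_free_polar_H = isTRUE(has_free_polar_H),
         has_tms = isTRUE(has_tms), extra = extra),
    class = "library_entry")
}

#' @export
print.library_entry <- function(x, ...) {
  cat("<library_entry>", x$compound_name,
      sprintf("(CUI %d, %d peaks)\n", x$cui, nrow(x$spectrum$peaks)))
  invisible(x)
}
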