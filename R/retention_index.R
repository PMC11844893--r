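# Kovats retention-index penalization and homolog consistency.

#' Retention-index configuration
#'
#' @param threshold RI difference below which no penalty applies, in
#'   Kovats units (default 15).
#' @param penalty_rate score units removed per threshold-width beyond the
#'   threshold (default 50), i.e. the penalty is
#'   `penalty_rate * (dRI - threshold) / threshold`.
#' @param methylene_ri Kovats units contributed by one CH2 in a linear
#'   alkane (default 100).
#' @param methylene_mass mass of a methylene unit, 14 Da.
#' @param ri_tolerance_frac fractional tolerance for
#'   [methylene_consistency()] (default 0.30).
#' @return A list of class `ri_config`.
#' @export
ri_config <- function(threshold = 15, penalty_rate = 50,
                      methylene_ri = 100, methylene_mass = 14,
                      ri_tolerance_frac = 0.30) {
  stopifnot(threshold > 0, penalty_rate >= 0, methylene_ri > 0,
            methylene_mass > 0, ri_tolerance_frac >= 0)
  structure(list(threshold = threshold, penalty_rate = penalty_rate,
                 methylene_ri = methylene_ri,
                 methylene_mass = methylene_mass,
                 ri_tolerance_frac = ri_tolerance_frac),
            class = "ri_config")
}

#' Retention-index score penalty
#'
#' Zero for `dri` at or below the threshold; beyond it the score penalty
#' grows linearly as `penalty_rate * (dri - threshold) / threshold`
#' score units (with the defaults, `50 * (dRI - 15) / 15`).
#'
#' @param dri absolute RI difference (Kovats units), `>= 0`.
#' @param cfg an [ri_config()].
#' @return Penalty in score units.
#' @export
ri_penalty <- function(dri, cfg = ri_config()) {
  if (any(dri < 0)) stop("'dri' must be non-negative; take abs() first")
  ifelse(dri <= cfg$threshold, 0,
         cfg$penalty_rate * (dri - cfg$threshold) / cfg$threshold)
}

#' Apply the RI penalty to a match-factor score
#'
#' Subtracts [ri_penalty()] of the absolute RI difference from the score,
#' clamping at 0. If either RI is missing, the score is returned unchanged
#' and `dri` is reported as `NA` (penalization needs both values).
#'
#' @param score match factor in `[0, 999]`.
#' @param query_ri,lib_ri Kovats retention indices, or `NULL`/`NA`.
#' @param cfg an [ri_config()].
#' @return A list with `score` (corrected) and `dri` (absolute difference,
#'   or `NA`).
#' @export
apply_ri_correction <- function(score, query_ri, lib_ri,
                                cfg = ri_config()) {
  stopifnot(score >= 0, score <= 999)
  if (is.null(query_ri) || is.null(lib_ri) ||
      is.na(query_ri) || is.na(lib_ri))
    return(list(score = score, dri = NA_real_))
  dri <- abs(query_ri - lib_ri)
  list(score = max(0, score - ri_penalty(dri, cfg)), dri = dri)
}

#' Methylene homolog consistency of DeltaMass and dRI
#'
#' A molecular-mass difference that is a multiple of 14 Da suggests
#' insertion or deletion of CH2 units; each methylene shifts the Kovats
#' index by about 100 units. This check compares the signed RI difference
#' (query minus library) with the value expected from
#' `DeltaMass / 14` methylene units.
#'
#' @param delta_mass molecular-mass difference in Da (query minus
#'   library).
#' @param dri signed RI difference in Kovats units (query minus library).
#' @param cfg an [ri_config()]; `ri_tolerance_frac` sets the acceptance
#'   band around the expected shift.
#' @return A list with `verdict` (`"consistent"`, `"inconsistent"` or
#'   `"not_applicable"`) and `expected_dri` (`NA` when not applicable).
#' @export
methylene_consistency <- function(delta_mass, dri, cfg = ri_config()) {
  if (is.na(delta_mass) || delta_mass == 0 ||
      delta_mass %% cfg$methylene_mass != 0)
    return(list(verdict = "not_applicable", expected_dri = NA_real_))
  n <- delta_mass / cfg$methylene_mass
  expected <- cfg$methylene_ri * n
  ok <- abs(dri - expected) <= cfg$ri_tolerance_frac * abs(expected)
  list(verdict = if (ok) "consistent" else "inconsistent",
       expected_dri = expected)
}
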