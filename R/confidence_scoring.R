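# Probability and CUI corrections, Identity/Reverse combination, the
# bounded composite score, group probability, and hit filtering.

#' Confidence-scoring configuration
#'
#' @param kp Probability weighting factor (default 0.25; the composite
#'   worked example in the literature uses 0.2, so the factor is
#'   configurable).
#' @param kc Compound Ubiquity Index weighting factor (default 2).
#' @param prob_floor Probability (%) below which no correction applies
#'   (default 75, the median Probability of good identifications).
#' @param prob_span span (%) over which the correction ramps to its
#'   maximum (default 25).
#' @param combine_reverse average the RI-corrected Identity and Reverse
#'   scores into the base score MF1? (default `TRUE`; turn off when query
#'   spectra are carefully deconvolved and contaminant peaks are not a
#'   problem).
#' @param filter_underivatized drop library entries carrying a free
#'   hydroxy/amino group and no trimethylsilyl group before hit-list
#'   construction? (default `FALSE`; enable for TMS-derivatized
#'   workflows).
#' @param surrogate_probability compute surrogate hit Probabilities from
#'   the score distribution when none are supplied? (default `FALSE`).
#' @param surrogate_scale softmax scale in score units for the surrogate
#'   (default `28 / log(2)`, i.e. a 28-unit score difference doubles the
#'   relative likelihood).
#' @return A list of class `confidence_config`.
#' @export
confidence_config <- function(kp = 0.25, kc = 2, prob_floor = 75,
                              prob_span = 25, combine_reverse = TRUE,
                              filter_underivatized = FALSE,
                              surrogate_probability = FALSE,
                              surrogate_scale = 28 / log(2)) {
  stopifnot(kp >= 0, kc >= 0, prob_floor >= 0, prob_floor < 100,
            prob_span > 0, surrogate_scale > 0)
  structure(list(kp = kp, kc = kc, prob_floor = prob_floor,
                 prob_span = prob_span,
                 combine_reverse = isTRUE(combine_reverse),
                 filter_underivatized = isTRUE(filter_underivatized),
                 surrogate_probability = isTRUE(surrogate_probability),
                 surrogate_scale = surrogate_scale),
            class = "confidence_config")
}

#' Probability score correction
#'
#' Hit-list "Probability" measures the uniqueness of a match among library
#' spectra; values above 75% increase identification confidence even at
#' modest scores. The correction is `0` for `p <= 75` and
#' `kp * 999 * (p - 75) / 25` above it.
#'
#' @param p Probability in percent, `0 <= p <= 100`.
#' @param cfg a [confidence_config()].
#' @return Correction in score units (real; truncate for reporting).
#' @export
probability_correction <- function(p, cfg = confidence_config()) {
  if (any(is.na(p)) || any(p < 0) || any(p > 100))
    stop("'p' must be a Probability in [0, 100] percent")
  ifelse(p <= cfg$prob_floor, 0,
         cfg$kp * 999 * (p - cfg$prob_floor) / cfg$prob_span)
}

#' Compound Ubiquity Index score correction
#'
#' The CUI counts how many of 58 diverse chemical collections cite a
#' compound and serves as a prior-likelihood proxy. The correction is
#' `kc * (cui - 1)` for `cui >= 1` (no correction at the neutral
#' `cui = 1`) and the active penalty `-10 * kc` for `cui = 0`.
#'
#' @param cui integer Compound Ubiquity Index, `>= 0`.
#' @param cfg a [confidence_config()].
#' @return Correction in score units (negative only for `cui = 0`).
#' @export
cui_correction <- function(cui, cfg = confidence_config()) {
  if (any(is.na(cui)) || any(cui < 0)) stop("'cui' must be >= 0")
  ifelse(cui == 0, -10 * cfg$kc, cfg$kc * (cui - 1))
}

#' Combine Identity and Reverse scores
#'
#' The arithmetic mean of the RI-corrected Identity and Reverse match
#' factors, used as the base score MF1 when contaminant peaks depress the
#' Identity score.
#'
#' @param mf_id,mf_rev scores in `[0, 999]`.
#' @return The real-valued mean.
#' @export
combine_identity_reverse <- function(mf_id, mf_rev) {
  stopifnot(all(mf_id >= 0 & mf_id <= 999), all(mf_rev >= 0 & mf_rev <= 999))
  (mf_id + mf_rev) / 2
}

#' Bounded composite score
#'
#' Adjusts a base score `MF1` by a total correction `Corr` (the sum of the
#' Probability and CUI corrections) while keeping the result in
#' `[0, 999]`. The headroom term is `dMF = 999 - MF1` for positive `Corr`
#' and `dMF = MF1` for negative `Corr`; the applied adjustment saturates
#' as
#' `MFcorr = dMF * |Corr| / (dMF + |Corr|)`,
#' added to (positive) or subtracted from (negative) `MF1`. The adjustment
#' therefore never exceeds the available headroom: the composite is
#' strictly increasing in `Corr` and approaches 999 (or 0) only
#' asymptotically.
#'
#' @param mf1 base score in `[0, 999]` (real-valued; e.g. an
#'   Identity/Reverse average).
#' @param corr total correction in score units (any sign).
#' @return A list of class `score_breakdown` with `mf1`, `corr`,
#'   `delta_mf`, `mf_corr`, `final` (real) and `final_reported`
#'   (truncated integer).
#' @examples
#' composite_score(705.5, 219)$final_reported  # 830
#' composite_score(865, 50)$final_reported     # 901
#' @export
composite_score <- function(mf1, corr) {
  stopifnot(mf1 >= 0, mf1 <= 999)
  if (corr > 0) {
    delta_mf <- 999 - mf1
    mf_corr <- if (delta_mf + corr > 0) delta_mf * corr / (delta_mf + corr) else 0
    final <- mf1 + mf_corr
  } else if (corr < 0) {
    delta_mf <- mf1
    a <- abs(corr)
    mf_corr <- if (delta_mf + a > 0) delta_mf * a / (delta_mf + a) else 0
    final <- mf1 - mf_corr
  } else {
    delta_mf <- 999 - mf1
    mf_corr <- 0
    final <- mf1
  }
  structure(list(mf1 = mf1, corr = corr, delta_mf = delta_mf,
                 mf_corr = mf_corr, final = final,
                 final_reported = floor(final)),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("<score_breakdown> MF1 %.1f %+.0f (dMF %.1f, MFcorr %.1f) -> %d\n",
              x$mf1, x$corr, x$delta_mf, x$mf_corr, x$final_reported))
  invisible(x)
}

#' Annotate a hit list with a group probability
#'
#' When several isomers with similar spectra top a hit list, their
#' individual Probabilities are each low, but a large score gap can
#' separate the isomer group from lower-ranked hits. The group is taken as
#' the hits above the largest adjacent score difference among the top
#' `gap_depth` hits (ties with the boundary score are included), and its
#' probability is the sum of member Probabilities, capped at 100%.
#'
#' @param hits a hit-list data.frame sorted by descending score, with
#'   columns `final` and `probability`.
#' @param gap_depth how deep to search for the largest gap (default 10).
#' @return `hits` with added columns `in_top_group` (logical) and
#'   `group_probability` (% for group members, `NA` otherwise).
#' @export
group_probability <- function(hits, gap_depth = 10L) {
  df <- as.data.frame(hits)
  n <- nrow(df)
  df$in_top_group <- FALSE
  df$group_probability <- NA_real_
  if (n == 0L) return(df)
  score <- df$final
  if (is.unsorted(rev(score))) stop("hits must be sorted by descending score")
  if (n < 2L) {
    df$in_top_group <- TRUE
    df$group_probability <- df$probability
    return(df)
  }
  m <- min(gap_depth, n)
  gaps <- score[seq_len(m - 1L)] - score[2:m]
  cut <- which.max(gaps)
  grp <- seq_len(cut)
  # include exact ties with the boundary score
  while (max(grp) < n && score[max(grp) + 1L] == score[cut])
    grp <- c(grp, max(grp) + 1L)
  df$in_top_group[grp] <- TRUE
  gp <- sum(df$probability[grp])
  df$group_probability[grp] <- if (is.na(gp)) NA_real_ else min(100, gp)
  df
}

#' Filter underivatized library candidates
#'
#' In workflows where active hydrogens are trimethylsilylated before
#' analysis, compounds retaining a free hydroxy or amino group should be
#' nearly absent from the sample, yet they can produce high-scoring,
#' almost certainly incorrect hits (e.g. long-chain alcohols whose spectra
#' and retention indices mimic alkenes). When enabled, entries flagged
#' `has_free_polar_H` without at least one TMS group are removed before
#' hit-list construction; partially derivatized entries (any TMS group)
#' are retained.
#'
#' @param entries list of [library_entry()] objects.
#' @param enabled apply the filter? `FALSE` returns `entries` unchanged.
#' @return The filtered list.
#' @export
filter_underivatized <- function(entries, enabled = TRUE) {
  if (!enabled) return(entries)
  Filter(function(e) !(e$has_free_polar_H && !e$has_tms), entries)
}

#' Surrogate hit Probabilities from the score distribution
#'
#' A clearly-labeled stand-in for externally supplied hit-list
#' Probabilities, enabling end-to-end runs when none are available. It
#' converts scores into normalized exponential weights
#' `exp(score / scale)` expressed in percent, so equal scores share the
#' probability mass and larger score differences imply larger likelihood
#' ratios. It is *not* the calibrated Probability model of library-search
#' software; outputs based on it are labeled as surrogate.
#'
#' @param scores numeric hit scores.
#' @param scale softmax scale in score units (default `28 / log(2)`: a
#'   28-unit difference doubles the relative likelihood).
#' @return Probabilities in percent, summing to 100.
#' @export
surrogate_probability <- function(scores, scale = 28 / log(2)) {
  stopifnot(length(scores) >= 1L, scale > 0)
  w <- exp((scores - max(scores)) / scale)
  100 * w / sum(w)
}
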