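# Orchestration: preprocessing, candidate scoring, corrections,
# filtering, ranking, annotation.

#' Search configuration
#'
#' Aggregates the per-module configurations and the search mode.
#'
#' @param mode `"identity"` (mass-weighted, RI-penalized, with optional
#'   Identity/Reverse combination), `"similarity"` (unweighted mass, no RI
#'   penalty) or `"hybrid"` (neutral-loss matching via DeltaMass; no RI
#'   penalty, methylene consistency reported instead).
#' @param top_k hit-list length (default 10).
#' @param prep a [prep_config()].
#' @param weighting a [weighting_scheme()] for the Identity/Reverse
#'   searches.
#' @param ri an [ri_config()].
#' @param confidence a [confidence_config()].
#' @return A list of class `search_config`.
#' @export
search_config <- function(mode = c("identity", "similarity", "hybrid"),
                          top_k = 10L, prep = prep_config(),
                          weighting = weighting_scheme(),
                          ri = ri_config(),
                          confidence = confidence_config()) {
  mode <- match.arg(mode)
  top_k <- as.integer(top_k)
  stopifnot(top_k >= 1L)
  structure(list(mode = mode, top_k = top_k, prep = prep,
                 weighting = weighting, ri = ri, confidence = confidence),
            class = "search_config")
}

#' Search a spectral library for a query spectrum
#'
#' Runs the full identification pipeline: base-peak normalization and
#' PFMD calibrant removal on the query; optional removal of underivatized
#' library candidates; the mode-specific match factor against every
#' entry; RI penalization and Identity/Reverse combination (identity
#' mode); Probability and CUI corrections truncated to integers, summed,
#' and applied through the bounded [composite_score()]; deterministic
#' ranking; and group-probability annotation. Every hit carries the full
#' score breakdown for audit.
#'
#' Ties in the final score are broken by higher Identity score, then
#' smaller absolute RI difference, then compound name.
#'
#' @param query a [spectrum()].
#' @param library a non-empty list of [library_entry()] objects.
#' @param cfg a [search_config()].
#' @param probabilities optional numeric vector of hit Probabilities (%)
#'   aligned with `library` (e.g. from external search software). When
#'   absent and `cfg$confidence$surrogate_probability` is `TRUE`,
#'   surrogate values are computed over the top `top_k` hits; otherwise
#'   the Probability correction is 0.
#' @return A data.frame of class `hitlist` (one row per candidate, top
#'   `top_k` after ranking) with the score breakdown columns described in
#'   [write_hitlist_tsv()].
#' @export
search_library <- function(query, library, cfg = search_config(),
                           probabilities = NULL) {
  stopifnot(inherits(query, "spectrum"))
  if (length(library) == 0L) stop("'library' must be non-empty")
  q <- remove_pfmd(normalize_base_peak(query), cfg$prep)
  keep <- if (cfg$confidence$filter_underivatized)
    vapply(library, function(e) !(e$has_free_polar_H && !e$has_tms),
           logical(1))
  else rep(TRUE, length(library))
  lib <- library[keep]
  if (!is.null(probabilities)) {
    stopifnot(length(probabilities) == length(library))
    probabilities <- probabilities[keep]
  }
  if (length(lib) == 0L) return(.empty_hitlist(q))

  nl <- length(lib)
  mf_identity <- mf_reverse <- mf1 <- rep(NA_real_, nl)
  dri <- delta_mass <- rep(NA_real_, nl)
  methylene <- rep(NA_character_, nl)

  if (cfg$mode == "identity") {
    for (j in seq_len(nl)) {
      ls <- lib[[j]]$spectrum
      rc_i <- apply_ri_correction(identity_match_factor(q, ls, cfg$weighting),
                                  q$ri, ls$ri, cfg$ri)
      rc_r <- apply_ri_correction(reverse_match_factor(q, ls, cfg$weighting),
                                  q$ri, ls$ri, cfg$ri)
      mf_identity[j] <- rc_i$score
      mf_reverse[j] <- rc_r$score
      dri[j] <- rc_i$dri
      mf1[j] <- if (cfg$confidence$combine_reverse)
        combine_identity_reverse(rc_i$score, rc_r$score) else rc_i$score
    }
  } else if (cfg$mode == "similarity") {
    for (j in seq_len(nl)) {
      ls <- lib[[j]]$spectrum
      mf1[j] <- similarity_match_factor(q, ls)
      if (!is.null(q$ri) && !is.null(ls$ri)) dri[j] <- abs(q$ri - ls$ri)
    }
  } else { # hybrid
    qM <- q$mw
    if (is.null(qM)) {
      est <- estimate_molecular_mass(q, cfg$prep)
      if (is.null(est))
        stop("hybrid mode: query molecular mass could not be determined; ",
             "supply 'mw' or a spectrum amenable to ",
             "estimate_molecular_mass()")
      qM <- est$mw
    }
    for (j in seq_len(nl)) {
      ls <- lib[[j]]$spectrum
      if (is.null(ls$mw)) {
        mf1[j] <- similarity_match_factor(q, ls)
      } else {
        hr <- hybrid_match_factor(q, ls, qM = qM)
        mf1[j] <- hr$score
        delta_mass[j] <- hr$delta_mass
        if (!is.null(q$ri) && !is.null(ls$ri)) {
          sdri <- q$ri - ls$ri
          dri[j] <- abs(sdri)
          methylene[j] <- methylene_consistency(hr$delta_mass, sdri,
                                                cfg$ri)$verdict
        } else {
          methylene[j] <- methylene_consistency(hr$delta_mass, NA_real_,
                                                cfg$ri)$verdict
        }
      }
    }
  }

  df <- data.frame(
    query_id = q$id %||% "",
    name = vapply(lib, `[[`, "", "compound_name"),
    formula = vapply(lib, function(e) e$formula %||% NA_character_, ""),
    mw = vapply(lib, function(e) e$spectrum$mw %||% NA_real_, 0),
    cui = vapply(lib, `[[`, 0L, "cui"),
    lib_ri = vapply(lib, function(e) e$spectrum$ri %||% NA_real_, 0),
    dri = dri, mf_identity = mf_identity, mf_reverse = mf_reverse,
    mf1 = mf1, delta_mass = delta_mass, methylene = methylene,
    stringsAsFactors = FALSE)

  # probability: supplied, surrogate over the top_k by MF1, or none
  ord1 <- order(-df$mf1, df$name, method = "radix")
  df$probability <- NA_real_
  if (!is.null(probabilities)) {
    df$probability <- probabilities
  } else if (cfg$confidence$surrogate_probability) {
    top <- ord1[seq_len(min(cfg$top_k, nl))]
    df$probability[top] <- surrogate_probability(
      df$mf1[top], cfg$confidence$surrogate_scale)
  }

  df$corr_p <- ifelse(is.na(df$probability), 0,
                      trunc(probability_correction(
                        pmin(100, pmax(0, df$probability)),
                        cfg$confidence)))
  df$corr_cui <- trunc(cui_correction(df$cui, cfg$confidence))
  df$corr <- df$corr_p + df$corr_cui
  comp <- mapply(function(m, co) {
    b <- composite_score(m, co)
    c(b$delta_mf, b$mf_corr, b$final)
  }, df$mf1, df$corr)
  df$delta_mf <- comp[1L, ]
  df$mf_corr <- comp[2L, ]
  df$final <- comp[3L, ]

  ord <- order(-df$final, -ifelse(is.na(df$mf_identity), -Inf,
                                  df$mf_identity),
               ifelse(is.na(df$dri), Inf, df$dri), df$name,
               method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- utils::head(df, cfg$top_k)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df <- group_probability(df)
  class(df) <- c("hitlist", "data.frame")
  df
}

.empty_hitlist <- function(q) {
  df <- data.frame(query_id = character(0), name = character(0),
                   formula = character(0), mw = numeric(0),
                   cui = integer(0), lib_ri = numeric(0), dri = numeric(0),
                   mf_identity = numeric(0), mf_reverse = numeric(0),
                   mf1 = numeric(0), delta_mass = numeric(0),
                   methylene = character(0), probability = numeric(0),
                   corr_p = numeric(0), corr_cui = numeric(0),
                   corr = numeric(0), delta_mf = numeric(0),
                   mf_corr = numeric(0), final = numeric(0),
                   rank = integer(0), in_top_group = logical(0),
                   group_probability = numeric(0))
  class(df) <- c("hitlist", "data.frame")
  df
}

#' @export
print.hitlist <- function(x, ...) {
  cat("<hitlist>", nrow(x), "hits",
      if (nrow(x)) paste0("for query '", x$query_id[1], "'"), "\n")
  cols <- intersect(c("rank", "name", "mf1", "corr", "final", "dri",
                      "delta_mass", "group_probability"), names(x))
  df <- as.data.frame(x)[, cols, drop = FALSE]
  for (cl in intersect(c("mf1", "final"), cols)) df[[cl]] <- floor(df[[cl]])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Triage spectra by identifiability
#'
#' Low median relative abundance (high dynamic range) correlates with
#' library-search identifiability; spectra whose median exceeds the cutoff
#' tend to be dominated by near-detection-limit contaminant peaks. The
#' default 1% cutoff corresponds to a median of 10 on the 999 base-peak
#' scale.
#'
#' @param spectra non-empty list of [spectrum()] objects.
#' @param cutoff_percent cutoff in percent of the base peak (default 1.0).
#' @return A list with `likely_identifiable` and `unlikely` (lists of
#'   spectra) and `summary`, a data.frame of per-spectrum medians.
#' @export
triage <- function(spectra, cutoff_percent = 1.0) {
  stopifnot(length(spectra) > 0)
  med <- vapply(spectra, median_relative_abundance, 0)
  ids <- vapply(seq_along(spectra),
                function(i) spectra[[i]]$id %||% paste0("spectrum_", i), "")
  likely <- med <= cutoff_percent
  list(likely_identifiable = spectra[likely],
       unlikely = spectra[!likely],
       summary = data.frame(id = ids, median_rel_abundance = med,
                            likely_identifiable = likely))
}

#' Re-annotate query spectra against a library
#'
#' Searches every query and re-emits it with annotation headers carrying
#' the top hit's score breakdown, group probability, RI difference and
#' the query's median relative abundance. When the top hit's truncated
#' final score exceeds 750, the query's name is replaced by the library
#' compound name (strictly greater: a 750 keeps the original name).
#'
#' @param queries list of [spectrum()] objects.
#' @param library list of [library_entry()] objects.
#' @param cfg a [search_config()].
#' @param msp_out,tsv_out optional output paths for the annotated MSP and
#'   the combined hit-list TSV.
#' @return Invisibly, a list with `entries` (annotated
#'   [library_entry()] objects) and `hits` (combined hit-list
#'   data.frame).
#' @export
annotate_library <- function(queries, library, cfg = search_config(),
                             msp_out = NULL, tsv_out = NULL) {
  entries <- list()
  hit_tabs <- list()
  for (qi in seq_along(queries)) {
    q <- normalize_base_peak(queries[[qi]])
    hits <- search_library(q, library, cfg)
    hit_tabs[[qi]] <- as.data.frame(hits)
    name <- q$name %||% q$id
    extra <- list()
    if (nrow(hits)) {
      top <- hits[1L, ]
      if (floor(top$final) > 750) name <- top$name
      extra <- list(
        Annot_Top_Hit = top$name,
        Annot_Score = as.character(floor(top$final)),
        Annot_MF1 = sprintf("%.1f", top$mf1),
        Annot_Corr = as.character(top$corr),
        Annot_Group_Probability =
          if (is.na(top$group_probability)) "NA"
          else sprintf("%.1f", top$group_probability),
        Annot_dRI = if (is.na(top$dri)) "NA" else format(top$dri),
        Annot_Median_Abundance =
          sprintf("%.2f", median_relative_abundance(q)))
      if (isTRUE(cfg$confidence$surrogate_probability))
        extra$Annot_Probability_Source <- "surrogate"
    }
    entries[[qi]] <- library_entry(q, compound_name = name, extra = extra)
  }
  hits_all <- if (length(hit_tabs))
    do.call(rbind, c(hit_tabs, list(make.row.names = FALSE)))
  else as.data.frame(.empty_hitlist(NULL))
  if (!is.null(msp_out)) write_msp(entries, msp_out)
  if (!is.null(tsv_out)) write_hitlist_tsv(hits_all, tsv_out)
  invisible(list(entries = entries, hits = hits_all))
}
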