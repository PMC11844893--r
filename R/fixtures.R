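# Synthetic library / query generator.
#
# Emulates the statistical structure the scoring methods assume for
# TMS-derivatized GC-EI-MS data: a 73 Da TMS fragment with an
# [M-15]+/[M]+ pair, CH2 homolog families sharing fragment patterns
# shifted by 14 Da with retention indices offset by ~100 Kovats units,
# skewed compound-ubiquity counts, and contaminated queries whose noise
# extends above the molecular ion. Not a physical fragmentation model.

#' Fixture-generator configuration
#'
#' @param n_compounds number of library entries (default 60).
#' @param peaks_min,peaks_max range of fragment counts per spectrum
#'   (default 8--20).
#' @param homolog_family_fraction fraction of entries generated inside
#'   CH2 homolog families (default 0.3).
#' @param contamination_rate fraction of a degraded query's peaks that
#'   are spurious (default 0.15).
#' @param high_mass_contaminant_bias place most contaminant peaks above
#'   the molecular ion? (default `TRUE`).
#' @param tms_fraction fraction of entries generated as TMS derivatives
#'   (73 Da fragment plus an `[M-15]+`/`[M]+` pair; default 0.6).
#' @param free_polar_fraction fraction of non-TMS entries flagged as
#'   retaining a free hydroxy/amino group (default 0.1).
#' @param seed random seed; mandatory, so fixtures are reproducible.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_compounds = 60L, peaks_min = 8L,
                           peaks_max = 20L,
                           homolog_family_fraction = 0.3,
                           contamination_rate = 0.15,
                           high_mass_contaminant_bias = TRUE,
                           tms_fraction = 0.6,
                           free_polar_fraction = 0.1, seed) {
  if (missing(seed)) stop("'seed' is required for reproducible fixtures")
  stopifnot(n_compounds >= 1, peaks_min >= 3, peaks_max >= peaks_min,
            homolog_family_fraction >= 0, homolog_family_fraction <= 1,
            contamination_rate >= 0, contamination_rate < 1,
            tms_fraction >= 0, tms_fraction <= 1,
            free_polar_fraction >= 0, free_polar_fraction <= 1)
  structure(list(n_compounds = as.integer(n_compounds),
                 peaks_min = as.integer(peaks_min),
                 peaks_max = as.integer(peaks_max),
                 homolog_family_fraction = homolog_family_fraction,
                 contamination_rate = contamination_rate,
                 high_mass_contaminant_bias =
                   isTRUE(high_mass_contaminant_bias),
                 tms_fraction = tms_fraction,
                 free_polar_fraction = free_polar_fraction,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# one synthetic compound; fragments drawn without replacement from
# 50..(mw-20), intensities log-uniform over the 999 dynamic range
.fixture_compound <- function(cfg, idx) {
  mw <- sample(180:420, 1L)
  npk <- sample(cfg$peaks_min:cfg$peaks_max, 1L)
  is_tms <- stats::runif(1) < cfg$tms_fraction
  frags <- sample(50:(mw - 20L), npk)
  intens <- exp(stats::runif(npk, log(5), log(999)))
  if (is_tms) {
    frags <- c(frags, 73L, mw - 15L, mw)
    intens <- c(intens,
                999 * stats::runif(1, 0.5, 1),      # TMS marker
                999 * stats::runif(1, 0.08, 0.5),   # [M-15]+
                999 * stats::runif(1, 0.01, 0.2))   # [M]+
  } else {
    frags <- c(frags, mw)
    intens <- c(intens, 999 * stats::runif(1, 0.06, 0.6))
  }
  ri <- round(7 * mw + stats::rnorm(1, 0, 60))
  cui <- min(58L, as.integer(round(stats::rexp(1, 1 / 6))))
  list(mw = mw, frags = as.integer(frags), intens = intens, ri = ri,
       cui = cui, is_tms = is_tms,
       free_polar = !is_tms && stats::runif(1) < cfg$free_polar_fraction)
}

.fixture_entry <- function(cmp, id, name) {
  s <- spectrum(cmp$frags, cmp$intens, id = id, ri = cmp$ri, mw = cmp$mw,
                name = name)
  s <- normalize_base_peak(s)
  s$peaks$intensity <- signif(s$peaks$intensity, 4)
  library_entry(s, compound_name = name, cui = cmp$cui,
                ri_source = sample(c("experimental", "AIRI"), 1L,
                                   prob = c(0.7, 0.3)),
                has_free_polar_H = cmp$free_polar,
                has_tms = cmp$is_tms)
}

#' Generate a synthetic spectral library
#'
#' Produces `n_compounds` entries with random fragment sets, molecular
#' masses, retention indices (roughly proportional to mass, as for a
#' nonpolar column) and skewed CUIs in 0--58. A
#' `homolog_family_fraction` of the entries is generated in CH2 homolog
#' families: members share the fragment pattern shifted by multiples of
#' 14 Da (the 73 Da TMS marker stays put), with molecular masses offset
#' by 14 Da and retention indices by ~100 Kovats units per methylene.
#' Deterministic for a fixed seed.
#'
#' @param cfg a [fixture_config()].
#' @return A list of [library_entry()] objects; homolog members carry a
#'   `Family` pass-through field.
#' @export
generate_library <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(cfg$seed)
  entries <- list()
  n_homolog <- round(cfg$homolog_family_fraction * cfg$n_compounds)
  fam <- 0L
  while (cfg$n_compounds - length(entries) > 0 &&
         n_homolog - sum(vapply(entries, function(e)
           !is.null(e$extra$Family), logical(1))) > 1) {
    fam <- fam + 1L
    size <- sample(2:4, 1L)
    base <- .fixture_compound(cfg, length(entries) + 1L)
    for (k in seq_len(size) - 1L) {
      if (length(entries) >= cfg$n_compounds) break
      cmp <- base
      shift <- 14L * k
      keep73 <- cmp$is_tms & cmp$frags == 73L
      cmp$frags <- ifelse(keep73, cmp$frags, cmp$frags + shift)
      cmp$mw <- cmp$mw + shift
      cmp$ri <- base$ri + 100 * k + round(stats::rnorm(1, 0, 4))
      idx <- length(entries) + 1L
      name <- sprintf("Homolog family %d member C%d", fam, k + 1L)
      e <- .fixture_entry(cmp, sprintf("LIB_%03d", idx), name)
      e$extra$Family <- as.character(fam)
      entries[[idx]] <- e
    }
  }
  while (length(entries) < cfg$n_compounds) {
    idx <- length(entries) + 1L
    cmp <- .fixture_compound(cfg, idx)
    entries[[idx]] <- .fixture_entry(cmp, sprintf("LIB_%03d", idx),
                                     sprintf("Compound %03d", idx))
  }
  entries
}

#' Add contaminant peaks to a query spectrum
#'
#' Models the contamination seen in low-abundance spectra: spurious peaks
#' at random masses (biased above the molecular ion when
#' `high_mass_contaminant_bias` is set) with relative intensities between
#' the spectrum's current median and 30% of the base peak, i.e. the
#' near-detection-limit peaks that inflate median relative abundance.
#' Contaminant peaks are added so they make up `contamination_rate` of
#' the degraded spectrum, which is then renormalized. Ground-truth
#' provenance of every peak is recorded in the `provenance` column of
#' `peaks`.
#'
#' @param s a normalized [spectrum()].
#' @param cfg a [fixture_config()] (`contamination_rate`,
#'   `high_mass_contaminant_bias`). The caller controls the RNG state.
#' @return The degraded spectrum.
#' @export
degrade_query <- function(s, cfg) {
  stopifnot(inherits(s, "spectrum"), inherits(cfg, "fixture_config"))
  if (cfg$contamination_rate == 0) {
    s$peaks$provenance <- "signal"
    return(s)
  }
  n <- nrow(s$peaks)
  m <- max(1L, round(cfg$contamination_rate /
                       (1 - cfg$contamination_rate) * n))
  base <- max(s$peaks$intensity)
  med_rel <- stats::median(s$peaks$intensity) / base
  mw <- s$mw %||% max(s$peaks$mz)
  pool_hi <- setdiff(seq(mw + 1L, mw + 120L), s$peaks$mz)
  pool_lo <- setdiff(50:max(51L, mw - 1L), s$peaks$mz)
  n_hi <- if (cfg$high_mass_contaminant_bias) round(0.6 * m) else round(0.2 * m)
  cont_mz <- c(sample(pool_hi, min(n_hi, length(pool_hi))),
               sample(pool_lo, min(m - n_hi, length(pool_lo))))
  lo <- max(med_rel, 0.02)
  cont_int <- base * stats::runif(length(cont_mz), lo, max(0.30, lo + 0.05))
  prov <- c(rep("signal", n), rep("contaminant", length(cont_mz)))
  o <- order(c(s$peaks$mz, cont_mz))
  out <- spectrum(c(s$peaks$mz, cont_mz), c(s$peaks$intensity, cont_int),
                  id = s$id, ri = s$ri, mw = s$mw, name = s$name)
  out <- normalize_base_peak(out)
  out$peaks$provenance <- prov[o]
  out
}

#' Generate a matched fixture set: library, clean and degraded queries
#'
#' Queries are drawn from the library (with replacement when
#' `n_queries > n_compounds`), perturbed with small multiplicative
#' intensity noise (lognormal, 10%) and retention-index jitter (sd 3
#' Kovats units) to emulate replicate measurement, then degraded with
#' [degrade_query()]. Ground truth maps each query to its source entry.
#'
#' @param cfg a [fixture_config()].
#' @param n_queries number of query spectra (default `n_compounds`).
#' @return A list with `library`, `queries_clean`, `queries_degraded`
#'   (lists) and `truth`, a data.frame with columns `query_id`, `lib_id`,
#'   `name`.
#' @export
generate_fixture_set <- function(cfg, n_queries = cfg$n_compounds) {
  lib <- generate_library(cfg)
  src <- sample(seq_along(lib), n_queries, replace = n_queries > length(lib))
  clean <- degraded <- vector("list", n_queries)
  for (i in seq_len(n_queries)) {
    e <- lib[[src[i]]]
    s <- e$spectrum
    s$peaks$intensity <- s$peaks$intensity *
      exp(stats::rnorm(nrow(s$peaks), 0, 0.1))
    s <- normalize_base_peak(s)
    s$peaks$intensity <- signif(s$peaks$intensity, 4)
    s$ri <- s$ri + round(stats::rnorm(1, 0, 3))
    s$id <- sprintf("QRY_%04d", i)
    s$name <- sprintf("query %04d", i)
    clean[[i]] <- s
    degraded[[i]] <- degrade_query(s, cfg)
    degraded[[i]]$peaks$intensity <-
      signif(degraded[[i]]$peaks$intensity, 4)
  }
  list(library = lib, queries_clean = clean, queries_degraded = degraded,
       truth = data.frame(
         query_id = vapply(clean, `[[`, "", "id"),
         lib_id = vapply(lib[src], function(e) e$spectrum$id, ""),
         name = vapply(lib[src], `[[`, "", "compound_name")))
}
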