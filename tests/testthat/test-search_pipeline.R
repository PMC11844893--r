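make_small_library <- function(seed = 202) {
  generate_library(fixture_config(n_compounds = 20, seed = seed))
}

test_that("an exact library match ranks first with the full score", {
  lib <- make_small_library()
  q <- lib[[5]]$spectrum
  hits <- search_library(q, lib,
                         search_config(confidence = confidence_config(kc = 0)))
  expect_equal(hits$name[1], lib[[5]]$compound_name)
  expect_equal(floor(hits$final[1]), 999)
  expect_equal(hits$rank, seq_len(nrow(hits)))
})

test_that("CUI correction can reorder isomeric entries with equal spectra", {
  s <- normalize_base_peak(random_spectrum(10, mw = 250, ri = 1750))
  iso1 <- library_entry(s, "rare isomer", cui = 3)
  iso2 <- library_entry(s, "ubiquitous isomer", cui = 26)
  filler <- make_small_library()
  # imperfect query (replicate noise) leaves headroom for the correction
  q <- s
  q$peaks$intensity <- s$peaks$intensity * exp(rnorm(10, 0, 0.3))
  q <- normalize_base_peak(q)
  hits <- search_library(q, c(list(iso1, iso2), filler))
  expect_equal(hits$name[1], "ubiquitous isomer")
  expect_gt(hits$final[1], hits$final[2])
  # kc = 0 restores the pure-identity tie broken lexicographically
  hits0 <- search_library(
    s, list(iso1, iso2),
    search_config(confidence = confidence_config(kp = 0, kc = 0,
                                                 combine_reverse = FALSE)))
  expect_equal(hits0$final, hits0$mf_identity)
})

test_that("hybrid mode ranks a CH2 homolog on top with DeltaMass +/-14", {
  cfg <- fixture_config(n_compounds = 30, homolog_family_fraction = 0.2,
                        seed = 31)
  lib <- generate_library(cfg)
  fam <- which(vapply(lib, function(e) identical(e$extra$Family, "1"),
                      logical(1)))
  expect_gte(length(fam), 2)
  q <- lib[[fam[2]]]$spectrum          # second member: 14 Da above member 1
  others <- lib[setdiff(seq_along(lib), fam[2])]
  hits <- search_library(q, others, search_config(mode = "hybrid"))
  expect_true(grepl("Homolog family 1", hits$name[1]))
  expect_equal(abs(hits$delta_mass[1]), 14)
  expect_equal(hits$methylene[1], "consistent")
  fam_hits <- grepl("Homolog family 1", hits$name)
  if (any(!fam_hits)) expect_gt(min(hits$mf1[fam_hits]),
                                max(hits$mf1[!fam_hits]))
})

test_that("hybrid mode estimates a missing query mass from the spectrum", {
  cfg <- fixture_config(n_compounds = 30, homolog_family_fraction = 0.2,
                        seed = 31)
  lib <- generate_library(cfg)
  tms <- which(vapply(lib, `[[`, logical(1), "has_tms"))[1]
  q <- lib[[tms]]$spectrum
  q$mw <- NULL                        # force the TMS pair-rule estimate
  hits <- search_library(q, lib, search_config(mode = "hybrid"))
  expect_equal(hits$name[1], lib[[tms]]$compound_name)
  expect_equal(hits$delta_mass[1], 0)
})

test_that("RI penalization demotes candidates with discrepant retention indices", {
  s <- normalize_base_peak(random_spectrum(10, mw = 250, ri = 1500))
  near <- library_entry(s, "right RI", cui = 1)
  far <- near; far$compound_name <- "wrong RI"
  far$spectrum$ri <- 1700
  hits <- search_library(s, list(far, near))
  expect_equal(hits$name[1], "right RI")
  expect_equal(hits$mf_identity[2],
               999 - 50 * (200 - 15) / 15, tolerance = 1e-9)
})

test_that("disabling every correction reduces ranking to RI-corrected identity order", {
  lib <- make_small_library(seed = 404)
  q <- lib[[3]]$spectrum
  cfg <- search_config(top_k = length(lib),
                       confidence = confidence_config(
                         kp = 0, kc = 0, combine_reverse = FALSE))
  hits <- search_library(q, lib, cfg)
  expect_equal(hits$final, hits$mf_identity)
  expect_equal(hits$final, sort(hits$final, decreasing = TRUE))
})

test_that("search is deterministic for fixed inputs", {
  lib <- make_small_library(seed = 77)
  q <- degrade_query(lib[[1]]$spectrum,
                     fixture_config(n_compounds = 1, seed = 5))
  h1 <- search_library(q, lib)
  h2 <- search_library(q, lib)
  expect_identical(h1, h2)
})

test_that("triage splits spectra at the median-abundance cutoff", {
  # medians anchored at the identifiable (0.49%) / unidentifiable (1.73%)
  # population values
  mk <- function(med_pct, id) {
    ints <- c(999, rep(med_pct / 100 * 999, 3))
    spectrum(c(50, 60, 70, 80), ints, id = id)
  }
  likely <- mk(0.49, "hi_dynamic_range")
  unlikely <- mk(1.73, "low_dynamic_range")
  flat <- spectrum(c(50, 60, 70), c(500, 500, 500), id = "flat")
  tr <- triage(list(likely, unlikely, flat), 1.0)
  expect_equal(vapply(tr$likely_identifiable, `[[`, "", "id"),
               "hi_dynamic_range")
  expect_setequal(vapply(tr$unlikely, `[[`, "", "id"),
                  c("low_dynamic_range", "flat"))
  expect_equal(median_relative_abundance(flat), 100)
})

test_that("annotation substitutes names only above the 750 score boundary", {
  lib <- make_small_library(seed = 88)
  exact <- lib[[2]]$spectrum           # final 999 > 750: renamed
  exact$id <- "UNK_A"; exact$name <- "original A"
  weak <- random_spectrum(8, id = "UNK_B")  # unrelated: low score, kept
  weak$name <- "original B"
  out <- annotate_library(list(exact, weak), lib,
                          search_config(confidence = confidence_config(kc = 0)))
  expect_equal(out$entries[[1]]$compound_name, lib[[2]]$compound_name)
  expect_equal(out$entries[[2]]$compound_name, "original B")
  expect_true("Annot_Score" %in% names(out$entries[[1]]$extra))
  # boundary: a truncated 750 keeps the original name (strict inequality)
  expect_true(floor(750.9) == 750)  # truncation convention feeding the rule
  # empty query set
  out0 <- annotate_library(list(), lib)
  expect_length(out0$entries, 0)
  expect_equal(nrow(out0$hits), 0)
})

test_that("annotation writes re-readable MSP and TSV outputs", {
  lib <- make_small_library(seed = 99)
  msp <- withr::local_tempfile(fileext = ".msp")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  out <- annotate_library(list(lib[[1]]$spectrum), lib,
                          msp_out = msp, tsv_out = tsv)
  suppressMessages(back <- read_msp(msp))
  expect_length(back, 1)
  expect_true("Annot_Score" %in% names(back[[1]]$extra))
  tab <- utils::read.delim(tsv)
  expect_equal(nrow(tab), nrow(out$hits))
})

test_that("the CLI runs the fixture and search subcommands end to end", {
  dir <- withr::local_tempdir()
  st <- specid_cli(c("fixtures", "--out", dir, "--seed", "9",
                     "--n-compounds", "12"))
  expect_equal(st, 0L)
  expect_true(file.exists(file.path(dir, "library.msp")))
  hits_tsv <- file.path(dir, "hits.tsv")
  st2 <- specid_cli(c("search", "-q", file.path(dir, "queries_clean.msp"),
                      "-l", file.path(dir, "library.msp"),
                      "-o", hits_tsv))
  expect_equal(st2, 0L)
  tab <- utils::read.delim(hits_tsv)
  expect_true(all(c("query_id", "rank", "name", "final") %in% names(tab)))
  expect_equal(specid_cli(c("search", "-q", "missing.msp")), 1L)
})
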