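# NIST MSP text I/O and TSV hit-list serialization.
#
# Dialect notes: header synonyms are matched case-insensitively with the
# first occurrence winning (Retention_index/RI, DBs/CUI, MW/MolWeight);
# peak lists may be wrapped over several lines and written either as
# "mz intensity" pairs or "(mz intensity;)" groups. Intensities are
# rescaled to a 999 base peak on read and serialized at 4 significant
# digits on write.

.msp_known_keys <- c(
  name = "name", id = "id", formula = "formula",
  mw = "mw", molweight = "mw", molecularweight = "mw",
  retentionindex = "ri", ri = "ri",
  risource = "ri_source",
  dbs = "cui", cui = "cui",
  freepolarh = "has_free_polar_H",
  hastms = "has_tms",
  numpeaks = "num_peaks")

.msp_parse_bool <- function(x) {
  tolower(trimws(x)) %in% c("1", "true", "yes", "t", "y")
}

#' Read spectra from a NIST MSP text file
#'
#' Parses an MSP library into [library_entry()] objects. Records start at a
#' `Name:` header and must declare `Num Peaks:`; peak lists may be wrapped
#' and may use either `mz intensity` or `(mz intensity;)` punctuation.
#' Unrecognized header fields are preserved verbatim in each entry's
#' `extra` map, so `read_msp(write_msp(...))` is the identity. Intensities
#' are normalized so the base peak is 999. Records lacking a `DBs`/`CUI`
#' field default to the neutral `CUI = 1` (a message reports how many).
#'
#' @param path path to an MSP text file.
#' @return A list of [library_entry()] objects.
#' @examples
#' tf <- tempfile(fileext = ".msp")
#' writeLines(c("Name: demo", "MW: 128", "Num Peaks: 2",
#'              "51 200; 128 999;"), tf)
#' read_msp(tf)
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  entries <- list()
  i <- 1L
  n_default_cui <- 0L
  is_name_line <- function(ln) grepl("^\\s*name\\s*:", ln, ignore.case = TRUE)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!is_name_line(lines[i]))
      stop("line ", i, ": expected a 'Name:' header, got: ", lines[i])
    rec_line <- i
    fields <- list()       # canonical key -> value (first match wins)
    extra <- list()        # pass-through headers, original key casing
    num_peaks <- NA_integer_
    rec_name <- sub("^[^:]*:\\s*", "", lines[i])
    while (i <= n) {
      ln <- lines[i]
      if (!nzchar(trimws(ln))) {
        stop("record '", rec_name, "' starting at line ", rec_line,
             ": missing 'Num Peaks' header")
      }
      if (i > rec_line && is_name_line(ln))
        stop("record '", rec_name, "' starting at line ", rec_line,
             ": missing 'Num Peaks' header")
      if (!grepl(":", ln, fixed = TRUE))
        stop("record '", rec_name, "', line ", i,
             ": expected 'Key: value' header, got: ", ln)
      key_raw <- trimws(sub(":.*$", "", ln))
      val <- trimws(sub("^[^:]*:\\s*", "", ln))
      key_norm <- gsub("[ _-]", "", tolower(key_raw))
      canon <- .msp_known_keys[key_norm]
      if (is.na(canon)) {
        extra[[key_raw]] <- val
      } else if (canon == "num_peaks") {
        num_peaks <- suppressWarnings(as.integer(val))
        if (is.na(num_peaks) || num_peaks < 0L)
          stop("record '", rec_name, "', line ", i,
               ": invalid 'Num Peaks' value: ", val)
        i <- i + 1L
        break
      } else if (is.null(fields[[canon]])) {
        fields[[canon]] <- val
      } # later synonyms ignored: first match wins
      i <- i + 1L
    }
    if (is.na(num_peaks))
      stop("record '", rec_name, "' starting at line ", rec_line,
           ": missing 'Num Peaks' header")
    # collect 2 * num_peaks numeric tokens from subsequent lines
    vals <- numeric(0)
    while (length(vals) < 2L * num_peaks) {
      if (i > n || is_name_line(lines[i]))
        stop("record '", rec_name, "' starting at line ", rec_line,
             ": peak count mismatch (expected ", num_peaks, " peaks, got ",
             floor(length(vals) / 2), ")")
      toks <- regmatches(lines[i],
        gregexpr("[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?", lines[i]))[[1]]
      vals <- c(vals, as.numeric(toks))
      i <- i + 1L
    }
    if (length(vals) != 2L * num_peaks)
      stop("record '", rec_name, "' starting at line ", rec_line,
           ": peak count mismatch (expected ", num_peaks,
           " peaks, found extra values on the final peak line)")
    mz <- vals[seq(1L, length(vals), by = 2L)]
    intensity <- vals[seq(2L, length(vals), by = 2L)]
    if (num_peaks == 0L)
      stop("record '", rec_name, "' starting at line ", rec_line,
           ": record has no peaks")
    s <- spectrum(mz, intensity,
                  id = fields$id %||% rec_name,
                  ri = if (!is.null(fields$ri)) as.numeric(fields$ri),
                  mw = if (!is.null(fields$mw)) as.numeric(fields$mw),
                  name = fields$name %||% rec_name)
    s <- normalize_base_peak(s)
    s$peaks$intensity <- signif(s$peaks$intensity, 4)
    if (is.null(fields$cui)) n_default_cui <- n_default_cui + 1L
    ri_source <-
      if (is.null(s$ri)) "absent"
      else if (!is.null(fields$ri_source)) fields$ri_source
      else "experimental"
    entries[[length(entries) + 1L]] <- library_entry(
      s, compound_name = fields$name %||% rec_name,
      formula = fields$formula,
      cui = if (is.null(fields$cui)) 1L else as.integer(fields$cui),
      ri_source = ri_source,
      has_free_polar_H = !is.null(fields$has_free_polar_H) &&
        .msp_parse_bool(fields$has_free_polar_H),
      has_tms = !is.null(fields$has_tms) && .msp_parse_bool(fields$has_tms),
      extra = extra)
  }
  if (n_default_cui > 0L)
    message(n_default_cui, " record(s) lacked a DBs/CUI field; ",
            "defaulted to the neutral CUI = 1")
  entries
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write library entries to a NIST MSP text file
#'
#' Serializes entries in the dialect read back by [read_msp()]: `Name`,
#' `ID`, `Formula`, `MW`, `Retention_index`, `RI_source`, `DBs` (the CUI),
#' `Free_Polar_H`, `Has_TMS`, any pass-through headers, then `Num Peaks`
#' and wrapped `mz intensity;` pairs. Intensities are written at 4
#' significant digits.
#'
#' @param entries list of [library_entry()] (or [spectrum()]) objects.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_msp <- function(entries, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (e in entries) {
    if (inherits(e, "spectrum")) e <- library_entry(e)
    s <- e$spectrum
    out <- c(paste0("Name: ", e$compound_name))
    if (!is.null(s$id)) out <- c(out, paste0("ID: ", s$id))
    if (!is.null(e$formula)) out <- c(out, paste0("Formula: ", e$formula))
    if (!is.null(s$mw)) out <- c(out, paste0("MW: ", format(s$mw)))
    if (!is.null(s$ri)) {
      out <- c(out, paste0("Retention_index: ", format(s$ri)),
               paste0("RI_source: ", e$ri_source))
    }
    out <- c(out, paste0("DBs: ", e$cui),
             paste0("Free_Polar_H: ", as.integer(e$has_free_polar_H)),
             paste0("Has_TMS: ", as.integer(e$has_tms)))
    for (k in names(e$extra)) out <- c(out, paste0(k, ": ", e$extra[[k]]))
    out <- c(out, paste0("Num Peaks: ", nrow(s$peaks)))
    pairs <- sprintf("%d %s;", s$peaks$mz,
                     format(signif(s$peaks$intensity, 4), trim = TRUE,
                            scientific = FALSE))
    idx <- split(pairs, ceiling(seq_along(pairs) / 5))
    out <- c(out, vapply(idx, paste, "", collapse = " "), "")
    writeLines(out, con)
  }
  invisible(path)
}

#' Write a hit list as tab-separated text
#'
#' Writes the hit-list data frame produced by [search_library()] with a
#' fixed, documented column order. Score columns (`mf_identity`,
#' `mf_reverse`, `mf1`, `final`) are serialized as integers under the
#' truncation (floor) convention; other numeric columns keep full
#' precision.
#'
#' @param records a hit-list data.frame (class `hitlist`), or any
#'   data.frame sharing one column schema.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_hitlist_tsv <- function(records, path) {
  df <- as.data.frame(records)
  trunc_cols <- intersect(
    c("mf_identity", "mf_reverse", "mf1", "final"), names(df))
  for (cl in trunc_cols) df[[cl]] <- .truncate_score(df[[cl]])
  canonical <- c("query_id", "rank", "name", "formula", "mw", "cui",
                 "lib_ri", "dri", "mf_identity", "mf_reverse", "mf1",
                 "probability", "corr_p", "corr_cui", "corr", "mf_corr",
                 "final", "delta_mass", "methylene", "in_top_group",
                 "group_probability")
  ord <- c(intersect(canonical, names(df)), setdiff(names(df), canonical))
  utils::write.table(df[, ord, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

# floor() for score reporting; keeps NA
.truncate_score <- function(x) ifelse(is.na(x), NA_real_, floor(x))
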