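# Identity / Reverse / Similarity / Hybrid match factors.
#
# All match factors are 999 * a modified cosine between weighted peak
# vectors. Identity weighting uses sqrt(intensity) components carrying a
# mass factor m, so a matched-pair score contribution scales with m^2;
# the Similarity and Hybrid searches drop the mass factor. Peak matching
# is exact on integer m/z (nominal-mass EI data). Scores are real-valued
# here; reporting truncates (floors) to integer.

#' Peak-weighting scheme for match factors
#'
#' @param intensity_exponent exponent applied to peak intensities
#'   (default 0.5).
#' @param mass_exponent exponent applied to the m/z value of each
#'   component. The Identity default of 1 on sqrt-intensity components
#'   makes paired-peak score contributions scale with the square of the
#'   mass; Similarity and Hybrid use 0.
#' @return A list of class `weighting_scheme`.
#' @export
weighting_scheme <- function(intensity_exponent = 0.5, mass_exponent = 1) {
  stopifnot(intensity_exponent >= 0, mass_exponent >= 0)
  structure(list(intensity_exponent = intensity_exponent,
                 mass_exponent = mass_exponent),
            class = "weighting_scheme")
}

#' Weighted sparse peak vector
#'
#' Each component is `intensity^intensity_exponent * mz^mass_exponent`.
#'
#' @param s a [spectrum()].
#' @param w a [weighting_scheme()].
#' @return A data.frame with columns `mz` and `weight`.
#' @export
weighted_vector <- function(s, w = weighting_scheme()) {
  stopifnot(inherits(s, "spectrum"))
  data.frame(mz = s$peaks$mz,
             weight = s$peaks$intensity ^ w$intensity_exponent *
               as.numeric(s$peaks$mz) ^ w$mass_exponent)
}

.cosine_999 <- function(vq, vl) {
  m <- match(vq$mz, vl$mz)
  num <- sum(vq$weight * vl$weight[m], na.rm = TRUE)
  999 * num / sqrt(sum(vq$weight^2) * sum(vl$weight^2))
}

#' Identity match factor
#'
#' The standard mass-weighted cosine match factor on the 0--999 scale,
#' symmetric in its arguments. Self-match scores 999; spectra with
#' disjoint m/z sets score 0. The returned value is real; truncate with
#' `floor()` for reporting.
#'
#' @param q,l normalized [spectrum()] objects (query and library).
#' @param w a [weighting_scheme()]; the default is the Identity weighting.
#' @return Score in `[0, 999]`.
#' @export
identity_match_factor <- function(q, l, w = weighting_scheme()) {
  stopifnot(inherits(q, "spectrum"), inherits(l, "spectrum"))
  if (nrow(q$peaks) == 0L || nrow(l$peaks) == 0L)
    stop("cannot match an empty spectrum")
  .cosine_999(weighted_vector(q, w), weighted_vector(l, w))
}

#' Reverse (identity) match factor
#'
#' The Identity match factor computed after deleting from the query every
#' peak whose mass is absent from the library spectrum. Query-side
#' contaminant peaks are thereby discarded, so
#' `reverse_match_factor(q, l) >= identity_match_factor(q, l)` always.
#'
#' @inheritParams identity_match_factor
#' @return Score in `[0, 999]`; 0 when the spectra share no masses.
#' @export
reverse_match_factor <- function(q, l, w = weighting_scheme()) {
  stopifnot(inherits(q, "spectrum"), inherits(l, "spectrum"))
  keep <- q$peaks$mz %in% l$peaks$mz
  if (!any(keep)) return(0)
  q2 <- q
  q2$peaks <- q$peaks[keep, , drop = FALSE]
  identity_match_factor(q2, l, w)
}

#' Similarity match factor
#'
#' The unweighted-mass cosine match factor (mass exponent 0), used for
#' related-compound retrieval. Because high-mass peaks are not up-weighted,
#' high-mass contamination is penalized less than in the Identity search.
#'
#' @inheritParams identity_match_factor
#' @param intensity_exponent intensity exponent (default 0.5).
#' @return Score in `[0, 999]`.
#' @export
similarity_match_factor <- function(q, l, intensity_exponent = 0.5) {
  identity_match_factor(
    q, l, weighting_scheme(intensity_exponent, mass_exponent = 0))
}

#' Hybrid (neutral-loss) match factor
#'
#' Augments the Similarity search with neutral-loss matching: library
#' peaks may additionally match query peaks after shifting by
#' `DeltaMass = qM - lM`, the molecular-mass difference between query and
#' library compound. Each library and query peak is used at most once;
#' the direct/shifted assignment is chosen to maximize the unweighted
#' cosine. With `DeltaMass = 0` no peak shifting occurs and the score
#' equals [similarity_match_factor()]. Shifted positions at mass <= 0 are
#' dropped.
#'
#' Because every peak has at most two candidate partners (direct and
#' shifted), the assignment conflict graph consists of simple paths and
#' cycles; the maximum-weight matching is found exactly by dynamic
#' programming.
#'
#' @param q,l normalized [spectrum()] objects.
#' @param qM,lM nominal molecular masses in Da; defaults are taken from
#'   the spectra. If the query mass is unknown, estimate it first with
#'   [estimate_molecular_mass()].
#' @param intensity_exponent intensity exponent (default 0.5).
#' @return A list of class `hybrid_result`: `score` in `[0, 999]`,
#'   `delta_mass` in Da, and `matched_pairs`, a data.frame with columns
#'   `query_mz`, `lib_mz`, `shifted`.
#' @export
hybrid_match_factor <- function(q, l, qM = q$mw, lM = l$mw,
                                intensity_exponent = 0.5) {
  stopifnot(inherits(q, "spectrum"), inherits(l, "spectrum"))
  if (is.null(qM) || is.na(qM))
    stop("query molecular mass is unknown; ",
         "estimate it with estimate_molecular_mass()")
  if (is.null(lM) || is.na(lM))
    stop("library molecular mass is unknown")
  if (nrow(q$peaks) == 0L || nrow(l$peaks) == 0L)
    stop("cannot match an empty spectrum")
  delta <- as.numeric(qM) - as.numeric(lM)
  wq <- q$peaks$intensity ^ intensity_exponent
  wl <- l$peaks$intensity ^ intensity_exponent
  norm <- sqrt(sum(wq^2) * sum(wl^2))

  # candidate edges: library peak j -> query peak k, direct or shifted
  lj <- integer(0); qk <- integer(0); sh <- logical(0)
  dm <- match(l$peaks$mz, q$peaks$mz)
  ok <- !is.na(dm)
  lj <- which(ok); qk <- dm[ok]; sh <- rep(FALSE, sum(ok))
  if (delta != 0) {
    tgt <- l$peaks$mz + delta
    sm <- match(tgt, q$peaks$mz)
    ok2 <- !is.na(sm) & tgt >= 1
    lj <- c(lj, which(ok2)); qk <- c(qk, sm[ok2])
    sh <- c(sh, rep(TRUE, sum(ok2)))
  }
  if (length(lj) == 0L)
    return(structure(list(score = 0, delta_mass = delta,
                          matched_pairs = data.frame(
                            query_mz = integer(0), lib_mz = integer(0),
                            shifted = logical(0))),
                     class = "hybrid_result"))
  wts <- wl[lj] * wq[qk]
  sel <- .mwm_degree2(paste0("L", lj), paste0("Q", qk), wts)
  pairs <- data.frame(query_mz = q$peaks$mz[qk[sel]],
                      lib_mz = l$peaks$mz[lj[sel]],
                      shifted = sh[sel])
  structure(list(score = 999 * sum(wts[sel]) / norm,
                 delta_mass = delta,
                 matched_pairs = pairs[order(pairs$query_mz), ,
                                       drop = FALSE]),
            class = "hybrid_result")
}

#' @export
print.hybrid_result <- function(x, ...) {
  cat(sprintf("<hybrid_result> score %.1f, DeltaMass %+g Da, %d pairs (%d shifted)\n",
              x$score, x$delta_mass, nrow(x$matched_pairs),
              sum(x$matched_pairs$shifted)))
  invisible(x)
}

# Exact maximum-weight matching on a graph of maximum degree 2.
# from/to are node labels (disjoint spaces), w positive edge weights.
# Returns indices of selected edges. Components of a degree-<=2 graph are
# paths or cycles; path components use the classic take/skip DP, cycle
# components split on exclusion of one of the two edges at the start node.
.mwm_degree2 <- function(from, to, w) {
  ne <- length(w)
  inc <- split(rep(seq_len(ne), 2L), c(from, to))  # node -> incident edges
  seen <- logical(ne)
  selected <- integer(0)

  path_dp <- function(ws) {
    k <- length(ws)
    if (k == 0L) return(integer(0))
    take <- numeric(k); skip <- numeric(k)
    take[1L] <- ws[1L]
    if (k > 1L) for (i in 2:k) {
      take[i] <- skip[i - 1L] + ws[i]
      skip[i] <- max(take[i - 1L], skip[i - 1L])
    }
    sel <- integer(0); i <- k
    while (i >= 1L) {
      if (take[i] >= skip[i]) { sel <- c(sel, i); i <- i - 2L }
      else i <- i - 1L
    }
    sel
  }
  dp_total <- function(ws, sel) sum(ws[sel])

  for (start in seq_len(ne)) {
    if (seen[start]) next
    # gather the component's edges
    comp <- integer(0); frontier <- start
    seen[start] <- TRUE
    while (length(frontier)) {
      e <- frontier[[1L]]; frontier <- frontier[-1L]
      comp <- c(comp, e)
      nbr <- setdiff(c(inc[[from[e]]], inc[[to[e]]]), comp)
      nbr <- nbr[!seen[nbr]]
      seen[nbr] <- TRUE
      frontier <- c(frontier, nbr)
    }
    if (length(comp) == 1L) { selected <- c(selected, comp); next }
    # order edges along the path/cycle
    comp_nodes <- unique(c(from[comp], to[comp]))
    degs <- vapply(comp_nodes,
                   function(nd) sum(inc[[nd]] %in% comp), integer(1))
    endpoints <- comp_nodes[degs == 1L]
    is_cycle <- length(endpoints) == 0L
    node <- if (is_cycle) from[comp[1L]] else endpoints[1L]
    path <- integer(0)
    repeat {
      cand <- setdiff(intersect(inc[[node]], comp), path)
      if (!length(cand)) break
      e <- cand[1L]
      path <- c(path, e)
      node <- if (from[e] == node) to[e] else from[e]
    }
    ws <- w[path]
    if (is_cycle) {
      k <- length(path)
      s1 <- path_dp(ws[-k])                 # exclude last edge
      s2 <- path_dp(ws[-1L]) + 1L           # exclude first edge
      sel_local <- if (dp_total(ws, s1) >= dp_total(ws, s2)) s1 else s2
    } else {
      sel_local <- path_dp(ws)
    }
    selected <- c(selected, path[sel_local])
  }
  selected
}
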