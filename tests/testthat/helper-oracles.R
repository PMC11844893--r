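# Shared fixtures and independent brute-force oracles.

# random normalized spectrum with n peaks in [lo, hi]
random_spectrum <- function(n, lo = 50L, hi = 450L, id = NULL, mw = NULL,
                            ri = NULL) {
  mz <- sample(lo:hi, n)
  normalize_base_peak(spectrum(mz, stats::runif(n, 1, 999), id = id,
                               mw = mw, ri = ri))
}

# brute-force weighted cosine over the union of masses, independent of the
# package's sparse-vector path
oracle_match_factor <- function(q, l, int_exp = 0.5, mass_exp = 1) {
  mzs <- sort(union(q$peaks$mz, l$peaks$mz))
  comp <- function(s, m) {
    i <- match(m, s$peaks$mz)
    if (is.na(i)) 0 else s$peaks$intensity[i]^int_exp * m^mass_exp
  }
  vq <- vapply(mzs, function(m) comp(q, m), 0)
  vl <- vapply(mzs, function(m) comp(l, m), 0)
  999 * sum(vq * vl) / sqrt(sum(vq^2) * sum(vl^2))
}

oracle_reverse <- function(q, l, int_exp = 0.5, mass_exp = 1) {
  keep <- q$peaks$mz %in% l$peaks$mz
  if (!any(keep)) return(0)
  q2 <- spectrum(q$peaks$mz[keep], q$peaks$intensity[keep])
  oracle_match_factor(q2, l, int_exp, mass_exp)
}

# exhaustive hybrid assignment: each library peak is assigned to nothing,
# its direct query partner, or its shifted partner; query peaks used at
# most once; maximize the summed sqrt-intensity products
oracle_hybrid <- function(q, l, delta, int_exp = 0.5) {
  wq <- q$peaks$intensity^int_exp
  wl <- l$peaks$intensity^int_exp
  norm <- sqrt(sum(wq^2) * sum(wl^2))
  nl <- nrow(l$peaks)
  best <- 0
  recurse <- function(j, used_q, total) {
    if (j > nl) {
      best <<- max(best, total)
      return(invisible(NULL))
    }
    recurse(j + 1L, used_q, total) # skip
    kd <- match(l$peaks$mz[j], q$peaks$mz)
    if (!is.na(kd) && !used_q[kd]) {
      u <- used_q; u[kd] <- TRUE
      recurse(j + 1L, u, total + wl[j] * wq[kd])
    }
    if (delta != 0) {
      tgt <- l$peaks$mz[j] + delta
      ks <- match(tgt, q$peaks$mz)
      if (!is.na(ks) && tgt >= 1 && !used_q[ks]) {
        u <- used_q; u[ks] <- TRUE
        recurse(j + 1L, u, total + wl[j] * wq[ks])
      }
    }
  }
  recurse(1L, logical(nrow(q$peaks)), 0)
  999 * best / norm
}

# brute-force sorted-middle median of intensities as % of base peak
oracle_median_rel <- function(s) {
  v <- sort(s$peaks$intensity)
  n <- length(v)
  mid <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  100 * mid / max(v)
}
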