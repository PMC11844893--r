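test_that("weighted vectors apply the intensity and mass exponents", {
  s <- normalize_base_peak(spectrum(c(50, 100), c(250, 999)))
  raw <- weighted_vector(s, weighting_scheme(1, 0))
  expect_equal(raw$weight, s$peaks$intensity)
  w <- weighted_vector(s, weighting_scheme(0.5, 1))
  expect_equal(w$weight, sqrt(s$peaks$intensity) * c(50, 100))
})

test_that("identity match factor: self-match 999, disjoint 0, symmetric, scale-invariant", {
  set.seed(21)
  for (i in 1:20) {
    q <- random_spectrum(sample(3:10, 1))
    l <- random_spectrum(sample(3:10, 1))
    expect_equal(identity_match_factor(q, q), 999)
    m1 <- identity_match_factor(q, l)
    expect_equal(m1, identity_match_factor(l, q))
    expect_gte(m1, 0); expect_lte(m1, 999)
    q2 <- q; q2$peaks$intensity <- q$peaks$intensity * 17.3
    expect_equal(identity_match_factor(q2, l), m1)
  }
  a <- spectrum(c(50, 60), c(999, 100))
  b <- spectrum(c(51, 61), c(999, 100))
  expect_equal(identity_match_factor(a, b), 0)
})

test_that("identity/similarity/reverse equal the brute-force oracle on 1000 random pairs", {
  set.seed(1234)
  for (i in 1:1000) {
    q <- random_spectrum(sample(2:10, 1), lo = 50, hi = 150)
    l <- random_spectrum(sample(2:10, 1), lo = 50, hi = 150)
    expect_equal(identity_match_factor(q, l),
                 oracle_match_factor(q, l, 0.5, 1), tolerance = 1e-12)
    expect_equal(similarity_match_factor(q, l),
                 oracle_match_factor(q, l, 0.5, 0), tolerance = 1e-12)
    expect_equal(reverse_match_factor(q, l),
                 oracle_reverse(q, l, 0.5, 1), tolerance = 1e-12)
  }
})

test_that("reverse search discards query-only contaminants and never scores below identity", {
  set.seed(99)
  l <- random_spectrum(8)
  q <- l
  extra <- setdiff(460:500, l$peaks$mz)[1:5]
  q2 <- spectrum(c(l$peaks$mz, extra), c(l$peaks$intensity,
                                         runif(5, 50, 400)))
  expect_equal(reverse_match_factor(q2, l), 999)
  expect_lt(identity_match_factor(q2, l), 999)
  expect_equal(reverse_match_factor(l, l), identity_match_factor(l, l))
  for (i in 1:100) {
    a <- random_spectrum(sample(2:10, 1), lo = 50, hi = 120)
    b <- random_spectrum(sample(2:10, 1), lo = 50, hi = 120)
    expect_gte(reverse_match_factor(a, b) + 1e-9,
               identity_match_factor(a, b))
  }
})

test_that("mass weighting penalizes high-mass contamination more than similarity", {
  set.seed(31)
  for (i in 1:20) {
    l <- random_spectrum(8, lo = 50, hi = 200)
    cont_mz <- setdiff(400:450, l$peaks$mz)[1:3]
    q <- spectrum(c(l$peaks$mz, cont_mz),
                  c(l$peaks$intensity, runif(3, 100, 500)))
    id_drop <- 999 - identity_match_factor(q, l)
    sim_drop <- 999 - similarity_match_factor(q, l)
    expect_lt(sim_drop, id_drop)
  }
})

test_that("hybrid matching equals the exhaustive assignment oracle on small instances", {
  set.seed(777)
  for (i in 1:400) {
    nq <- sample(2:6, 1); nl <- sample(2:6, 1)
    q <- random_spectrum(nq, lo = 50, hi = 90, mw = sample(80:120, 1))
    l <- random_spectrum(nl, lo = 50, hi = 90, mw = sample(80:120, 1))
    h <- hybrid_match_factor(q, l)
    expect_equal(h$score, oracle_hybrid(q, l, q$mw - l$mw),
                 tolerance = 1e-12, info = paste("instance", i))
    # matched pairs respect the shift relation and single-use constraints
    mp <- h$matched_pairs
    if (nrow(mp)) {
      expect_true(all(mp$query_mz[mp$shifted] - mp$lib_mz[mp$shifted] ==
                        h$delta_mass))
      expect_true(all(mp$query_mz[!mp$shifted] == mp$lib_mz[!mp$shifted]))
      expect_false(anyDuplicated(mp$query_mz) > 0)
      expect_false(anyDuplicated(mp$lib_mz) > 0)
    }
  }
})

test_that("hybrid with DeltaMass 0 reduces to the similarity score", {
  set.seed(4321)
  for (i in 1:1000) {
    q <- random_spectrum(sample(2:8, 1), lo = 50, hi = 150, mw = 200)
    l <- random_spectrum(sample(2:8, 1), lo = 50, hi = 150, mw = 200)
    expect_equal(hybrid_match_factor(q, l)$score,
                 similarity_match_factor(q, l), tolerance = 1e-12)
  }
})

test_that("a pure methylene-shifted homolog recovers a full hybrid match", {
  set.seed(55)
  l <- random_spectrum(8, lo = 60, hi = 250, mw = 280)
  q <- spectrum(l$peaks$mz - 14L, l$peaks$intensity, mw = 280 - 14)
  h <- hybrid_match_factor(q, l)
  expect_equal(h$score, 999)
  expect_equal(h$delta_mass, -14)
  expect_true(all(h$matched_pairs$shifted))
})

test_that("hybrid never scores below similarity and requires molecular masses", {
  set.seed(65)
  for (i in 1:100) {
    q <- random_spectrum(sample(2:8, 1), lo = 50, hi = 120,
                         mw = sample(100:160, 1))
    l <- random_spectrum(sample(2:8, 1), lo = 50, hi = 120,
                         mw = sample(100:160, 1))
    expect_gte(hybrid_match_factor(q, l)$score + 1e-9,
               similarity_match_factor(q, l))
  }
  q <- random_spectrum(4)
  l <- random_spectrum(4, mw = 150)
  expect_error(hybrid_match_factor(q, l), "estimate_molecular_mass")
})
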