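---
title: "Scoring model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specid)
```

## The problem

Nontargeted GC-EI-MS analysis of complex mixtures matches each observed
70 eV fragmentation spectrum against a reference library and reports a
hit list sorted by a spectral match factor on the 0–999 scale. In
practice the match factor alone is an unreliable identification
criterion: spectra of isomers can be nearly identical, low-abundance
analytes accumulate contaminant peaks that depress scores, and a
high-scoring library compound may be chemically implausible for the
sample. `specid` implements a set of library-derived corrections that
move the hit-list score from "spectral similarity" toward
"identification confidence", together with the spectrum cleanup,
retention-index handling and triage metrics that support them.

## Match factors

All match factors are `999 · cos(θ)` between weighted peak vectors with
exact matching on integer m/z (nominal-mass EI data; no tolerance
window). A peak at mass *m* with relative intensity *I* contributes a
component `I^a · m^b`:

* **Identity search** uses `a = 0.5`, `b = 1`, so a matched pair
  contributes `√(I_q I_l) · m²` — high-mass peaks are weighted by the
  square of the mass. These are the defaults of `weighting_scheme()`;
  the exact exponent pair used by library-search software is not
  published as part of the method reimplemented here, so the scheme is
  configurable and the m² pair-contribution property is what the
  default preserves.
* **Similarity search** drops the mass factor (`b = 0`), which makes it
  much less sensitive to high-mass contamination.
* **Reverse identity search** deletes from the query every peak whose
  mass is absent from the candidate library spectrum before computing
  the Identity cosine. Removing query-only vector components can only
  shrink the query norm, so the Reverse score is never below the
  Identity score; the difference grows with contamination.
* **Hybrid similarity search** additionally lets each library peak
  match at its mass shifted by `DeltaMass = M_query − M_library`,
  capturing conserved neutral losses in homologous compounds. Each
  query and library peak may be used at most once and the
  direct/shifted assignment maximizes the unweighted cosine. With
  `DeltaMass = 0` nothing shifts and the Hybrid score equals the
  Similarity score exactly.

Scores are kept real-valued internally; every reported score is
truncated (floored) to an integer. This truncation convention is what
makes the worked composite examples below come out exactly.

### Hybrid assignment

Each library peak has at most two candidate partners (its direct mass
and its shifted mass) and, symmetrically, each query peak can be the
direct partner of one library peak and the shifted partner of another.
The assignment conflict graph therefore has maximum degree 2 — a
disjoint union of simple paths and cycles — and the maximum-weight
matching is computed *exactly* by a take/skip dynamic program on each
path (cycles are split on one of the two edges at an arbitrary node).
An exhaustive search over all direct/shifted assignments would also be
exact but exponential; a greedy pass on product magnitude would be fast
but can be suboptimal on alternating chains. The DP is both exact and
linear in the number of candidate pairs, and the test suite verifies it
against an exhaustive oracle on all generated instances with ≤ 6 peaks
per side. Shifted positions at mass ≤ 0 are dropped.

## Retention-index penalization

Kovàts retention indices confirm or veto spectral matches. The penalty
is zero for `dRI ≤ threshold` and `penalty_rate · (dRI − threshold) /
threshold` beyond it; defaults are a threshold of 15 Kovàts units and a
rate of 50 score units per threshold-width, i.e. `50·(dRI − 15)/15`,
subtracted from the score and clamped at zero. When either RI is
missing no penalty is applied and the missing value is flagged —
reference libraries here may lack RI values, unlike the setting where
machine-estimated indices guarantee one for every entry.

Hybrid hits are not RI-penalized (a homolog legitimately elutes
elsewhere); instead each hit gets a methylene-consistency verdict: a
`DeltaMass` of `14n` Da predicts an RI shift of `100n` Kovàts units
(each CH₂ in a linear alkane contributes ~100), accepted within a
fractional tolerance of 0.30. The tolerance was chosen once to cover
observed homolog behavior (shifts of 115 for one CH₂ and 216 for two
are accepted) with margin; it is configurable as `ri_tolerance_frac`.

## Confidence corrections and the composite score

Two corrections convert non-spectral evidence into score units:

* **Probability.** Library-search software reports a hit "Probability"
  (uniqueness of the match given the hit-list score distribution).
  Median Probability of good identifications is about 75%, so values
  above it add `Kp · 999 · (P − 75)/25` score units and values at or
  below it add nothing. `Kp` defaults to 0.25; the published worked
  composite uses 0.2, so both are exercised in the tests and the factor
  is a configuration value.
* **Compound Ubiquity Index (CUI).** The number of 58 diverse chemical
  collections citing the compound, a prior-likelihood proxy. The
  correction is `Kc · (CUI − 1)` for `CUI ≥ 1` and an active penalty of
  `−10·Kc` for `CUI = 0`, with `Kc = 2` by default.

Corrections are truncated to integers before being summed into `Corr`,
which is required to reproduce the printed arithmetic (135 + 84). The
composite score then adjusts the base score `MF1` (by default the mean
of the RI-corrected Identity and Reverse scores) through a saturating
form that can never leave [0, 999]:

```
ΔMF     = 999 − MF1      if Corr > 0,   MF1 otherwise
MFcorr  = ΔMF · |Corr| / (ΔMF + |Corr|)
final   = MF1 ± MFcorr
```

The published description of this bounded correction appears only as a
figure whose formula is not rendered in the text available to us; the
form above was reconstructed under the constraint that it reproduce the
three printed worked outcomes (705.5 + 219 → 830, 865 + 50 → 901,
697 + 159 → 801), which simple addition does not. Three other printed
outcomes (a phenanthrene 822, a benzoic-acid-TMS 909, and a syringol
"+50 → 797") could not be reproduced from the stated inputs under any
convention we tried; they are treated as known discrepancies of the
source material and are not asserted anywhere.

`composite_score()` is strictly increasing in `Corr`, approaches 999
(or 0) only asymptotically, and reduces to `MF1` at `Corr = 0`.

### Group probability

When near-identical isomers share the top of a hit list their
individual Probabilities are small even though the *class* is certain.
The group is taken as the hits above the largest adjacent score gap
(searched over the top 10 by default — the published rule names "the
hit list" without a depth; exact score ties with the boundary are
included so that two tied top hits form a group), and the group
probability is the capped sum of member Probabilities.

### Surrogate probabilities

True Probabilities come from external search software. For end-to-end
runs without them, `surrogate_probability()` offers a clearly-labeled
softmax surrogate `exp(score/scale)`; the default scale `28/log(2)`
makes a 28-score-unit difference a factor of 2 in relative likelihood,
matching the published rate at which score differences translate into
likelihood ratios. It is off by default and is not a calibrated
probability model.

### Hit filtering

In trimethylsilylation workflows, library compounds retaining a free
hydroxy or amino group should be nearly absent from the derivatized
sample, yet long-chain alcohols in particular mimic alkene spectra and
retention. `filter_underivatized()` removes such entries (keeping any
entry with at least one TMS group) *before* hit-list construction. It
defaults to off because the package does not assume a derivatization
chemistry; enable it for TMS workflows.

## Spectrum cleanup and triage

* **PFMD removal.** Perfluoromethyldecalin, a common internal standard,
  shows characteristic peaks at 69, 131, 243 and 293 Da. The published
  procedure names the masses but not a trigger rule; we require *all
  four* masses at ≥ 1% of the base peak before deleting them
  (`pfmd_trigger_min_rel`), a conservative choice that avoids deleting
  genuine CF₃⁺ or other fragments when the full pattern is absent.
  Whether abundance thresholding should precede or follow PFMD removal
  is likewise unstated; the pipeline removes PFMD first and leaves
  thresholding to the analyst.
* **Molecular-mass estimation.** For TMS spectra (73 Da fragment at
  ≥ 10% of base — the fragment is characteristic but no published
  threshold exists, so 10% is this package's declared choice) the
  estimate seeks an [M]⁺/[M−15]⁺ pair where only the methyl-loss peak
  must clear the 5% floor and the molecular ion need merely be present.
  Otherwise the highest non-isotopic mass above 5% is used; a peak at
  *m* is flagged as an isotope when it is below 25% of the peak at
  *m − 1*, a bound that covers plausible ¹³C contributions for
  GC-amenable compounds (the published rule says only "nonisotopic").
* **Median relative abundance.** The median peak intensity as a percent
  of the base peak. Identifiable spectra have high dynamic range and
  low medians; spectra dominated by near-detection-limit contaminants
  have high medians. `triage()` uses a default cutoff of 1% (10 on the
  999 scale), between the population medians observed for identifiable
  (0.49%) and unidentifiable (1.73%) spectra.

## The synthetic fixture generator

`generate_library()` / `degrade_query()` emulate the statistical
structure the methods assume, not fragmentation physics:

* fragments drawn without replacement from 50–450 Da with log-uniform
  intensities (the dynamic-range premise behind the median-abundance
  metric); molecular masses 180–420 Da; retention indices roughly
  proportional to mass (≈ 7·M, as for a homologous series on a
  nonpolar column) with 60-unit scatter;
* ~60% TMS-like entries carrying the 73 Da marker plus an
  [M−15]⁺/[M]⁺ pair, so both molecular-mass rules are exercised;
* CH₂ homolog families (fraction 0.3, sizes 2–4) sharing a fragment
  pattern shifted by 14 Da per member — the 73 Da marker stays put —
  with masses offset by 14 Da and RIs by ~100 units;
* skewed CUIs (exponential, mean ≈ 6, capped at 58, including zeros);
* degraded queries receive contaminant peaks (15% of peaks by default,
  60% placed above the molecular ion) with relative intensities between
  the spectrum's median and 30% of base — near-detection-limit noise
  that provably never lowers the median, mirroring the contamination
  signature of unidentifiable spectra.

Because queries are jittered copies of library spectra, passing tests
show that the pipeline's ranking, corrections and triage behave as
designed under the assumed structure; they do not show robustness to
real-world deconvolution artifacts, co-elution, or library coverage
gaps, which the generator does not model.

The directional experiment in the test suite uses a 60-compound library
with 250 clean and 250 degraded queries — large enough for stable means
and rank-recovery estimates while keeping the default test run quick.

## Numerical conventions

* Intensities normalize to a 999 base peak and serialize at 4
  significant digits; MSP header synonyms are accepted
  case-insensitively with the first occurrence winning; missing CUI
  defaults to the neutral 1 (a `CUI = 0` penalty must be explicit).
* Reported scores truncate (floor); corrections truncate before
  summing; internal values stay real.
* Search ties break by higher Identity score, then smaller |dRI|
  (missing last), then compound name — the published method never
  specifies tie handling, and this chain makes runs deterministic.
* `ri_source` (experimental / AIRI / absent) is this package's own
  convention for marking RI provenance; entries read without a source
  tag but with an RI default to "experimental".
* Query renaming during annotation requires a truncated final score
  strictly greater than 750.
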