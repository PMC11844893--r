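# specid

Library-based compound identification scoring for GC-EI-MS.

Nontargeted GC-EI-MS studies identify compounds by matching 70 eV
fragmentation spectra against reference libraries, producing a hit list
sorted by a 0–999 match factor. The match factor alone is often not a
sufficient identification criterion: isomers share spectra, contaminant
peaks depress scores for low-abundance analytes, and a high-scoring
library compound may be chemically implausible in the sample. `specid`
implements the scoring stack that addresses this:

* **Match factors** — Identity (mass-weighted cosine: a matched pair at
  mass *m* contributes `√(I_q I_l)·m²`), Reverse (query-only
  contaminant peaks discarded), Similarity (no mass weighting) and
  Hybrid neutral-loss search, which also matches library peaks shifted
  by `DeltaMass = M_query − M_library` with an exact maximum-weight
  peak assignment.
* **Retention-index penalization** — scores are reduced by
  `50·(dRI − 15)/15` score units beyond a 15 Kovàts-unit threshold;
  hybrid hits instead get a CH₂ homolog consistency verdict
  (`DeltaMass = 14n` Da ⇔ `dRI ≈ 100n`).
* **Confidence corrections** — hit-list Probability above 75% adds
  `Kp·999·(P−75)/25`; the Compound Ubiquity Index adds `Kc·(CUI−1)`
  (penalty `−10·Kc` at CUI 0). Their integer-truncated sum `Corr`
  adjusts the base score `MF1` (mean of RI-corrected Identity and
  Reverse) through the bounded composite
  `final = MF1 ± ΔMF·|Corr|/(ΔMF+|Corr|)` with `ΔMF = 999−MF1` for
  positive and `MF1` for negative corrections.
* **Cleanup and triage** — base-peak normalization,
  perfluoromethyldecalin calibrant removal (69/131/243/293 Da),
  abundance thresholding, TMS-aware molecular-mass estimation
  ([M]⁺/[M−15]⁺ pair rule), and median-relative-abundance triage of
  spectra into likely/unlikely identifiable.
* **I/O** — NIST MSP text libraries in and out, tab-separated hit
  lists, a `specid` command-line tool, and a seeded synthetic fixture
  generator (homolog families, contaminated queries) so everything runs
  without external downloads.

## Worked example

The composite-score chain for a low-scoring fatty-acid TMS spectrum:
Identity 597 and Reverse 814 average to MF1 = 705.5; a Probability of
92% (Kp = 0.2) contributes 135 and a CUI of 43 (Kc = 2) contributes 84:

```r
library(specid)
mf1  <- combine_identity_reverse(597, 814)                        # 705.5
corr <- trunc(probability_correction(92, confidence_config(kp = 0.2))) +
        trunc(cui_correction(43, confidence_config(kc = 2)))      # 135 + 84
composite_score(mf1, corr)
#> <score_breakdown> MF1 705.5 +219 (dMF 293.5, MFcorr 125.4) -> 830
```

A score of 597 — far below a typical 800 acceptance threshold — becomes
a composite 830, indicative of a good identification.

End-to-end on synthetic data:

```r
fx <- generate_fixture_set(fixture_config(n_compounds = 30, seed = 7),
                           n_queries = 1)
search_library(fx$queries_degraded[[1]], fx$library,
               search_config(top_k = 5))
#> <hitlist> 5 hits for query 'QRY_0001'
#>  rank                       name mf1 corr final dri delta_mass group_probability
#>     1               Compound 021 955    2   957   2         NA                NA
#>     2               Compound 023   0   42    40  62         NA                NA
#>     3 Homolog family 3 member C2   0   18    17 742         NA                NA
#>     ...
```

The true source compound ranks first at 957 despite 15% contaminant
peaks; the runners-up are RI-penalized to the floor. Columns carry the
full audit trail (Identity/Reverse scores, dRI, corrections, ΔMF,
MFcorr).

From the shell:

```sh
specid fixtures --out fx --seed 9
specid search -q fx/queries_degraded.msp -l fx/library.msp -o hits.tsv \
       --kp 0.25 --kc 2
specid triage -q fx/queries_degraded.msp --cutoff 1.0
```

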