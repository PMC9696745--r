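---
title: "Distribution-guided LOINC mapping: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-guided LOINC mapping: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`loincmap` treats a lab test as the distribution of its observed numeric
values. If a local code and a reference LOINC code denote the same
analyte measured comparably, their empirical cumulative distribution
functions (eCDFs) should nearly coincide; if not, they should differ. The
pipeline is:

1. **Sampling.** Up to `sample_size` readings per code (default 1000) are
   drawn uniformly *without replacement*. Without-replacement is the
   natural reading of "randomly drawn from the stored data": it
   represents the stored empirical distribution rather than a bootstrap
   of it. Codes with fewer observations contribute everything they have,
   with a warning — the method degrades gracefully rather than silently
   excluding codes, but users should know that very small codes carry
   more sampling noise.
2. **Distance.** The two-sample Kolmogorov–Smirnov statistic
   $\sup_x |F_a(x) - F_b(x)|$ between each query eCDF and each reference
   eCDF fills an $N \times K$ matrix $D$. The KS statistic is used as a
   pure distance; no p-value is attached (the null "same distribution" is
   not what is being tested — we want the *nearest* distribution).
3. **Assignment and acceptance.** Each query code maps to its argmin
   column. Row $i$ of $D$ is standardized to z-scores; the mapping is
   accepted iff the z-score at the argmin is strictly below a cutoff
   (default $-5$). The intuition: when the true LOINC is present, the
   minimum distance is a pronounced outlier within its row; when it is
   absent, the minimum is just the left tail of the wrong-code distance
   distribution.

Assumptions worth stating explicitly: codes are distinguishable by value
distribution (two analytes with identical distributions cannot be told
apart by any distribution-based method); query and reference sites
measure on the same scale and unit (unit-of-measure consistency is *not*
checked — see Limitations); and the reference vocabulary is large
relative to the query list, which the z-score needs (below).

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `sample_size` | 1000 | readings/code | enough that the two-sample KS noise (≈ 1.36·√(2/n) ≈ 0.06 at the 5% level) is well below typical between-analyte distances |
| `cutoff` | −5 | z-score | the headline operating point for accepting a mapping |
| `z_cutoff` (ensemble) | −3.80 | z-score | the confidence gate at which the distribution-based candidate overrides an external text-based candidate |
| `sd_divisor` | `n_minus_1` | — | sample standard deviation, the default of mainstream statistical environments; the population variant (`n`) is a flag for reproducing that convention |
| `master_seed` | 0 | — | every sampling step derives a per-code sub-seed from `(master_seed, stream, code_id)`, so adding or removing a code never perturbs other codes' samples |

Both cutoffs are operating points, not constants of nature: they were
originally chosen on one dataset pair and should be re-examined on any
new reference panel (sweep them with `run_repeated_evaluation()`).

## Numerical choices

- **Exact KS scan.** The supremum of the difference of two step
  functions is attained at a support point, so scanning the sorted union
  of the two supports computes the statistic exactly — including tied
  values across samples, common for integer-valued analytes. The test
  suite pins this against both a dense-grid brute force and
  `stats::ks.test` on the raw samples at `1e-12`.
- **Strict inequality.** Acceptance is `z < cutoff`, never `<=`.
- **Argmin ties** break toward the lexicographically smallest LOINC code
  (deterministic, input-order independent) and are counted in a message.
- **Degenerate rows** (every reference equally distant) are unmappable:
  the record is emitted with `z_score = NA` and `accepted = FALSE`
  rather than crashing, and a single-column reference (`K < 2`) is a
  hard error because a z-score over one candidate is meaningless.
- **Serialization.** Reference eCDF panels are written with 17
  significant digits and re-parsed with base R's `strtod`, so a panel
  survives a write/read cycle bit-for-bit. (Sharing eCDF panels instead
  of raw values is the privacy-preserving deployment mode: no
  patient-level observation leaves the reference site.)
- **Precision with zero accepted mappings** is reported as `NA`, never 0
  or 1; averaged curves and plots skip undefined points.

## What the synthetic generator emulates — and what it does not

`generate_scenario()` draws per-code values from parametric families
chosen to mimic common analyte shapes: normal (electrolytes), lognormal
(enzymes), gamma (skewed counts), uniform, and Poisson ("discrete",
integer-valued — this family deliberately exercises the tie-handling
path of the KS scan). Query observations are perturbed by a mild
cross-site shift, additive on location and multiplicative on spread
*around the family mean* (a calibration-slope shift applied to raw
magnitudes would dislocate far-from-zero analytes by many sd). The
default shift — 3% of the reference sd on location, 2% on scale — models
assay differences without breaking identifiability.

Two design points deserve their own paragraphs.

**The reference panel must dwarf the query list.** With one clear
minimum among $K$ row entries, the most extreme achievable z-score is
about $-\sqrt{K}$; with $K \approx 20$ a $-5$ cutoff is unreachable by
arithmetic alone, while real deployments compare dozens of local codes
against hundreds of reference LOINCs. The packaged scenarios therefore
include reference-only "distractor" codes (`n_query = 0` specs), and
`scenario_partial_reference()` uses 30 query codes among 81 reference
LOINCs.

**Withheld codes need a stable wrong-distance environment.** The
`unmapped_fraction` device removes a share of true LOINCs from the
reference panel, creating codes whose every candidate is wrong — the
population the cutoff must reject. For the z-score to separate these
from correct mappings, a withheld code's nearest wrong reference must be
neither a near-twin (which would produce a confidently wrong mapping)
nor so distant that its row is a constant shelf at 1 (in which case
*any* unique minimum, right or wrong, looks like an extreme outlier).
`scenario_partial_reference()` therefore places all codes on a regular
grid at 0.75 sd spacing — neighbouring codes overlap substantially, so
every row carries a ladder of partial overlaps — and interleaves the
query codes evenly among interior distractor positions, so no two query
codes are grid-adjacent and every withheld code keeps its nearest
(wrong) reference at exactly one grid step. Under these conditions
correct mappings concentrate just below the −5 operating point and
withheld ones just above it, which is precisely the regime the cutoff is
for.

What the generator does **not** emulate: mixed or mislabeled units,
detection-limit censoring and other truncation artifacts, non-numeric
results mixed into numeric columns beyond simple drops, temporal assay
drift, patient-population case-mix differences between sites, and pairs
of genuinely indistinguishable analytes (e.g. the same measurand from
serum vs plasma). Passing the packaged tests therefore demonstrates the
machinery and the qualitative behaviour of the cutoff, not performance
on any real EHR pair.

## Evaluation design

Because sampling is stochastic, a single mapping run is noisy;
`run_repeated_evaluation()` repeats the pipeline (default 30 runs, each
on a sub-seed derived from the master seed and the run index) and
averages precision and acceptance counts along a cutoff grid, with the
accept-everything regime (`Inf`) appended. The correct-vs-incorrect
z-score comparison uses a one-sided Wilcoxon rank-sum test by default —
a rank test makes no normality assumption about z-scores whose
distribution is an order-statistic construct; a Welch t-test is
available behind `method = "t"`. No false-discovery-*rate* estimator is
attached to the threshold: the acceptance rule is exactly a z-score
cutoff, and inventing an FDR estimate the method does not define would
overstate what it controls.

Problem sizes used throughout the package's own tests and in
`scripts/acceptance.R`: 20–30 query codes, 60 distractors, 2000 stored
observations per code, 1000-reading samples, 30 runs. These are desk
scale by choice: large enough that the KS noise floor and the z-score
geometry behave as in deployment, small enough that the whole suite
re-runs in minutes.

## Known limitations

- Unit-of-measure consistency between a local code and its mapped LOINC
  is not checked; a value-scale coincidence across different units can
  produce a confident false mapping.
- The −5 and −3.80 operating points are dataset-derived defaults, not
  universal constants; both are configurable and should be swept on new
  reference panels.
- Only quantitative tests are mappable; qualitative results ("POS",
  "NEG") are dropped at ingestion.
- A single reference dataset biases the reference eCDFs toward its
  patient population; pooling several references would be the natural
  extension.
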