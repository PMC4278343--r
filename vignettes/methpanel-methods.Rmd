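---
title: "Methods: methylation panel calling, operating characteristics and model ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation panel calling, operating characteristics and model ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpanel)
```

## The measurement model

MS-qPCR interrogates bisulfite-converted DNA with primers specific to the
methylated allele: the cycle threshold Cq at which fluorescence exceeds
background falls with the amount of methylated template. The panel consists
of 24 cancer-associated CpG-island markers measured by 29 assays — five
markers (RASSF5, MOXD1, KIFC2, NEUROG3, HEMK1) carry two assays targeting
different island regions or opposing strands.

Calling is binary with a single cutoff for all assays:

* **call = 1** iff Cq < cutoff (strict; default 35 cycles). "Below the
  cutoff" is read literally, so Cq = 35.0 is negative.
* **level** = max(0, cutoff − Cq), in cycles. The level scale is a design
  choice: the source data are semi-quantitative and no copy-number
  calibration exists, so we use the ΔCq-like quantity that (i) preserves
  the defining equivalence *call = 1 ⇔ level > 0* and (ii) orders cores
  monotonically in template abundance. All level-based statistics are
  scale-dependent and should be interpreted as such.
* **pooling**: a dual-assay marker's call is the OR of its assay calls and
  its level the max of the assay levels. OR is the only rule consistent
  with "any assay below the cutoff means methylated"; max keeps the
  call/level equivalence. A marker is missing only when *all* of its assays
  were not run; missingness is per-cell and excluded from every
  denominator.

A reaction that never amplifies is a *negative observation* (call 0), not
missing data. In Cq CSV files an empty cell or `NA` means no amplification
and the sentinel `NR` means the assay was not run; in memory these are
`NA` and `NaN` respectively.

## Representative cores

Operating-characteristic tables use one core per patient so no patient is
counted twice: each control's most-methylated core (the highest available
methylation burden for that individual), each case's cancer core (the
most-methylated one if two were sampled), and for field-effect analyses
each case's most-methylated non-cancer ("CCNC") core. Ties on marker count
are broken by higher mean level, then by stable input order; the rule is
deterministic and permutation-stable when counts are distinct. Group-mean
comparisons (e.g. CCNC vs control burden) use *all* cores by default,
since the reported per-core means are over full core sets, while the
operating-characteristic tables use representative cores.

## Operating characteristics and intervals

Sensitivity and specificity are observed proportions conditional on true
status, with per-marker denominators reduced by missing cells. Intervals
are 95% Wald: p̂ ± z₀.₉₇₅ √(p̂(1−p̂)/n).

Three deliberate conventions:

* **Continuity correction off by default.** The published intervals match
  the *uncorrected* Wald formula at two-decimal rounding (33/37 →
  (0.79, 0.99); corrected would give (0.78, 1.00)), so the uncorrected
  interval is the default and the corrected one a flag.
* **Raw bounds unclipped, rendering floors the lower bound.** `wald_ci()`
  returns raw bounds (upper bounds like 1.01 or 1.03 are meaningful
  evidence of the normal approximation straining near p̂ = 1). In rendered
  tables the lower bound is floored at 0.00, matching the reporting
  convention of the validation tables; upper bounds print unclipped.
* **Degenerate estimates have no interval.** At p̂ ∈ {0, 1} the Wald
  interval collapses; it is undefined (`NA`) and rendered `--`.

Rendering rounds half away from zero to two decimals; full precision is
kept internally.

The k-of-24 composite rule calls a core positive at ≥ k methylated
markers. Sensitivity is non-increasing and specificity non-decreasing in k
by construction, and PPV/NPV are computed at observed prevalence as
tp/(tp+fp) and tn/(tn+fn).

## ROC analysis

AUC is the Mann-Whitney statistic — the probability a random case
outscores a random control, ties counted ½ — computed by ranks and equal
to the trapezoidal area under the empirical curve (property-tested against
brute-force pairwise comparison). Three score definitions are offered,
because "number of methylated markers and their methylation levels" admits
more than one combination:

* `count_only` — the marker count;
* `level_mean` — mean level over non-missing markers;
* `count_then_level` (default) — lexicographic count-then-mean-level,
  embedded as count + mean_level/(1 + max_level) so the level term is < 1
  and only breaks count ties.

Sequential marker-combination curves score each core within a marker
prefix (count with mean-level tie-break), one curve per prefix length.

## Group statistics

Within-case contrasts pair each cancer core with the same patient's
representative CCNC core: a paired t-test per marker on levels (a
count-based variant exists), dropping incomplete pairs per marker.
Independent-group contrasts use the Welch unequal-variance t-test;
age-methylation associations use OLS stratified by disease status. No
multiplicity correction is applied across the 24 paired tests, matching
the source analysis; `p.adjust` can be applied downstream if desired.

Degenerate inputs are flagged rather than fatal: zero-variance differences
return p = 1 (all-zero) or p = 0 (constant non-zero shift) with
`degenerate = TRUE`, so extreme simulation configurations complete.

## Best-subsets model ranking

The cohort (one representative core per patient) is split stratified by
status into training (floor of 2/3 per stratum: 44 controls + 24 cases at
the study's sizes) and test (23 + 13). All C(24,1)+C(24,2)+C(24,3) = 2,324
marker subsets — optionally each with patient age appended, and with
binary-indicator or level covariates — are fitted by logistic regression
and ranked by stratified 4-fold cross-validated AUC (mean of per-fold
held-out AUCs; folds are seeded, dealt round-robin within stratum).
Coefficients are refit on the full training set, and test-set AUC is
computed with those coefficients *frozen* — the test data never
participates in fitting or ranking (property-tested: shuffling test labels
cannot change the ranking or coefficients).

With ~70 training patients and near-perfect binary markers, complete
separation is routine and maximum-likelihood logistic regression diverges.
Fits therefore carry a small ridge penalty (0.1 on non-intercept
coefficients, Newton/IRLS, convergence tolerance 1e-6, ≤ 30 iterations):
coefficients stay finite while the induced risk-score *ordering* — all
that AUC ranking uses — is essentially unchanged. Ranking ties are broken
by smaller subset, then lexicographic covariate names, making reruns
byte-stable. The specific published AUC values are not reproducible
without the patient-level data and the authors' unrecorded split; the
procedure, not those numbers, is the contract here.

## The synthetic cohort generator

The generator emulates the validation study's design: 67 controls
contributing 1–3 cores (mostly 2; extra cores abnormal with the observed
proportion) and 37 cases contributing one cancer core plus 1, 2 or 4
non-cancer cores, with patient age, PSA, Gleason and core-age marginals
near the published summaries. Marker calls are independent Bernoulli draws
per (core, marker) from tissue-class profiles:

* **cancer** — the published per-marker sensitivities unscaled (sum
  13.80, matching the observed mean of 13.66 methylated markers per
  cancer core);
* **control classes** — the published 1 − specificity column describes
  each control's *most methylated* core, so its raw sum (1.92) overstates
  the per-core rate; it is scaled to the reported all-core mean of 1.5.
  Benign and abnormal control cores share a profile (no mean difference
  was observed);
* **case CCNC / case abnormal** — the CCNC sensitivity column (sum 6.52)
  scaled to the reported per-core means 5.9 and 4.36 respectively.

`calibrate = FALSE` keeps the raw selected-core frequencies for
reproducing selected-core analyses. Positive calls receive levels from a
log-normal law on the cutoff − Cq scale (sdlog 0.6; meanlog 1.6 for
cancer, 1.2 for case non-cancer, 0.8 for control classes — cancer cores
amplify a few cycles earlier, consistent with higher methylated-template
fractions; the law itself is a modelling choice, no level distribution was
published). Cq = cutoff − level; the second assay of a dual marker
amplifies with probability 0.7 at a level no larger than the first, so
pooling recovers the marker call and level exactly. Per-cell dropout
(default 0.007 ≈ the 36/5112 missing cells implied by the study) is
applied last. Markers are independent by default — the source analysis
models nothing jointly and independence reproduces its printed means — but
an exchangeable Gaussian-copula correlation (`rho`) is available as a
sensitivity knob, preserving marginals while concentrating per-core counts
at the extremes as rho → 1.

What passing tests on this generator do **not** show: real FFPE cores have
spatially correlated field effects, marker-marker dependence, DNA-quality
gradients with block age, and non-random missingness; none of these are
emulated beyond the dropout and copula knobs. Results on synthetic data
validate the *computations*, not clinical performance.

## Problem sizes and numerical choices

Tests run the generator at the study's cohort sizes (67/37) for
integration checks, n = 5000 cores for marginal-recovery checks (3
binomial SEs), 20 permuted-label replicates at subset size ≤ 2 for the
model-selection null calibration (the honesty property — frozen test AUC
≈ 0.5 under the null — does not depend on subset size), and a full
2,324-subset enumeration once. The ridge solver falls back to flagging a
candidate unconverged rather than erroring if its Hessian solve fails;
ranking then uses the achieved score. Truncated log-normal levels are
resampled above cutoff − 0.5 so every generated Cq is positive.

## Known limitations

* The level scale (cutoff − Cq) is a monotone proxy, not copies or
  normalized concentration; level-based effect sizes are not comparable
  across assay chemistries.
* PPV/NPV use the standard tp/(tp+fp), tn/(tn+fn) estimators at observed
  prevalence; published predictive values computed under other conventions
  may differ.
* One core per patient analyses discard within-patient replication; no
  mixed-effects modelling is attempted.
* The missing-cell pattern of the original data is unknown; the generator
  uses uniform per-cell dropout.
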