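---
title: "Paired oral-gastric profiles: diversity, association, and taxa sharing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired oral-gastric profiles: diversity, association, and taxa sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the data model

A hypochlorhydric stomach — for instance under autoimmune atrophy of the
acid-secreting mucosa — loses the chemical barrier that normally kills
bacteria swallowed with saliva. A natural study design is therefore a
case–control cohort in which every subject contributes **one saliva sample
and one gastric biopsy**, both shotgun-sequenced and taxonomically
classified. `gastroshare` starts where the classifier stops: a
taxa-by-sample matrix of **classified read counts** and a metadata table
assigning each sample to a subject, a compartment (`saliva`/`biopsy`) and a
group (`case`/`control`).

Two structural facts about such data drive every design choice below:

* **Depth asymmetry.** Saliva profiles are deep (order 10^4–10^5 classified
  reads, hundreds of taxa); biopsies are shallow (order 10^1–10^3 reads,
  tens of taxa), because gastric biopsies are mostly host DNA. Any statistic
  computed on raw counts across compartments would measure depth, not
  biology. Counts are therefore stored as absolute classified reads, never
  pre-normalized, and relative abundances are derived on demand exactly
  where a method needs them.
* **Pairing.** Subjects, not samples, are the unit of the sharing analysis.
  Per-compartment statistics use every available sample; the sharing stage
  uses only subjects with both compartments (incomplete subjects are
  reported and excluded from sharing only, so the per-compartment *n* and
  the paired *n* may legitimately differ).

## Alpha-diversity

The Shannon–Wiener index `H = -sum(p_i log p_i)` is computed per sample on
relative abundances, **natural log by default**. The base is exposed
(`shannon_index(counts, base = 2)`) and recorded in outputs; printed values
between 2 and 3 for communities of tens to hundreds of taxa are consistent
with nats. We deliberately do **no rarefaction**: with biopsy depths of a
few hundred reads, rarefying would discard most of the already-scarce
signal. Instead the per-sample read depth is reported next to the index so
depth–diversity coupling is visible rather than hidden.

Group comparisons use the Welch *t*-test (unequal variances is the safe
default; a pooled-variance option exists) with a **stratified percentile
bootstrap** (resampling within each group, B = 1000 by default, seed
mandatory) for the CI of the mean difference, a Mann–Whitney p alongside —
the t and the rank test answer the mean/median question respectively, and
we report both rather than guess which a reader wants — and a post hoc
power estimate at the observed effect.

Post hoc power uses the pooled SD and the noncentral *t* distribution.
This is one convention among several in commercial software; the
implementation is validated against a Monte-Carlo oracle (100k simulated
pooled t-tests), not against any published power value, and published post
hoc powers from other tools should not be expected to reproduce exactly.

## Beta-diversity

Bray–Curtis dissimilarity is computed **after per-sample normalization**
(see depth asymmetry above), so it is invariant to sequencing depth and lies
in [0, 1]. Ordination is classical PCoA: double-center `-D^2/2`,
eigendecompose, scale eigenvectors by the square roots of positive
eigenvalues. Bray–Curtis matrices are generally not Euclidean-embeddable,
so negative eigenvalues occur; we **discard and count** them (no
Cailliez/Lingoes correction — the count is reported so a user can judge
distortion), and variance proportions are taken over the positive spectrum
only, hence they sum to at most 1.

Group separation is tested with a one-way PERMANOVA-style pseudo-F and a
seeded label-permutation null, `p = (1 + #{F* >= F}) / (1 + n_perm)` with
`n_perm = 999` by default; the minimum attainable p is `1/(1 + n_perm)`.
`n_perm = "all"` enumerates every distinct two-group assignment, which the
test suite uses to check the sampled p against exact enumeration. The
original study reports beta-diversity p-values without naming the test;
this package documents its choice in the output metadata and does not claim
to reproduce unnamed procedures.

## Group–taxon association

For each taxon in a compartment we correlate case membership (1/0) with the
taxon's relative abundance — or its binary presence — using **midrank
Spearman** correlation. Two properties matter:

* For two binary vectors, midrank Spearman is exactly the **phi
  coefficient** of the 2x2 table. With 20 cases and 20 controls, a taxon
  present in 4 cases and no controls gives `rho = 80/240 = 0.3333`, which is
  why presence-driven correlations in shallow compartments cluster at such
  values. The equivalence is verified exhaustively over all 2x2 tables with
  margins up to 20/20 in the test suite.
* p-values use the *t* approximation `t = rho sqrt((n-2)/(1-rho^2))` on
  `n - 2` df (e.g. `rho = 1/3, n = 40 -> p = 0.036`). At `|rho| = 1` the
  approximation degenerates; p is reported as 0 with a warning.

Both the raw p and the Benjamini–Hochberg q (step-up, computed within
compartment) are reported. Published tables of this kind are often
consistent with *unadjusted* p despite a stated FDR correction; reporting
both sidesteps the ambiguity. The default mode is relative abundance;
presence mode exists because shallow-biopsy associations are effectively
presence signals. Taxa constant across samples have undefined rho and are
reported as missing, with a warning, rather than silently dropped. The
case view and the control view are exact negations of each other and both
are emitted, sorted by rho descending.

## The sharing procedure

For each paired subject: the **presence set** of a sample is the set of
taxa with at least `threshold` classified reads (default 1); the subject's
**shared set** is the intersection of the saliva and biopsy presence sets.
The detection default follows from internal consistency: the conventional
2.5% prevalence cut-off on 40 samples resolves to "detected in at least one
sample", so one classified read *is* detection. The threshold is exposed,
and raising it can only shrink shared sets (a tested monotonicity
invariant). Whether a minimum relative abundance should additionally be
required is genuinely open; the default is documented rather than hidden.

Group summaries count, per taxon, the subjects whose shared set contains it,
as counts and percentages of group size; the absolute difference
`pct_case - pct_control`; and the relative difference
`(pct_case - pct_control)/pct_case`, undefined (NA) when the case share is
zero. A taxon shared in one group and never in the other is flagged
`only-case`/`only-control` (rendered `Only CA`/`Only CO` in report tables).
Rows sort by absolute difference, ties by case count, then label — the
layout of the familiar "top N shared taxa" table (N = 12 by default, a pure
report parameter). The per-subject shared-set sizes `k` are summarized as a
histogram; the identity `sum_k k n_k = sum_taxa shared_count` ties the two
views together and is asserted in the tests. Co-sharing patterns flag taxa
that are never the sole shared taxon of any subject.

Sharing is presence-based, not abundance-correlation-based, and the package
makes no directional claim: a shared taxon is evidence of association
between the oral and gastric communities, compatible with either
translocation or independent colonization.

## The synthetic cohort generator

`cohort_params()`/`generate_cohort()` produce a full paired cohort with
ground truth. The stated world (defaults):

| parameter | default | rationale |
|---|---|---|
| subjects | 20 + 20 | the emulated study design |
| oral / gastric pool | 500 / 130 taxa | matches a ~3.9:1 observed taxa ratio |
| pool overlap | 30 taxa | oral commensals genuinely resident in stomachs, so controls share too |
| saliva depth | lognormal(log 26000, 0.55) | median ~26k, quartile ratio ~1.4 |
| case biopsy depth | lognormal(log 159, 1.2) | median 159; implied mean ~325 |
| control biopsy depth | lognormal(log 113, 0.85) | median 113; implied mean ~162 |
| taxon abundances | lognormal, sd 2.0 | heavy-tailed ranks typical of microbiomes |
| per-sample jitter | lognormal, sd 0.6 | sample-to-sample rank wobble |
| evenness penalty (case biopsy) | 0.85 | abundances raised to 1/0.85, concentrating the community; calibrated to produce a small but consistent Shannon deficit in cases |
| translocators | k = 4, prob 0.2, rel. abundance 0.05 | four designated oral taxa, each seeded into ~20% of case biopsies |

Reads are multinomial at a drawn depth, so per-sample totals equal drawn
depths exactly — seeded translocator reads are *reserved out of* the depth
(floor of one read per seeded taxon) before the multinomial remainder, which
both preserves that conservation law and makes the strong-effect
configurations genuinely forced: with `transloc_prob = 1` and disjoint
pools, every translocator is case-shared and nothing else can be, so
case-exclusive detection has sensitivity 1 and false-positive rate 0 by
construction. Translocators are picked from the most *abundant* oral taxa
outside the gastric pool, mirroring the fact that observed mouth-to-stomach
taxa are core oral commensals — and guaranteeing the donor saliva actually
contains them. These defaults were chosen once, calibrated to the published
summary statistics (not fitted to data, and not adjusted against test
outcomes).

What the generator does **not** emulate: read-level sequencing error and
classifier confusion, host-DNA competition, zero-inflation beyond what
shallow multinomial sampling induces, taxon–taxon correlation structure,
and any real phylogenetic signal in the labels. A green recovery test
therefore establishes that the *pipeline* recovers planted structure under
the stated noise model — not that the model captures everything real
cohorts do.

`evaluate_recovery()` scores an analysis against truth three ways:
taxon-level sensitivity (translocators recovered as case-exclusive), a
seeded-event sensitivity (per seeded subject-taxon event; the taxon-level
view saturates once every translocator is seeded into at least one of 20
cases, so only an event-level rate can increase across the whole seeding
grid), association-rank sensitivity, and the false-positive rate among
non-translocators.

## Numerical conventions and edge cases

* Percentiles/IQR: linear interpolation (type 7); SD uses the n−1
  denominator.
* All-zero sample columns are flagged and kept at validation; they are
  excluded from Bray–Curtis (undefined there) and produce NA diversity.
* Degenerate two-group tests (all values identical in both groups) report
  p = 1 with a warning rather than NaN.
* Every stochastic routine (bootstrap, permutation test, generator) takes an
  explicit seed; same seed, same bytes. Widening the bootstrap cannot move
  the t, p, or mean difference, only the CI.
* Report formatting: rho to 4 decimals, p to 3, percentages as integers.
* Prevalence filtering at cut-off 0 is the identity; filtering is
  idempotent; an empty filtered table downgrades beta-diversity and
  association to empty outputs instead of aborting the run.

## Known limitations

* Sample-level tests only: a published saliva diversity contrast with a
  tiny effect and a ~0 p-value suggests some upstream analyses are run on
  units other than per-sample summaries (e.g. read-level resampling); this
  package does not attempt to reverse-engineer such procedures.
* Post hoc power and the beta-diversity permutation test follow documented
  conventions that need not match unnamed or proprietary implementations.
* The *t* approximation for Spearman p is used even under heavy ties
  (binary presence); under permutation nulls its average rejection rate is
  close to nominal (tested), but per-taxon calibration at extreme
  sparseness is approximate.
* No strain-level transmission inference, no compositional (CLR/ALR)
  transforms, no phylogeny-aware metrics.
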