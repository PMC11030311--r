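---
title: "Regional missense constraint: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional missense constraint: model, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmcr)
```

## The problem

Gene-level measures of missense depletion average over a transcript, but
selection against missense variation is often regional: a kinase domain may
tolerate almost nothing while a linker tolerates everything. `rmcr`
segments each transcript's coding sequence into **missense constraint
regions (MCRs)** with statistically distinct levels of depletion, using only
the presence/absence pattern of rare missense variants in a large reference
cohort against a calibrated neutral expectation.

## The neutral expectation (mu_adj)

Every possible missense substitution carries a context-dependent mutation
rate `mu` keyed by its trinucleotide context, alternate allele, and (for CpG
sites) methylation level. Two calibrations convert `mu` into the expected
probability of observing the variant in the reference cohort:

* **Plateau calibration.** A linear fit of the proportion of possible
  variants actually observed at putatively neutral (synonymous) sites
  against `mu`, fitted separately per chromosome class
  (autosomal/pseudoautosomal, X, Y) and CpG status, because CpG transitions
  saturate at large cohort sizes. Predictions are clamped to [0, 1]; a
  linear fit can leave the unit interval at extreme rates, but the quantity
  is a proportion. `fit_plateau()` accepts any rate table and any
  proportion-observed table, so the calibration is data-agnostic.
* **Low-coverage correction.** Sites with median exome depth below 40x are
  under-called. The default correction is a single scaling factor (total
  observed synonymous variants over the total expectation mass); an optional
  linear model on log10(depth), fitted over depth strata below the
  threshold, is provided as a smoother alternative since the exact published
  functional form of this correction is not printed anywhere we could
  verify. Both are exposed through `fit_coverage_scaling(form = )`. The
  correction is never applied at or above the threshold, and zero-coverage
  sites are expected to be excluded upstream (they are unobservable).

The per-site result `mu_adj` is additive: the expectation of any site set is
the sum of its sites' contributions (`expected_count()`).

## Observed variants and the OE ratio

A possible site counts as observed when allele count > 0, allele frequency
< 0.1% (rare variation reflects recent mutation-selection balance; common
variants are old and already filtered by selection), variant QC pass, and
median coverage > 0 (`filter_observed()`). Constraint is the capped ratio
`OE = min(1, obs / max(exp, 1e-9))`: capped at 1 because the method looks
for depletion, not enrichment; floored in the denominator so empty
expectations stay finite. Transcripts with outlier counts under neutrality
(zero expectation in any class, too many observed variants, or too few
synonymous variants, |z| > 4 by default) can be excluded with
`filter_outlier_transcripts()`; the z-bound is configurable because the
upstream pipelines that flag such transcripts do not publish exact numeric
bounds.

## The breakpoint search

Observed counts are modeled as Poisson around `exp × OE`. For each candidate
breakpoint the likelihood under a shared OE (null) is compared with
per-section OEs (alternative); the statistic is `χ² = 2(ln p1 − ln p0)`,
computed in log space with the factorial terms dropped (they cancel in the
ratio). Because each section's capped OE is the constrained maximizer of its
Poisson likelihood over [0, 1], the statistic is non-negative by
construction.

Key parameters (`search_config()`):

* `min_expected = 16` expected missense variants per created subsection.
  This prevents splits that would create tiny, unstable sections; it is the
  eligibility rule for candidate positions, and consequently every region
  produced by a split retains at least 16 expected variants. (A transcript
  whose total expectation is below 16 is still emitted as its own single
  region — the floor applies to split products, not to input transcripts.)
* `alpha = 0.001` with χ² reference distributions of 1 df (single break:
  one extra OE parameter; critical value 10.83) and 2 df (simultaneous
  double break: 13.82). The published method states only the significance
  level, not the reference degrees of freedom; the defaults follow standard
  likelihood-ratio accounting and both are configurable.
* Tie-breaking: when several positions attain the exact maximum χ², the
  leftmost (smallest coding position) is chosen. Deterministic; the
  alternative (reporting all tied positions) complicates the recursion for
  no statistical gain.
* A breakpoint at position k assigns sites with `cds_pos <= k` to the left
  section (closed-left convention).

A "position" is a coding-sequence position: substitutions at the same
`cds_pos` are pooled, since a breakpoint between two alternate alleles of
one position is meaningless. The scan is exhaustive (no heuristic pruning):
cumulative observed/expected arrays give O(1) section sums, making the
single-break scan O(n) and the two-break scan O(n²) per section. The
recursion applies the single-break scan first, the two-break scan only when
no single break is significant, then treats every new subsection as an
independent transcript — including re-attempting two-break scans inside
subsections produced by a two-break split.

## The MPC deleteriousness score

Six variant features feed a logistic regression separating pathogenic
(label 1) from benign training variants: the substitution class's overall
OE; the curvature (second difference over the ten local-OE bins
[0, 0.1), ..., [0.9, 1.0+]) of the class's OE profile, evaluated at the
variant's bin; BLOSUM and Grantham substitution severity; the local OE (MCR
if the transcript has several, else transcript); and PolyPhen-2. These are
consumed as precomputed columns — the package does not compute protein-level
predictors. Second differences use the central estimator with one-sided
copies at the two end bins; the published description names the quantity but
not the estimator. Bin edges are left-closed/right-open, with the final bin
absorbing OE = 1.

Training sets are assembled from clinically labeled variants (pathogenic:
P/LP, non-conflicting, ≥ 1 review star, in genes with pHaplo ≥ 0.86 or a
dominant non-LoF developmental-disorder association) and common population
variants (AF > 0.1%, QC pass); variants qualifying for both sets are dropped
from both. Train/test transcript splits are stratified on s_het and on the
number of possible missense sites (`stratified_split()`), canonicalized on
sorted transcript ids so the split is order-invariant.

The score is a rank, not a probability:
`d_i = −log10(max(0.83, f_i) / M)` where `f_i` counts the M benign training
variants that the model considers *less benign-looking* than variant i —
i.e. benign variants whose pathogenic-direction fitted value is strictly
greater than the variant's, which is exactly the count "strictly less than
variant i" on the regression's benign-direction scale. Written either way
the transform is the same; we state both because the direction of the fitted
value depends on an arbitrary label coding, while the score's meaning (larger
= more deleterious, maximum `log10(M/0.83)` ≈ 4.89 at M = 64,023) does not.
Ties with benign fitted values do not count toward `f_i`, so ranks are
reproducible. Because only ranks matter, the score is invariant under any
strictly monotone transform of the fitted values, and the small ridge
penalty used as a fallback under detected quasi-separation perturbs scores
negligibly. Variants missing any feature are unscored (`NA`), never given a
default. Models persist to JSON with the full sorted benign fitted values
(exact-count storage) for bit-reproducible ranks.

## Evidence-threshold calibration

`local_posterior()` estimates the probability that a variant is pathogenic
as a function of a continuous score, from labeled variants: at each grid
point, the proportion pathogenic among the k nearest labeled variants
(default k = 100; a k-nearest window adapts to the labeled set's density
where a fixed-width window would go empty), converted from the labeled set's
own prevalence to a chosen clinical prior on the odds scale. One-sided 95%
bootstrap bounds (variant resampling, seeded) provide the stringent side:
lower for pathogenic claims, upper for benign claims.

`evidence_thresholds()` converts the point-based classification framework's
odds — c = 350 for very strong evidence and its 1/2, 1/4, 1/8 roots for
strong/moderate/supporting — into posterior cutoffs at the prior (default
0.0441, the framework's canonical value; the calibration prior used in the
source analyses is unstated, so both are configuration). The score threshold
for each strength is the most permissive score whose stringent bound meets
the cutoff; using the bound instead of the point estimate can only move
thresholds toward conservatism, which the tests assert. Strengths never met
are reported as `NA` rather than extrapolated.

## Enrichment statistics

`rate_ratio()` compares per-individual variant rates between cohorts; the
p-value and interval come from a binomial test of the case share of pooled
variants with cohort sizes as the null proportion, mapped back to the
rate-ratio scale. The per-variant-count construction is one reasonable
reading of "confidence intervals calculated from a binomial test"; the
per-individual alternative is not implemented. `top_percentile_or()` ranks
pooled case and control scores, takes the top percentile (ties at the
boundary included — the inclusive rule is deterministic and errs toward
larger, better-powered top sets), and reports the sample odds ratio with
Fisher's exact p. `oe_bin_enrichment()` applies the rate ratio within
left-closed bins of local OE with an open-ended final bin.

## The synthetic-data generator

`simulate_transcript()` draws each possible substitution independently as
Bernoulli with probability `min(1, OE × mu_adj)` — site-level generation, so
the search scans data with realistic granularity; region totals are then
Poisson-binomial, which at per-site rates well below 1 is the Poisson the
model assumes. Defaults encode the study conditions: `mu = 0.4` expected
variants per possible substitution (large-cohort scale, where roughly half
of possible neutral variants are observed) and `n_alts = 3` substitutions
per coding position, matching real site tables where nearly every coding
position carries 2–3 possible missense changes; together ~1.2 expected
variants per coding position. Breakpoint localization precision is
information-limited by this per-position density: a direct simulation of the
changepoint maximum-likelihood estimator with *known* rates localizes within
±5 positions ~94.9% of the time at 1.2 expected/position (and only ~72% at
0.4/position), so sparser defaults would misrepresent the method as
imprecise and denser ones are not biologically available. The plug-in
likelihood-ratio scan tracks that ceiling to within ~1–2%.

`simulate_labeled_variants()` draws the six MPC features from
class-conditional Gaussians with specified mean shifts;
`simulate_cohorts()` draws per-individual, per-bin Poisson variant counts at
control base rates times case multipliers. All generators are reproducible
from (profile, seed), and every downstream seed in the tests and the
acceptance script derives from a single top-level seed.

What passing tests on these simulations do **not** show: robustness to
mis-specified mutation rates, to coverage or QC artifacts correlated along
the transcript, to allele-frequency spectra (the generator flags variants
observed/unobserved without modeling frequencies beyond the rare cutoff), or
to 3D-clustered constraint that a linear scan cannot represent.

## Numerical choices and degenerate inputs

* Poisson log-likelihoods drop factorial terms (they cancel in the ratio)
  and define 0·log(0) = 0, so empty sections at rate zero contribute
  nothing.
* Expectations of exactly zero are floored at 1e-9 inside the OE ratio.
* `oe_bin()` uses left-closed bins with the final bin closed at 1.0+.
* Degenerate fits error early: plateau calibration requires two distinct
  rate/proportion pairs; training assembly errors on an empty class;
  `local_posterior()` marks grid points undefined rather than extrapolating
  when the window cannot gather k labeled variants.
* Problem sizes in the test suite and acceptance script — 200 recovery
  replicates of 300-position transcripts, 500 null transcripts of 150
  positions, exhaustive 2×2 enumeration to grand total 30 — were chosen as
  the smallest sizes at which the targeted rates are measurable with ~1–3%
  Monte-Carlo error.

## Known limitations

* Only linear (sequence-contiguous) regions: constraint clustered in 3D
  structure is invisible to the scan.
* Missense enrichment (OE > 1) is deliberately not detected; the cap
  discards that signal.
* The two-break scan is O(n²) per section; very long transcripts dominate
  runtime, though eligibility pruning keeps the constant small.
* Published headline values (genome-wide MCR counts, specific gene OEs,
  clinical OE cutoffs 0.37/0.21) require the full reference-population,
  clinical-variant, and cohort datasets; nothing in this package's tests
  claims to reproduce them.
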