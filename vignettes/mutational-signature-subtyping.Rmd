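---
title: "Mutational-signature subtyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational-signature subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MutSigSubtypes)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
cohorts do and do not emulate, and the places where the design was genuinely
open and a choice had to be made.

## From SNV catalog to spectrum

A somatic single-nucleotide variant in its trinucleotide context belongs to
one of 192 raw classes (6 substitutions x 4 x 4 flanks, on either strand).
Because sequencing does not observe which strand a mutational process acted
on, the field collapses each class onto its pyrimidine-referenced
representative, giving the canonical 96 channels. `collapseSubstitution()`
implements this as an exact 2-to-1 surjection (exhaustively enumerated in the
tests), with the COSMIC ordering convention: substitution class major, then
5' flank, then 3' flank. Reference signature files are matched to this order
**by channel label, never by row position**, so a re-sorted signature TSV
loads correctly.

Input handling follows MAF conventions (1-based positions); VCF input is
converted on read. Indels, MNVs and ambiguous-base rows are dropped silently
with per-reason counts returned as metadata, since the analysis is defined
over single-base substitutions only. Duplicate records (same sample,
chromosome, position, ref, alt) are counted once by default — repeated caller
output should not inflate a channel — with `dedupe = FALSE` available when
duplicates are genuine. All contigs, including sex chromosomes, are treated
uniformly, and all samples are included regardless of hypermutation status;
hypermutated tumors are rare in the cohorts this design mirrors and their
exclusion is not part of the method.

## The cosine-similarity feature space

Each sample's spectrum is compared against every reference signature by
cosine similarity. Cosine is scale-invariant, so whether spectra are raw
counts or normalized frequencies is mathematically irrelevant; the package
uses raw counts. The samples-by-signatures CS matrix — not NMF exposures, and
not a signature-refitting deconvolution — is the feature space throughout.
This is a deliberate property of the method: CS against a fixed catalog is
stable across sequencing platforms with very different mutation yields
(WES vs targeted panels), which is what makes cross-cohort classifier
transfer plausible.

Samples with zero accepted SNVs have no defined cosine; they are flagged and
excluded from prevalence denominators and clustering, never silently zeroed.

**The retention filter.** A signature is excluded when the fraction of
samples attaining `CS >= csThreshold` for it falls below `minPrevalence`
(defaults 0.24 and 0.10). The filter sentence this encodes admits a second
reading (a mean-CS rule); the per-sample-prevalence reading was chosen as the
most literal one, both boundaries inclusive (`>=`), and the filter reports
per-signature prevalences so the decision is auditable. Raising either
threshold can only shrink the retained set (property-tested).

## NMF consensus clustering

The retained CS matrix `V` (samples x signatures) is factorized as
`V ~ W H` under Frobenius loss with Lee–Seung multiplicative updates. Details
that matter numerically:

* initialization: uniform random entries scaled by `sqrt(mean(V) / k)`, from
  a per-run seed, so every run is reproducible bit-for-bit;
* `1e-12` added to update denominators, which keeps the objective trace
  non-increasing (asserted on every fitted model) without altering fixed
  points in practice;
* stopping at relative objective change below `tol` (default `1e-6`,
  consensus runs use `1e-5`) or `maxIter`.

Hard clusters are the arg-max over each row of `W`, ties broken toward the
lower cluster index for determinism. Rank stability follows common Brunet-style
practice: repeated seeded restarts (default 50), connectivity matrices
averaged into a consensus matrix, and the cophenetic coefficient — the
correlation between the consensus distance `1 - C` and the cophenetic
distances of its average-linkage dendrogram — scored per rank. Restarts that
collapse into a single cluster are discarded with a warning. Subsampling-based
consensus was considered and rejected: at the cohort sizes involved
(tens to a few hundred samples) restart-consensus already discriminates
planted structure from noise clearly, and it keeps the procedure
deterministic given the seed.

The pipeline's working rank is fixed at `k = 2` — the two-subtype solution is
the point of the method — while `consensusCluster()` still reports the full
cophenetic profile over `kRange` so a user can see whether their cohort
prefers a different rank. Clustering is performed on all retained signatures
rather than a further-reduced set.

**Labeling.** Between the two clusters, the one with the higher mean CS over
the APOBEC signatures (SBS2/SBS13) is MUT1; the other, enriched in practice
for clock-like/MMR/chemotherapy signatures, is MUT2. If no APOBEC signature
survives the filter, labeling falls back to the mismatch-repair pair
(SBS6/SBS15) with the rule inverted, and warns loudly — the fallback flags an
unusual cohort rather than silently mislabeling it.

## The nearest-shrunken-centroid classifier

The classifier is implemented from scratch. With per-feature pooled
within-class standard deviation `s_i`, fudge constant `s0 = median(s_i)`
(guarding near-constant features), and `m_k = sqrt(1/n_k - 1/n)`, the
standardized contrast `d_ik` is soft-thresholded by `Delta` and the centroids
reconstructed; features whose contrast vanishes in every class drop out of
the discriminant entirely, which is the feature selection that makes the
model transferable. Two conventions exist for `m_k`; the default follows the
reference software implementation (`sqrt(1/n_k - 1/n)`), with the published
variant (`sqrt(1/n_k + 1/n)`) behind `mCorrection = "published"`.

`Delta` is selected by stratified cross-validation (10 folds, capped at the
smallest class size) with the **one-standard-error rule**: the largest
`Delta` whose CV error is within one SE of the minimum. The parsimony bias is
deliberate — a classifier meant for external cohorts should carry as few
features as the data allow. Class priors default to training proportions
(`priors = "uniform"` available); posteriors are the softmax of
`-delta_k / 2`, the Gaussian-discriminant correspondence; prediction ties
break to the first class label deterministically. Models serialize to JSON so
a trained classifier can be applied elsewhere without refitting.

## Survival and categorical statistics

The Kaplan–Meier product-limit estimator and the two-group log-rank test are
written out from their defining formulas (with the convention that subjects
censored at an event time remain at risk at that time; the log-rank median is
the smallest event time with `S(t) <= 0.5`), and are cross-checked in the
tests against the survival package as an independent oracle. Cox regression
delegates partial-likelihood maximization to `survival::coxph()` with Efron
tie handling — the standard choice for clinical data — with fixed coding
conventions: subtype MUT1 = reference (so HR > 1 means MUT2 excess hazard),
sex female = reference, smoking never = reference with former/current
dummies. Rows missing survival data are dropped; multivariate fits are
complete-case with a reported count. The chi-square test is Pearson without
continuity correction (Yates behind a flag).

The Table-1-style summarizer pools per-cohort category counts and reports
percentages of the pooled total, rounded **half-up** to one decimal — the
convention under which the bundled six-cohort demographic table reproduces
its printed margins exactly. (One printed value, the female percentage, is
internally inconsistent with every other percentage in that table under any
single rounding rule; the summarizer computes 24.0% where 24.1% was printed,
and the discrepancy is in the source, not the arithmetic.)

An optional externally supplied `risk` column (dichotomized at 1: low < 1,
high >= 1) passes through the clinical schema untouched; the score that
produces it is not part of this package.

## What the synthetic cohorts emulate — and what they do not

`simulateCohort()` draws, per tumor: a subtype (60/40 MUT1/MUT2), an exposure
vector from a Dirichlet centered on the subtype's mean exposures
(concentration 50 — tight enough that subtypes are coherent, loose enough
that tumors vary visibly), a mutation burden from a log-normal
(median 100, sigma 0.8 — WES-like), and channel counts from a multinomial
over `signatures x exposure`. Each mutation becomes a concrete MAF row with a
channel-consistent context written on a random strand, so the full purine
collapse and MAF-parsing path is exercised, not just the matrix algebra. The
burden distribution is floored at 100 SNVs so that every simulated tumor
carries enough mutations for a stable spectrum at discovery scale; this floor
is a property of the simulated study conditions, stated here once.

The default exposure presets — MUT1: SBS2 0.35, SBS13 0.35, SBS5 0.20, SBS1
0.10; MUT2: SBS1 0.30, SBS6 0.25, SBS15 0.20, SBS87 0.15, SBS5 0.10 — are
anchored to the qualitative biology of the two subtypes (APOBEC vs
clock-like/MMR/chemotherapy), not to any estimated magnitudes; no per-subtype
exposure magnitudes are published, and these numbers are stand-ins, fully
configurable and never to be read as estimates of real cohorts.

Survival is exponential with MUT1 median 15 months and a MUT2 hazard ratio of
1.74; censoring is uniform on `(0, C)` with `C` solved numerically (uniroot
on the closed-form expected event fraction) for a target event fraction of
0.39, the pooled event rate of the mirrored cohorts. Note one deliberate
consequence: under exponential proportional hazards, a MUT1 median of 15
months and HR 1.74 imply a MUT2 median near 8.6 months — the generator is
internally consistent rather than matching every printed median
simultaneously. Response is Bernoulli at 31.8% (MUT1) vs 13.1% (MUT2).
Age, sex and smoking are drawn from pooled-cohort-like marginals
**independent of subtype**, so univariate recovery targets are clean;
confounded scenarios can be built by post-editing the clinical table.

Reference signatures for desk-scale work come from
`makeSyntheticSignatures()`: sparse Dirichlet columns (concentration 0.08 per
channel), rejection-sampled until every pair has cosine below 0.7, named so
that the APOBEC/MMR labeling logic runs unchanged. Synthetic signatures are
*more* mutually orthogonal than the real catalog, and simulated tumors carry
no sequencing artifacts, panel-capture effects, subclonal structure or
genome-position realism. Passing tests therefore demonstrate that the
machinery is correct and that the statistical pipeline recovers planted
structure under realistic noise — not that any particular real cohort splits
cleanly into two subtypes. Applying the pipeline to a real cohort with the
full COSMIC v3 catalog is supported (the loader accepts any COSMIC-style TSV
and records the signature count) but is beyond desk scale.

## Problem sizes

The shipped checks run at: discovery n = 300 with a 200-sample external
cohort for transfer (50 consensus restarts over ranks 2–4); 2000 null
replicates of two 100-subject arms for log-rank calibration; 200 replicates
of n = 1000 for hazard-ratio recovery; 2000–4000 patients for
response-rate and event-fraction checks. These sizes were chosen to put
Monte-Carlo error well inside the assertion bands while keeping a full run in
tens of seconds on one core.

## Known limitations

* The CS feature space deliberately discards total mutation burden; cohorts
  whose subtype signal lives in burden rather than spectrum shape will not
  split.
* NMF multiplicative updates converge to local optima; the consensus
  machinery averages over restarts but a pathological initialization set
  could still mislead the cophenetic score at small n.
* The log-rank variance term degenerates for a single subject at risk
  (handled), and the Cox wrapper inherits coxph's behavior under complete
  separation (a warning, no penalized fallback by default).
* De novo signature extraction, exposure deconvolution (NNLS refitting),
  doublet/indel signatures, and harmonization between WES and targeted panels
  are out of scope.
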