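# MutSigSubtypes

Mutational-signature subtyping of urothelial carcinoma cohorts from somatic
SNV catalogs.

Urothelial carcinoma has well-established transcriptomic subtypes, but a
purely genomic classification — one computable from a mutation table alone,
including targeted-panel data — is attractive because DNA sequencing is far
more routine than RNA profiling. This package implements such a scheme: each
tumor's somatic SNVs are binned into the 96 pyrimidine-referenced
trinucleotide channels, the spectrum is compared against a reference set of
single-base-substitution (SBS) signatures by cosine similarity (CS), and the
samples-by-signatures CS matrix — after a prevalence filter — is clustered by
non-negative matrix factorization (NMF) into two subtypes:

* **MUT1** — enriched for APOBEC-associated signatures (SBS2/SBS13); better
  prognosis and higher immunotherapy response,
* **MUT2** — enriched for clock-like, mismatch-repair-deficiency and
  chemotherapy signatures (SBS1/SBS6/SBS15/SBS87); worse outcomes.

A from-scratch nearest-shrunken-centroid (PAM) classifier transfers the
subtype call to external cohorts, and the survival module (Kaplan–Meier,
log-rank, Cox proportional hazards, chi-square) stratifies overall survival
and immunotherapy response by subtype.

## The method in brief

For spectrum `x_i` and signature `s_j` (both nonnegative 96-vectors),

```
CS(i, j) = x_i . s_j / (||x_i|| ||s_j||)
```

Signatures with `CS >= 0.24` in fewer than 10% of samples are excluded. NMF
(`V ~ W H`, Frobenius loss, Lee–Seung multiplicative updates) is applied to
the retained samples-by-signatures CS matrix; hard clusters come from the
arg-max of each row of `W`, rank stability from the cophenetic coefficient of
the consensus matrix over seeded restarts, and the two-cluster solution is
labeled MUT1/MUT2 by mean APOBEC similarity. The nearest-shrunken-centroid
classifier soft-thresholds standardized class contrasts
`d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))` and classifies by the
discriminant `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 -
2 log pi_k`.

Because the original cohorts are controlled-access, the package ships a
synthetic-cohort generator with known ground truth (subtype-specific
signature exposures, exponential survival with a configurable hazard ratio,
Bernoulli response), which the test suite uses to verify every stage
end-to-end.

## Worked example

```r
library(MutSigSubtypes)

sigs <- makeSyntheticSignatures(seed = 7)                 # reference SBS set
cohort <- simulateCohort(simulationConfig(nSamples = 80, seed = 11), sigs)

maf <- tempfile(); data.table::fwrite(cohort$maf, maf, sep = "\t")
spectra <- buildSpectrumMatrix(readMAF(maf)$records)      # 80 x 96 counts
cs <- buildCSMatrix(spectra, sigs)
ret <- filterSignatures(cs)                               # CS >= 0.24 in >= 10%
ret
#> RetainedSignatures: 9 of 12 signatures retained (CS >= 0.24 in >= 10 % of samples)

call <- discoverSubtypes(cs, ret, kRange = 2:3, nRuns = 20, seed = 3)
call
#> SubtypeCall: 80 samples ( MUT1: 62, MUT2: 18 )
#>   cophenetic at working rank: 0.996
mean(subtypeLabels(call) == cohort$trueSubtypes)          # recovery vs truth
#> [1] 1
```

The retention report says 9 of the 12 synthetic signatures passed the
prevalence filter; the cophenetic coefficient of 0.996 indicates a highly
stable two-cluster solution, and every sample's label matches the simulated
ground truth. Survival stratification on the same cohort:

```r
clin <- cohort$clinical
a <- clin[clin$subtype == "MUT1", ]; b <- clin[clin$subtype == "MUT2", ]
logrankTest(a$os_months, a$os_event, b$os_months, b$os_event)
#> Log-rank test: chi-square = 0.04291 on 1 df, p = 0.8359
coxFit(clin, c("subtype", "age", "sex", "smoking"))$table[1, ]
#>          term       hr        lo      hi         p
#> 1 subtypeMUT2 1.118127 0.4891477 2.55589 0.7912407
```

With only 18 MUT2 patients the survival contrast is far from powered — the
point estimate is consistent with the configured hazard ratio of 1.74 but
the interval is wide. At the package's default discovery scale (n = 300+)
and across replicates, the configured ratio is recovered tightly (the
acceptance script reports it at n = 10 x 1000).

A thin CLI over the same functions lives at
`inst/scripts/mutsig-pipeline.R` (stages `simulate`, `spectra`, `cs`,
`filter`, `discover`, `classify`, `survive`, `summarize`, `report`; every
stage writes TSV/JSON artifacts plus a provenance JSON).

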