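# lineagemix

Deeply divergent mitochondrial barcode lineages are often read as evidence
for cryptic species. But mitochondria are maternally inherited and never
recombine, so two barcode lineages can coexist inside one freely
interbreeding population — ancient polymorphism brought back together by
secondary contact. `lineagemix` implements the dual-marker analysis that
separates these hypotheses for diploid organisms genotyped at both a
mitochondrial barcode (e.g. a COI mini-barcode) and a panel of nuclear
microsatellites. It was built around the textbook case of Kuhl's
pipistrelle bats, where two lineages ~6% K2P apart co-occur in strict
sympatry yet share one nuclear gene pool.

## What it computes

**Mitochondrial side.**
Haplotype collapsing; nearest-reference lineage assignment (a sequence is
assigned when within `max_distance` mutations of a reference, default 2);
Kimura two-parameter distances, where for transition fraction *P* and
transversion fraction *Q*

d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q),

with the transition/transversion bias *R* obtained from the transitional and
transversional components of *d*; median-joining haplotype networks with
inferred median vectors; mismatch distributions; least-squares fits of the
sudden-expansion (Rogers–Harpending) model giving the expansion parameter τ
with a parametric-bootstrap goodness-of-fit *p* and CI; and molecular dating
via τ = 2*T*μ, where μ is calibrated from a between-lineage distance and an
external divergence date.

**Nuclear side.**
Per-locus diversity indices (*A*, rarefied allelic richness *Rs*, *H*<sub>O</sub>,
unbiased gene diversity *Ĥ*); Guo–Thompson Monte-Carlo exact
Hardy–Weinberg tests; Weir–Cockerham multi-allelic *F*<sub>ST</sub>/*F*<sub>IS</sub>;
a Chakraborty-style null-allele screen; a Structure-style Bayesian admixture
MCMC (admixture model, independent or correlated allele frequencies) with
Evanno's ΔK model selection and exhaustive label-switching alignment across
runs; and a permutation test on ΔQ̄, the difference in mean cluster
membership between individuals carrying different mitochondrial lineages —
the statistic that directly asks whether mitochondrial ancestry predicts
nuclear ancestry.

Calibrated synthetic-data generators (star-genealogy barcodes,
Balding–Nichols genotypes, moment-matched membership coefficients) make the
whole pipeline testable offline, and `run_pipeline()` drives the full
workflow from one configuration.

## Worked example

```r
library(lineagemix)

# simulate a two-lineage cohort at the study scale (55 + 29 bats, 384 bp)
sim <- simulate_mtdna(seed = 42)
refs <- lineage_references(c("Western", "Eastern"), sim$truth$founders)
assignments <- assign_lineages(sim$records, refs)
table(assignments$lineage)
#> Eastern Western
#>      29      55

collapse_haplotypes(sim$records)
#> haplotype_set: 4 haplotypes from 84 sequences

west <- sim$records[assignments$lineage == "Western"]
fit <- fit_expansion(mismatch_distribution(west))
fit <- bootstrap_expansion_test(west, fit, n_iter = 200, seed = 1)
#> tau = 0.037 (95% CI 0.000-0.115), SSD = 0.0000, p = 0.63

cal <- dating_calibration(distance = 0.061, divergence_years = 1.8e6,
                          fragment_length = 384, generation_years = 1)
date_expansion(fit$tau, cal, fit$tau_ci)
#> expansion time: 2834 years (95% CI 0-8850)

# do mitochondrial lineages predict nuclear cluster membership?
q <- simulate_q_values(seed = 42)   # two groups of membership coefficients
permutation_test_delta_q(q$values, q$labels, n_perm = 100000, seed = 43)
#> delta-Qbar = 0.283, one-sided p = 3.00e-05
```

The expansion fit says the Western-lineage mismatch distribution is
compatible with a recent sudden expansion (bootstrap p = 0.63, no
rejection); with the 6.1%/1.8-Mya calibration its τ translates to an
expansion a few thousand years ago. The permutation test says a ΔQ̄ of 0.28
between the two lineage-defined groups essentially never arises when 60/38
groups are drawn at random from the pooled values — mitochondrial lineage
carries a real (if modest) nuclear signal.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the one-sided
100,000-resample permutation p-value for ΔQ̄ between two groups simulated to
match the published group moments (0.60 ± 0.34, n = 60 versus 0.28 ± 0.23,
n = 38), and writes it as JSON.
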