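---
title: "Methods: dual-marker tests of lineage interbreeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-marker tests of lineage interbreeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

A DNA barcode survey that finds two haplogroups separated by several percent
sequence divergence inside one nominal species faces a fork: cryptic
species, or deep intraspecific polymorphism. Mitochondria are inherited
clonally through females, so barcode divergence measures the age of the
maternal lineages, not reproductive isolation. The decisive evidence is
nuclear: if bats (or any diploids) carrying the two barcodes draw their
nuclear alleles from one pool, they are one biological species.
`lineagemix` implements both halves of that argument and the statistic that
joins them.

## Mitochondrial model and procedures

**Lineage assignment.** Because within-lineage diversity is tiny relative
to the between-lineage gap (~1–2 versus ~20 mutations on a 384-bp
fragment), a Bayesian phylogeny is unnecessary: each query is assigned to
the nearest user-supplied reference sequence if within `max_distance`
(default 2) mutations, else `"unassigned"`; exact ties return
`"ambiguous"` rather than an error, so downstream code can treat them as a
category. This nearest-reference rule replaces tree inference by design;
it is exactly what makes assignment "trivial" in the regime the package
targets, and it fails loudly (unassigned) outside that regime.

**Distances.** K2P distances are computed from the transition fraction
$P$ and transversion fraction $Q$ over compared sites,
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$, with pairwise deletion:
sites carrying `N`, gaps or ambiguity codes in either sequence are dropped.
The source material is silent on missing-data handling; pairwise deletion
is the default of the distance software ecosystem and wastes the least
data. Saturated pairs ($1-2P-Q \le 0$ or $1-2Q \le 0$) raise an error
rather than returning `NaN`.

**Transition/transversion bias.** $R$ is estimated by pooling $P$ and $Q$
over all pairs and decomposing the K2P distance into its transitional
component $A = \tfrac12\ln\frac{1}{1-2\bar P-\bar Q} -
\tfrac14\ln\frac{1}{1-2\bar Q}$ and transversional component
$B = \tfrac12\ln\frac{1}{1-2\bar Q}$, with $R = A/B$. This equals the rate
ratio $\alpha/2\beta$ of the K2P model and tends to $\bar P/\bar Q$ at
small distances. A maximum-likelihood estimator (as in MEGA) can differ
slightly from this pooled-moments decomposition; on near-star data the
difference is far below the tolerances used anywhere in the package.

**Median-joining networks.** The network starts from the
$\varepsilon$-relaxed minimum spanning network (the union of all minimum
spanning trees at $\varepsilon = 0$) and iteratively adds quasi-median
vectors of linked triplets when they strictly reduce the total spanning
weight, keeping the candidates within $\varepsilon$ of the minimal
connection cost per round; median nodes whose removal does not increase the
spanning weight are pruned. Sites where all three triplet members disagree
expand to all three states only while the number of such sites is at most
3 (bounded blow-up); beyond that the first sequence's state is kept. For
the intraspecific, low-divergence data this package targets, three-way
polymorphic sites within a triplet are rare, and the brute-force Steiner
oracle in the test suite checks minimality on small cases.

**Mismatch distributions and expansion fitting.** The observed histogram of
pairwise differences is fitted by least squares with the sudden-expansion
(Rogers–Harpending) expectation $F_j(\tau, \theta_0, \theta_1)$, which
approaches Poisson($\tau$) as $\theta_0 \to 0,\ \theta_1 \to \infty$. The
software the source study used fits a *spatial* expansion with an extra
migration parameter; only $\tau$ is carried forward into dating, and the
two families share the interpretation of $\tau$, so the sudden-expansion
family was adopted as the desk-scale implementable deviation. Its
goodness-of-fit $p$-values are therefore only approximately comparable to
the spatial-model ones; no test in the package asserts those published
p-values. The fit minimises the SSD between observed relative frequencies
and $F_j$ by a coarse grid over $(\tau, \theta_0, \theta_1)$ followed by
bounded quasi-Newton refinement from the best starts; SSD ties break toward
the smallest $\tau$. The point estimate is the least-squares $\tau$, not a
distribution mode.

**Bootstrap.** The parametric bootstrap simulates datasets of the same
size and fragment length under a star genealogy: each tip receives
Poisson($\hat\tau/2$) private mutations (so expected pairwise differences
equal $\hat\tau$), transitions favoured with odds $R\!:\!1$. Each replicate
is refitted; $p = \Pr(\mathrm{SSD}_{sim} \ge \mathrm{SSD}_{obs})$ and the
$\tau$ CI is the 2.5/97.5 percentile interval of refitted values. The star
genealogy matches the expansion regime the model itself assumes; it is not
a general coalescent (see Limitations).

**Dating.** $\tau = 2T\mu$ with
$\mu = \frac{d_{between}}{2\,T_{div}} \cdot L \cdot g$ per fragment per
generation. The worked-example calibration (between-lineage K2P 6.1%,
divergence 1.8 Mya, $L = 384$, one-year generations) reproduces the
published expansion times to within 0.1%. Dating is exactly linear in
$\tau$, which the test suite asserts.

## Nuclear model and procedures

**Diversity.** Gene copies are $n_g = 2\times$ typed individuals. Unbiased
gene diversity is $\hat H = \frac{n_g}{n_g-1}(1-\sum p_i^2)$; rarefied
allelic richness uses the hypergeometric expectation
$Rs = \sum_i [1 - \binom{n_g-c_i}{g}/\binom{n_g}{g}]$ with default
$g = 2\times$ the smallest typed sample across loci (the Fstat convention —
it makes $Rs = A$ for the smallest sample, as in the motivating study's
table). Monomorphic loci report $H_O$ and $\hat H$ as missing-with-flag and
are excluded from column means; that exclusion is itself verified against
the published table arithmetic in a test.

**Hardy–Weinberg.** A Monte-Carlo exact test: gene copies are shuffled into
diploid genotypes and the conditional table probability (proportional to
$2^{het}/\prod n_{ij}!$ given allele counts) compared with the observed
one; $p = (1 + \#\{P_{sim} \le P_{obs}\})/(n_{MC}+1)$. Which exact variant
the original software ran is unstated; the Monte-Carlo exact test is the
standard conservative choice and is validated against a closed-form
two-allele enumeration oracle plus a 1000-replicate calibration.

**F-statistics.** Weir–Cockerham variance components (per allele, summed
over alleles and loci) rather than the AMOVA $\Phi$ formulation: standard
for microsatellites and structurally equivalent, but a small numeric
difference from AMOVA-based outputs is expected and documented. Pairwise
$F_{ST}$ is computed pair by pair; per-cluster $F_{IS} = 1 - c/(b+c)$ from
within-cluster components. Loci entirely missing in one cluster of a pair
are skipped with a warning.

**Admixture MCMC.** The Gibbs sampler augments the data with the origin
cluster of every allele copy. Updates: origins $Z$ multinomial given
$(P, Q)$; frequencies $P$ Dirichlet($\lambda$ + counts) under the
independent model or Dirichlet($p_A(1-F_k)/F_k$ + counts) under the
correlated (F-)model, whose ancestral frequencies $p_A$ (mass-shuffling
Metropolis, Dirichlet($\lambda$) prior) and drift parameters $F_k$
(logit random walk, Uniform(0,1) prior — the original software's gamma
prior is not reproduced, and with informative data the influence is minor)
are sampled too; memberships $Q$ Dirichlet($\alpha$ + counts); $\alpha$ by
log-scale random walk under a Uniform(0, 10) prior. Missing calls
contribute nothing to any count. $L(K)$ is summarised as
mean $-$ variance/2 of the per-sweep data log-likelihood — the "estimated
ln probability of data" that Evanno's $\Delta K$ consumes. The correlated
model is the default (it mirrors the motivating analysis); the independent
model is retained because its updates are exactly conjugate, which makes it
the cleaner object for testing.

**Run combination.** $\Delta K$ needs several runs per $K$; cluster labels
switch between runs, so aligned consensus memberships are produced by
exhaustively matching column permutations ($K \le 8 \Rightarrow \le
40{,}320$ permutations) against an incrementally built reference — exact at
this scale, unlike stochastic large-K heuristics.

**The $\Delta\bar Q$ permutation test.** The joining statistic: the
difference in mean membership (for a designated cluster column) between
individuals carrying the two mitochondrial lineages. The null re-partitions
the pooled memberships into groups of the original sizes by sampling
without replacement — complementary partitions whose sizes sum to the pool,
which is how the published group sizes (60 + 38 = 98) read most naturally.
The add-one estimator $(1+\#)/(n_{perm}+1)$ keeps $p$ off zero and makes
the test exactly level-$\alpha$ under the null; an exhaustive-enumeration
mode exists for small pools and anchors the sampler in tests. Which column
is "the" cluster of interest is information the user has (plot colours,
biology); if unspecified, the column maximising $|\Delta\bar Q|$ is chosen
and flagged as exploratory in the output.

## The synthetic world

The generators' defaults are the stated conditions of the motivating study,
not knobs: 55 + 29 barcodes of 384 bp with ~20 fixed between-lineage
differences, $R = 5.46$, per-lineage $\tau$ of 0.09267/0.14595; five
microsatellite loci; membership groups with moments $0.60 \pm 0.34$
($n=60$) and $0.28 \pm 0.23$ ($n=38$). Where a value is not stated, one
realistic choice was made once: 10 ancestral alleles per simulated locus
(microsatellite panels in this size range typically carry ~8–17 alleles)
and drift $F = 0.2$ for the default two-population scenario (the
between-continent differentiation band of the study).

What the generators emulate — and do not:

* **Star genealogies**, not a coalescent. Appropriate for the
  recent-expansion regime and analytically transparent
  ($E[\text{pairwise diff}] = \tau$ within, $\approx D + \tau$ between),
  but they understate the variance of deep genealogies; a green
  $\tau$-recovery test says the estimator is unbiased under the expansion
  model, not under arbitrary demography.
* **Back-mutation is allowed** (sites can be hit twice), so expectations
  are approximate at large $\tau/L$; all quoted tolerances absorb this at
  the defaults.
* **Exchangeable allele labels**, no stepwise mutation ladder: every
  downstream statistic used is label-invariant, which a test asserts.
* **Beta moment matching** for membership coefficients reproduces the two
  group moments, not the full shape of a real consensus-Q distribution.

## Numerical choices

* Expansion fit: grid $\tau \in [0, 2(J+1)]$ (21 points, plus the observed
  mean), $\theta_0 \in \{0, 0.5, 2\}$, $\theta_1 \in \{1, 10, 1000\}$;
  4 best starts refined by `nlminb` with bounds
  $\tau \in [0, 8(J+1)]$, $\theta_0 \in [0, 100]$,
  $\theta_1 \in [10^{-3}, 10^5]$; ties broken toward smaller $\tau$.
* Degenerate inputs: all-identical sequences fit $\tau = 0$ with SSD 0 and
  bootstrap $p = 1$; monomorphic loci give HWE $p = 1$ and flagged
  diversity cells; $K = 1$ MCMC runs return all-ones memberships but a
  real likelihood.
* All stochastic operations take an explicit integer seed (default 0);
  pipeline stages derive their seeds deterministically from the master
  seed and the stage name, so re-running one stage reproduces its output
  even after unrelated pipeline edits.
* Probabilities are accumulated in log space (`lchoose`, `lgamma`) wherever
  counts can be large.

## Scaling in the shipped tests

The package defaults are the study-scale parameters (110,000 MCMC sweeps,
20 runs, $10^4$ bootstrap iterations, $10^5$ permutations). The shipped
test suite and pipeline smoke tests run the same code at reduced chain
lengths and iteration counts (hundreds to thousands) so the whole suite
completes in minutes; parameter-recovery tolerances were chosen for those
reduced settings *a priori* from the simulators' analytic expectations, not
tuned afterwards.

## Known limitations

* The expansion goodness-of-fit $p$ is not exchangeable with the spatial
  expansion model's; treat published spatial-model p-values as a
  qualitative, not numeric, comparison.
* The admixture sampler is plain R, adequate for ~100 individuals × 5–20
  loci; it is not a replacement for compiled samplers on genome-scale
  panels, and it implements neither the linkage model nor location priors.
* Spatially explicit clustering (Voronoi-prior models) is out of scope;
  F-statistics are computed on externally supplied cluster labels instead.
* The nearest-reference assigner presumes the reference pair spans the
  observed lineages; novel deep lineages surface only as `"unassigned"`.
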