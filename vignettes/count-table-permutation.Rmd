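---
title: "Permutation nulls for count-table interaction measures: method and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation nulls for count-table interaction measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countperm)
```

## The problem

Entropy-based measures of two-SNP–phenotype interaction (multi-information,
mutual-information variants, synergy scores, and the like) have no clean
analytic null distribution, so their significance is usually assessed by
permutation: shuffle the phenotype labels, recompute the statistic, repeat.
Every such statistic considered here is a function of a single sufficient
statistic, the $3\times3\times2$ count table

$$c_{ijk} = \#\{\text{individuals with SNP}_1 = i,\ \text{SNP}_2 = j,\
\text{phenotype} = k\},$$

with $i, j \in \{0,1,2\}$ (homozygous major, heterozygous, homozygous
minor) and $k \in \{0,1\}$. In a pairwise genome scan the tables — not the
entropies — dominate the cost: a naive permutation test re-tallies each
table from the raw $n \times m$ genotype matrix at $O(n)$ per permutation
per pair.

## The direct table transform

Two facts make the naive loop unnecessary. Under any permutation of the
phenotype labels:

1. the genotype cell counts $n_{ij} = c_{ij0} + c_{ij1}$ are unchanged, and
2. the phenotype-0 total $n_0 = \sum_{ij} c_{ij0}$ is unchanged.

So a permuted table is fully determined by its phenotype-0 layer, and that
layer can be sampled directly. Fix any order over the nine genotype cells.
The first cell receives $c^*_{ij0} \sim
\mathrm{Hypergeometric}(n,\, n_0,\, n_{ij})$ — drawing the cell's $n_{ij}$
labels without replacement from the pool of $n$ labels of which $n_0$ are
zeros. Each subsequent cell draws from what remains:

$$c^*_{ij0} \sim \mathrm{Hypergeometric}\!\Big(n - \textstyle\sum_{\text{prior}} n_{i'j'},\;
n_0 - \sum_{\text{prior}} c^*_{i'j'0},\; n_{ij}\Big),$$

and $c^*_{ij1} = n_{ij} - c^*_{ij0}$. This is exactly the distribution of
a uniformly label-permuted table — not an approximation — because drawing
labels without replacement cell by cell is a sequential description of a
uniform random placement of the $n_0$ zero labels. The package's test
suite verifies this against an exhaustive enumeration of all
$\binom{n}{n_0}$ label placements at small $n$, and against large naive
ensembles via Epps–Singleton tests at realistic $n$.

The cost per permuted table is at most nine hypergeometric draws,
independent of $n$; `sample_ensemble()` additionally vectorizes the draws
across the whole ensemble, so a batch of $N_p$ tables costs nine vectorized
draw calls. The naive route (`naive_ensemble()`) is retained as the
reference oracle.

Two deliberate consequences of this design:

- **Cell order is cosmetic.** Exchangeability of the label placement means
  any assignment order gives the same joint distribution; `cell_order()`
  is configurable and an Epps–Singleton test across two orders is part of
  the suite. The default visits cells column-major over the genotype grid.
- **No independence shortcut.** The marginal law of every cell is
  $\mathrm{Hypergeometric}(n, n_0, n_{ij})$, and at large $N_p$ each looks
  temptingly normal, but the cells are negatively correlated through the
  shared label pool. Sampling cells independently (the package's
  `binomial_ensemble()` negative control) violates the conservation law
  $\sum_{ij} c^*_{ij0} = n_0$ on almost every draw and is reliably
  rejected by the validation suite — evidence that the suite has power,
  so its passes are meaningful.

Degenerate inputs flow through the same loop: $n_0 = 0$ or $n_0 = n$
forces every draw, an empty genotype cell ($n_{ij} = 0$) contributes a
deterministic zero and no random draw, and the final populated cell's draw
is mathematically forced yet still routed through the sampler so that
edge parameters stay exercised.

## Interaction measures

All shipped measures are functions of the entropy profile — the plug-in
Shannon entropies of each variable, each pair, and the triple, in bits
(log base 2; the base is a convention and rescaling by $\ln 2$ gives
nats). The registry ships multi-information

$$\Omega = H_1 + H_2 + H_3 - H_{123},$$

which is zero iff the two SNPs and the phenotype are jointly independent.
Users can register any other entropy functional with
`register_measure()`; measures written with vectorized arithmetic
evaluate over whole null ensembles at no extra cost.

Numerical choices: probabilities are the maximum-likelihood counts$/n$
(no shrinkage or bias correction — the plug-in estimator keeps the
observed statistic and its permutation null on exactly the same footing);
$0 \log 0$ is handled by masking zero cells rather than adding a
pseudocount, which would bias $\Omega$ away from zero. The plug-in
estimator is biased upward at finite $n$ (roughly degrees-of-freedom
$/\,2n\ln 2$); the suite checks that the null mean of $\Omega$ decreases
with $n$ over $n \in \{100, 1000, 10000\}$. Because observed value and
null are computed identically, this bias cancels out of the empirical
p-value.

## Significance

`null_distribution()` evaluates a measure over a transformed ensemble;
`empirical_pvalue()` uses the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + N_p)$ — ties count
toward the tail, the smallest attainable value is $1/(N_p+1)$, and the
estimator is never anti-conservative. The tail is one-sided upper, since
all shipped measures are non-negative dependence scores. `scan_pairs()`
builds each pair's table once from the genotype matrix and never touches
the matrix again; each pair's RNG sub-stream is derived from the scan
seed and the pair's row index, so results are reproducible and
independent of execution order. No multiple-testing correction is
applied: the scan reports raw permutation p-values and leaves
Bonferroni/BH (or adaptive permutation schemes, which are out of scope)
to the caller.

## The synthetic generator

`generate_snp()` draws genotypes under perfect Hardy–Weinberg equilibrium
with minor allele frequency $p$: $P(0) = p^2$, $P(1) = 2p(1-p)$,
$P(2) = (1-p)^2$; `generate_phenotype()` draws labels with
$P(0) = q$. The package's reference scenario is $p = 0.45$, $q = 0.66$,
$n = 10{,}000$ — the regime of the stored example table
(`example_count_table()`).

A note on coding conventions: with genotypes labeled by minor-allele
count, some toolchains emit the opposite homozygote labeling
($P(0) = (1-p)^2$). The generator implements the $P(0)=p^2$ convention
stated above and documents it; for the permutation machinery and for any
relabeling-invariant measure (including $\Omega$, which the suite checks
is invariant under category relabeling), the choice is immaterial.

The generator is null-only by design: SNPs are independent (no linkage
disequilibrium), the phenotype is independent of both SNPs (no main
effects, no epistasis), there are no covariates, no missingness, and no
quantitative traits. That is precisely what is needed to validate a
permutation null and to calibrate type-I error; passing these checks says
nothing about power on real data, about LD-induced dependence between
neighboring tests, or about confounding — those properties must be
assessed on data with the corresponding structure. Missing values are
accepted by all tallying code (complete-case per tuple) but never
generated.

## Validation protocol

`run_equivalence_trial()` generates one null table, samples $N_p$
permuted tables with both the transform and naive shuffling, and compares
the two samples of $c^*_{ij0}$ for each of the nine cells with a
two-sample Epps–Singleton test. The test is built on empirical
characteristic functions evaluated at $t = (0.4, 0.8)$ scaled by the
pooled semi-interquartile range (the conventional omnibus choice, kept at
its documented default) and is valid for discrete data — the reason it is
used here instead of a Kolmogorov–Smirnov test on integer counts. The
implementation applies the standard small-sample correction below 25
observations and was verified to numerical identity against an
independent reference implementation on frozen cases.

`run_equivalence_suite()` repeats this across trials with $p, q \sim
U(0.01, 0.99)$ and pools the per-cell p-values; under equivalence they
are uniform, checked by KS test and QQ plot. Cells whose pooled sample is
constant — empty genotype cells at extreme $p$, or near-degenerate label
splits at extreme $q$ — admit no distribution test and are excluded and
counted (`n_applicable`), so the nominal nine-per-trial p-value count
holds only when all cells are populated; at $n = 10^4$ and moderate
parameters, empty cells are vanishingly rare.

Problem sizes: routine validation runs 100 trials of 200 permutations at
$n = 10^4$ (the package's default suite size, giving several hundred
pooled p-values in seconds), with the exact-enumeration check at
$n \le 8$ over $2\times10^5$ transforms and the moment-law check over
$10^5$ transforms of the reference table. A full-scale run — 1000 trials
of 1000 permutations, giving 9000 pooled p-values, and $10^6$-table
overlays — is available through the same functions' arguments and the
`validate` CLI subcommand.

## RNG contract

All stochastic entry points take an optional integer `seed`; seeded calls
restore the caller's RNG state on exit, so package calls never perturb a
user's simulation stream. Unseeded calls consume the ambient RNG stream,
the normal R idiom. Scans derive one sub-seed per pair from
(`seed`, row index) via a fixed 32-bit linear map — reproducible,
order-independent, and safe for parallel chunking (identical results to
sequential execution).

## Known limitations

- The contract is fixed at $3\times3\times2$: biallelic SNPs, binary
  phenotype. The iterative construction generalizes (multivariate
  hypergeometric layers for multi-class phenotypes; higher-order tuples),
  but none of that is implemented or validated here.
- Per-tuple nulls are computed independently even when tuples share
  margins; pooling nulls across margin-identical tuples would be a
  further optimization.
- No adaptive early stopping: every pair receives its full $N_p$
  permutations.
- The Epps–Singleton p-value is asymptotic; at the suite's $N_p \ge 100$
  per sample this is unproblematic, but very small ensembles are refused
  rather than tested.
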