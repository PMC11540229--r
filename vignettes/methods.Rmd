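---
title: "Methods: models, estimators and simulation design in aneuscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and simulation design in aneuscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuscreen)
```

# Overview

`aneuscreen` analyses pooled competitive fitness screens in which every
strain in a pool carries one barcoded low-copy plasmid bearing one extra
gene copy, and the pool is grown competitively for a known number of
generations in different cellular contexts: wild type versus an
*ssd1*-null background, euploid versus disomic (one extra chromosome).
Barcode abundance is read out by amplicon sequencing before and after
growth. The package provides

1. a **mechanistic simulator** of pooled growth with full ground truth,
2. **barcode quantification** from FASTQ by exact matching,
3. **fitness estimation** (filtering, normalization, log2 fold-change
   scores, moderated-*t* significance),
4. **gene-set calling** rules for context-specific detrimental,
   ameliorated and beneficial duplications plus hypergeometric
   enrichment,
5. a **cumulative-burden model** relating a chromosome's fitness cost to
   the summed single-gene duplication effects of the genes it carries,
6. a **multiplicative-null interaction test** for drug-by-aneuploidy
   (and drug-by-*ssd1*) epistasis in growth-rate data.

This vignette states each model precisely, lists parameters with units
and defaults, and explains the design decisions behind the simulator and
the validation strategy.

# The generative model of pooled growth

## Deterministic core

Let $N_g(t)$ be the number of cells carrying plasmid $g$ after $t$
generations of pooled growth, and let $s_g$ be the **per-generation
fitness effect** of carrying that plasmid in the current cellular
context, on the log2 scale. A neutral plasmid has $s_g = 0$ and doubles
once per generation; the pool evolves as

$$N_g(t + 1) = N_g(t) \cdot 2^{\,1 + s_g}.$$

Only relative abundance is observable, so the simulator works with pool
fractions $p_g(t) = N_g(t) / \sum_h N_h(t)$, propagated in log space by
`evolve_abundance()` for numerical stability. After $G$ generations the
expected log2 fold change of the normalized abundance of gene $g$
relative to the pool is $G \cdot s_g$ plus a constant absorbed by
normalization. The fitness score defined below therefore estimates
$G s_g$, and $s_g$ itself is recovered by dividing by the number of
generations.

The truth object (`sim_truth()`, `make_truth()`) stores one $s_g$ per
gene and per cellular context. The four contexts are fixed and exported
as `CELL_CONTEXTS`: `wt_euploid`, `ssd1d_euploid`, `wt_aneuploid`,
`ssd1d_aneuploid`. `make_truth()` plants, on top of a neutral majority
with deleterious and beneficial exponential tails, two context-specific
gene sets with known membership:

* an **ssd1-sensitive** set, penalized in every context except the wild
  type euploid (duplications tolerated only when Ssd1 is present and the
  cell is euploid), and
* an **aneuploid-beneficial** set, boosted only in the *ssd1*-null
  aneuploid.

These planted sets are the ground truth for testing the gene-set calling
rules.

## Stochastic layers

Four noise layers separate the truth from the observed counts:

1. **Transformation-stock founding.** The initial pool fractions are
   drawn once per independent transformation stock with lognormal
   founder noise (`init_sd`, log2 scale, default 0.25). The
   generation-0 sample of a stock and all later samples of that stock
   share this founding draw; different stocks do not.
2. **Per-stock effect noise** (`stock_sd`, log2 per generation, default
   0.03): a gene's realized $s_g$ in a stock deviates from the truth,
   modelling stock-specific plasmid integrity or copy-number drift.
3. **Per-replicate effect noise** (`rep_sd`, log2 per generation,
   default 0.01): additional deviation in each grown culture.
4. **Sequencing sampling.** Reads are drawn multinomially at the
   configured depth; setting `overdispersion` to a finite value switches
   to a Dirichlet-multinomial with that precision parameter, modelling
   PCR jackpotting. The default `Inf` is plain multinomial sampling.

Two structural effects are also modelled: plasmids whose insert lies
close to a centromere can mis-segregate as dicentrics and suffer a fixed
per-generation penalty in aneuploid hosts (`dicentric_loss`, default
0.15 log2 per generation, applied to a fraction
`frac_centromere_adjacent` = 0.02 of genes), and a configurable number
of genes may be represented by more than one plasmid
(`n_multi_plasmid_genes`), which the scoring pipeline excludes as
ambiguous.

## What the simulator does and does not emulate

It **emulates**: exponential competitive growth, shared founding
structure within a transformation stock, per-stock and per-replicate
effect noise, finite sequencing depth with optional overdispersion,
context-dependent fitness, centromere-proximity artefacts, and
chromosome-level growth-rate burden (below).

It **does not emulate**: plasmid loss dynamics within a culture,
frequency-dependent selection or cross-feeding, read errors in the
barcode (quantification is exact-match by design, and mutated barcodes
simply drop out as unmatched), batch effects in library preparation
beyond what depth differences capture, or cell-cycle and lag-phase
structure — growth is generation-synchronous by construction.

## Simulation parameters

All defaults live in `sim_config()`:

| parameter | default | units / meaning |
|---|---|---|
| `n_genes` | 4872 | pool size (plasmids) |
| `generations` | 10 | pooled doublings between samples |
| `replicates` | 3 | grown cultures per strain |
| `n_stocks` | `replicates` | independent transformation stocks |
| `depth` | 3e6 | reads per sample |
| `seed` | 1 | RNG seed |
| `frac_deleterious`, `frac_beneficial` | 0.10, 0.02 | fraction of genes in each tail |
| `effect_scale_deleterious`, `effect_scale_beneficial` | 0.05, 0.02 | exponential-tail scale, log2/generation |
| `context_set_sizes` | 200, 100 | planted ssd1-sensitive / aneuploid-beneficial genes |
| `context_effect_toxic` | 0.25 | planted penalty, log2/generation |
| `context_effect_beneficial` | 0.08 | planted boost, log2/generation |
| `init_sd` | 0.25 | founder noise, log2 |
| `stock_sd`, `rep_sd` | 0.03, 0.01 | effect noise, log2/generation |
| `overdispersion` | `Inf` | Dirichlet-multinomial precision (`Inf` = multinomial) |
| `dicentric_loss` | 0.15 | centromere-adjacent penalty in aneuploids, log2/generation |
| `frac_centromere_adjacent` | 0.02 | fraction of genes affected |
| `burden_coefficient` | 0.1 | growth-rate burden per unit cumulative score |
| `growth_noise_sd` | 0.02 | growth-rate replicate noise (rate units) |
| `baseline_rate` | 0.45 | euploid reference growth rate, 1/h |

The default pool size, depth and generation count are the package's own
choice of a realistic working point for a genome-scale yeast plasmid
pool sequenced on a mid-size flow cell; nothing in the estimators
depends on them.

## Why independent stocks are the default (`n_stocks = replicates`)

Replicates can be drawn either from a single shared transformation stock
or from independent stocks. With a shared stock the founding noise
(`init_sd`) is common to all replicates: every replicate's log2 fold
change contains the *same* founding error, the replicate errors are
positively correlated, the replicate variance understates the true
error, and the moderated-*t* test becomes anticonservative (in
simulations roughly 11% of truly neutral genes are flagged at a nominal
FDR of 0.05). With independent stocks each replicate's gene-specific
error is independent and the test is calibrated. The package therefore
defaults to one stock per replicate; the shared-stock design remains
available by setting `n_stocks < replicates`, and `fitness_scores()`
always pairs each grown sample with the generation-0 sample of **its
own** stock, which removes the founding error from each replicate's fold
change whenever that pairing exists.

# Fitness estimation

The pipeline (`score_experiment()`) applies, in order:

1. **Filtering** (`filter_barcodes()`): drop barcodes with zero total
   generation-0 counts, then the bottom 5% by total generation-0
   abundance (`floor(0.05 n)` barcodes; ties broken lexicographically so
   the filter is deterministic). Low founders have unstable fold
   changes.
2. **Pseudocount** (`add_pseudocount()`): add 1 read to every cell so
   log ratios are finite.
3. **TMM normalization** (`tmm_factors()`): trimmed mean of M-values
   with the standard trims (30% on log-ratios, 5% on average log
   abundance), computed via `edgeR::calcNormFactors()` with the
   reference column chosen as the sample whose upper-quartile fraction
   is closest to the mean. Composition-robust: a minority of strongly
   selected barcodes does not drag the scale of the unselected majority.
4. **Scores**: for each gene and replicate, the log2 ratio of normalized
   generation-$G$ abundance to the paired generation-0 abundance; the
   reported `score` is the replicate mean and estimates $G s_g$.
   Multi-plasmid genes are removed (recorded in an attribute).
5. **Significance** (`test_differential()`): one-sample moderated *t*
   against 0 (or a two-set contrast), with empirical-Bayes variance
   shrinkage via `limma::squeezeVar()` and Benjamini–Hochberg FDR.
   Replicate variances are floored at `1e-10` before shrinkage so
   degenerate zero-variance genes cannot produce infinite statistics,
   and a degenerate (infinite or undefined) shrinkage prior falls back
   to the unmoderated test.

## A note on TMM and exact depth invariance

If two samples have exactly proportional counts (pure depth difference),
normalized abundances should be identical. Plain library-size
normalization achieves this exactly. TMM's precision weights
$w = (n - x)/(nx) + (n_r - x_r)/(n_r x_r)$ depend on library size, so
TMM factors on proportional columns are only *approximately* 1 (the
weighted trimmed mean of exactly-zero log ratios is exactly 0, but after
the pseudocount the log-ratios are only near zero and the weights shift
slightly with depth). In practice the deviation is far below biological
noise (the test suite bounds it at $10^{-2}$ and verifies exact
invariance for the pure library-size path). This is a property of the
published TMM formula, not an implementation artefact; the
implementation is verified to machine precision against an independent
step-by-step coding of that formula.

# Gene-set calling rules

Let $f_{g,c}$ be the score of gene $g$ in strain $c$ and $q_{g,c}$ its
FDR. With defaults `fdr_threshold = 0.05`:

* **Detrimental in a focal strain** (`call_detrimental_in_focal()`):
  $f_{g,\text{focal}} < 0$, $q_{g,\text{focal}} < 0.05$, and
  $f_{g,\text{ref}} - f_{g,\text{focal}} > 1.5$ for at least one
  reference strain; the call is the union over references with
  provenance recorded. The 1.5 log2 margin demands a substantial
  context-specific drop, not merely significance.
* **Ameliorated in the aneuploid** (`call_ameliorated_in_aneuploid()`):
  the sign-mirror — detrimental in the euploid but at least 1.5 log2
  higher in the aneuploid.
* **Ssd1-sensitive** (`call_ssd1_sensitive()`): negative moderated
  contrast (ssd1-null minus wild type, pooled across contexts) at
  FDR < 0.05.
* **Beneficial in the ssd1-null aneuploid**
  (`call_beneficial_in_ssd1_aneuploid()`): strict mode requires the
  focal score to be significantly positive and to exceed *every*
  available reference strain by at least 0.5 log2; relaxed mode only
  requires it to be strictly higher. Strict calls are provably a subset
  of relaxed calls; a missing wild-type aneuploid reference is skipped.

Enrichment of a called set against annotation categories uses the
hypergeometric upper tail,
`phyper(k - 1, K, N - K, n, lower.tail = FALSE)`, with BH correction
across categories; the test suite verifies it against exhaustive
enumeration of all draws for every configuration with universe size
$\le 12$.

# The cumulative-burden model

For chromosome growth assays, `relative_fitness()` converts replicate
growth rates to rates relative to the euploid control, and the simulator
generates them as

$$\text{relative rate}(c) = 1 + \beta \sum_{g \,\in\, \text{chr } c} s_g + \varepsilon,$$

so a chromosome's cost is proportional to the **cumulative single-gene
duplication score** of the genes it carries (`cumulative_score()`).
`fit_burden_model()` regresses observed on predicted burden by OLS and
reports slope, intercept, $R^2$, adjusted $R^2$ and the overall *F*
*p*-value; chromosomes can be excluded (e.g. ones whose cost is known to
be dominated by a single gene). `permute_burden_r2()` provides a
chromosome-label permutation null; for $n$ points the null expectation
of $R^2$ is $1/(n-1)$, which the test suite checks. At zero growth noise
the fit recovers $\beta$ exactly, which is the package's structural
correctness check for this module.

# The multiplicative-null interaction test

For a drug (e.g. a microtubule poison) applied to euploid and aneuploid
strains, the null hypothesis is that drug and aneuploidy effects
multiply. With replicate-paired growth rates,
`expected_wt_aneuploid_ntc()` computes per replicate $i$

$$\hat r_i = r^{\text{aneu,ctrl}}_i \cdot
  \frac{r^{\text{eu,drug}}_i}{r^{\text{eu,ctrl}}_i},$$

and `expected_ssd1_aneuploid_ntc()` composes the *ssd1* effect with the
wild-type aneuploid drug response analogously.
`paired_interaction_test()` then runs a one-tailed paired *t* test of
observed versus expected (alternative "less": observed slower than the
multiplicative expectation indicates synergistic sensitivity), with
significance tiers `**`, `*`, `+` at $p < 0.01, 0.05, 0.1$. A variance
floor of $10^{-12}$ guards exactly-degenerate differences and is flagged
in the result. `simulate_ntc_null()` draws growth rates from an exactly
multiplicative world with lognormal replicate noise; 1000 such draws
show the test rejecting at its nominal 5% rate.

# Validation strategy

The test suite validates against **independent oracles**, not against
the implementation itself: a step-by-step coding of the published TMM
formula, exhaustive enumeration for the hypergeometric tail, closed-form
OLS, and brute-force set enumeration for overlaps. End-to-end checks use
the simulator's ground truth: score-versus-truth correlation, FDR
calibration on all-neutral pools, power on planted effects, Jaccard
recovery of planted gene sets, exact burden-coefficient recovery, and
interaction-test calibration.

Recovery checks deliberately set `stock_sd = rep_sd = 0` so that the
only error is sequencing sampling: this isolates the estimator's
structural correctness (any residual bias is the pipeline's fault, not
irreducible noise), while calibration and power checks keep noise on
where it is the quantity under test.

`scripts/acceptance.R` re-runs all of these computations from scratch
against the installed package and writes the headline numbers as JSON.

# Limitations

* Exact-match counting discards reads with any barcode error; with
  error-prone chemistry a mismatch-tolerant matcher would recover more
  depth (at the cost of collision handling).
* The moderated-*t* machinery assumes approximately normal replicate
  log fold changes; with very low counts a count-based GLM would be more
  appropriate.
* The burden model is linear by construction; saturating or epistatic
  chromosome-level burden would need a richer model.
* The interaction test's multiplicative null is one specific epistasis
  null; additive-on-rate alternatives are not provided.
* The simulator's generation-synchronous growth ignores lag and
  stationary phases, so absolute time calibration is out of scope.
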