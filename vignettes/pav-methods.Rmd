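---
title: "Coverage-based presence-absence variation calling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based presence-absence variation calling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavpan)
```

## The problem

In species with very high intraspecific structural variation — large
insertion/deletion polymorphisms segregating in natural populations — a
reference genome assembled from one individual contains regions that
other individuals carry on one haplotype (hemizygous), both (homozygous),
or neither (absent). Genes inside such regions show *presence-absence
variation* (PAV): the same gene can be entirely missing from some
individuals. The union of gene content across a population is a
pan-genome with a *core* set (present in everyone) and a *dispensable*
set (absent in at least one individual).

Read depth is the observable. If an individual's sequencing yields a mean
depth λ₁ per haplotype copy, then over a gene's exons the expected mean
depth is approximately 2λ₁, λ₁ or ~0 for two, one or zero copies. The
whole pipeline is built on that proportionality.

## Depth model and the synthetic generator

The package ships a generator whose output has the statistical structure
the analysis assumes, so every stage can be validated against known truth:

* **Architecture.** Dispensable genes occur in *blocks* of contiguous,
  co-inherited genes (emulating multi-kilobase hemizygous insertion
  blocks); each block has a haplotype allele frequency f, each of an
  individual's two haplotypes carries it independently with probability
  f, and the copy number is their sum — Hardy-Weinberg proportions
  ((1−f)², 2f(1−f), f²). Core genes have f = 1. Defaults: block sizes
  log-uniform over 1–25 genes; dispensable f uniform on (0.1, 0.9). A
  skewed Beta spectrum can be selected to produce rare/private genes,
  which is what drives open pan-genome accumulation.
* **Gene structure.** 1–5 exons of 150–400 bp, 200-bp introns, GC drawn
  around 32% (mollusk-like); genes are packed into blocks and blocks
  into ~25-block scaffolds. These are realism choices, fixed once; they
  are not fitted to any dataset.
* **Depth noise.** One depth value per `window` bp (default 100, a
  read-length proxy emulating read-level autocorrelation) drawn from a
  negative binomial with mean μ = c·λ + ε and variance μ + φμ²
  (dispersion φ, default 0.05; φ = 0 gives Poisson). ε (default 0.5X) is
  background mis-mapping depth, so absent regions are noisy-but-low
  rather than exactly zero; ε = 0 reproduces a clean zero peak. Windows
  are tiled *within* each copy-number segment, so a window never mixes
  two copy states.
* **Determinism.** Every stochastic operation takes a `seed` and restores
  the caller's RNG state; identical seeds give byte-identical outputs,
  including emitted files.

What the generator does *not* emulate — GC-dependent coverage bias,
mappability variation along real genomes, paralog cross-mapping,
reference errors, partial (exon-level) deletions — bounds what passing
tests mean: they validate the inference machinery under the stated depth
model, not its robustness to every artifact of real sequencing data.

## Calibration: locating the one-allele depth

Normalized coverage must mean "multiples of the one-allele expectation",
so each individual needs its λ₁ estimated. Two routes are provided.

**Stable-gene anchoring** (`calibrate_individuals()`, default). Genes
whose depth varies little across individuals (coefficient of variation
≤ 0.2) and never drops low relative to each individual's median (≥ 0.5)
are, with overwhelming probability, homozygous everywhere; up to 4,000
lowest-CV such genes are kept (all thresholds configurable). An
individual's median stable-gene depth is its homozygous expectation λ₂,
and λ₁ = λ₂/2. This estimator is nearly unbiased and is the default
because it exploits the cross-individual design directly.

**Peak pairing** (`estimate_depth_peaks()`). For a raw depth
distribution (per-base values, or per-gene means when no stable set is
available): exclude the zero peak (values below 0.15 × the positive
median — unmappable sequence), find the local maxima of a Gaussian KDE
(Silverman bandwidth), score candidate mode pairs by |log(ratio) − log 2|
(the homozygous:hemizygous ratio should be 2:1), and refine the winning
pair with a two-component mixture EM whose component means are reported
as (λ₁, λ₂). The 2:1 ratio is enforced on the refined means
([1.8, 2.2] by default, relaxable with `ratio_constraint = FALSE`).

Two numerical details matter. First, the *component family*: sequencing
depth is over-dispersed and right-skewed, and a Gaussian mixture lets the
wide homozygous component absorb the hemizygous component's right tail,
biasing both means low by several X. Integer count input therefore uses
negative-binomial components (on the lattice spacing actually present in
the data, which keeps the estimator scale-equivariant), while continuous
per-gene means — central-limit averaged and nearly symmetric — use
moment-matched gamma components. Second, the candidate gate is *loose*
(ratios 1.4–2.9): the raw KDE mode of a skewed component sits below its
mean, so a hard 2:1 gate on raw modes would reject genuinely 2:1 data.
Degenerate cases are defined rather than guessed: unimodal input is an
error under the ratio constraint unless a stable-gene prior disambiguates
which peak is missing; with the constraint disabled a single mode is read
as the homozygous peak, giving (mode/2, mode).

## Zygosity calls and the partition

With normalized coverage x (1.0 = one allele), the call is

* **0 (absent)** if x ≤ t_p, with t_p = 0.25 — i.e. the gene shows less
  than 25% of the depth expected for a hemizygous gene; equality counts
  as absent. The threshold is deliberately strict: it prioritizes
  high-confidence absence calls at the cost of some false "present"
  calls.
* **1 (hemizygous)** if t_p < x ≤ t_h,
* **2 (homozygous)** if x > t_h, with t_h = 1.5, the midpoint of the one-
  and two-allele expectations. Only the presence threshold has an
  external definition; the 1/2 boundary is this package's declared,
  configurable default and is recorded in every output.

Core = call ≥ 1 in every individual; dispensable = absent somewhere.
Genes annotated on accessory contigs (sequence absent from the reference
assembly, supplied as extra ids) are dispensable by definition. With a
single individual the partition degenerates to present/absent and is
emitted with a warning. The partition is asserted disjoint-and-exhaustive
on every run.

## Pan-genome growth and openness

`recursive_accumulate()` is the set-level abstraction of iterative
map-and-assemble pan-genome construction: starting from the reference
gene set, each individual contributes the genes not yet in the growing
pan-genome. Because the de novo assembly step itself is out of scope,
accessory content enters as gene sets plus a contig metadata filter
(taxonomy label, GC within [0.20, 0.50] around a 32% genome, depth
bounds, minimum length 500 bp; every removal reports the first failing
rule, checked in the order taxonomy, gc, depth, length).

`growth_curve()` averages the accumulation over random orderings of the
individuals (the endpoint is order-invariant; the path is not), and
`fit_openness()` fits the mean novel-gene increments to the
Heaps/Tettelin power law novel(N) = κ·N^(−α) by least squares on
log-log scale, excluding (and reporting) zero-increment steps and
requiring at least three positive ones. α < 1 means the cumulative count
diverges — an open pan-genome. The functional form, the zero-increment
exclusion and the α < 1 criterion are declared decisions; the fit is
exact on exact power-law input and recovers α = 0.5 within ±0.1 under
10% multiplicative noise over 15 steps.

## Mendelian segregation

A parent with c copies of a gene transmits it with probability c/2; the
offspring distribution is the product convolution, exact in rational
arithmetic (all probabilities are multiples of 1/4). The canonical case:
two hemizygous parents give (¼, ½, ¼) for 0/1/2 copies — the gene is
expected entirely absent in 25% of offspring. Observed family counts are
tested with an exact two-sided binomial test of the absent count against
that expectation, appropriate for the very small full-sib families of
controlled crosses. The two-sided p-value uses the minimum-likelihood
("minlike") convention — the sum of probabilities of all outcomes no more
likely than the observed one — stated explicitly because two-sided exact
conventions differ between implementations. The test is conservative at
small n; under a true null at α = 0.05 its rejection rate stays below
6%.

## Mapping artifacts and divergence

Could allelic divergence, rather than true absence, explain low coverage?
Under a fixed-read-length, independent-substitution model with an
end-to-end mapper tolerating m mismatches, retention is the binomial
lower tail r(L, d, m) = Σ_{k≤m} C(L,k) d^k (1−d)^(L−k). Observed
normalized coverage of a truly present gene is copies · r, and
`divergence_to_absence()` bisects for the smallest divergence pushing
that below t_p. For typical short-read settings (L = 100, m = 2) a
hemizygous gene needs per-base divergence of several percent — far above
plausible allelic divergence — before it would be miscalled absent,
which is the quantitative basis for excluding divergence artifacts.
Indels and local-alignment rescue are outside this model and noted as
such.

## Enrichment

Term enrichment of the dispensable set uses exact hypergeometric tails
(via R's `phyper`) with the universe defined as *all* genes in the
partition, including unannotated ones — the universe choice materially
changes p-values, so it is stated and configurable. Over- and
under-representation tails are BH-adjusted as separate families; a
direction is assigned when the corresponding q ≤ 0.05 *and* the fold
change agrees. Terms with fewer than 5 genes are skipped by default.

## Problem sizes and validation

The test suite validates each operation against an independent oracle:
exhaustive subset enumeration for hypergeometric tails, direct binomial
summation and Monte-Carlo simulation for retention, naive per-base
summation for exonic depth, hand step-up for BH, and simulated truth for
calls. The standard synthetic validation runs use 2,000 genes × 10
individuals at 40X per haplotype for call accuracy (≥ 99% per-cell
against truth), ≥ 10⁵ depth values for peak recovery (λ₁ within ±1X of
41.5X when the homozygous mode is 83X, and within 3% relative error in
general), and 10,000-offspring crosses for segregation fractions. These
sizes were chosen as the smallest at which the statistical tolerances
are comfortably non-trivial.

## Known limitations

* Depth is taken at face value: no mapping-quality filtering, GC
  correction, or multi-mapping resolution (all upstream concerns).
* No per-exon partial-deletion calling and no phasing; the unit is the
  whole gene.
* Calls carry no per-cell uncertainty; boundary genes near t_h are the
  dominant error mode at moderate depth.
* The openness fit extrapolates nothing: it classifies the observed
  curve, and gives no species-wide pan-genome size estimate.
* The divergence model is substitution-only with hard mismatch cutoffs.
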