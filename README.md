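# pavpan

Coverage-based detection of gene **presence-absence variation (PAV)** and
pan-genome analysis for diploid genomes, in R.

In highly heterozygous species — the motivating case is a marine bivalve
whose genome carries thousands of genes entirely missing from some
individuals — a large fraction of the genome is *hemizygous*: present on
only one of the two homologous chromosomes. Whole-genome resequencing
depth then becomes a copy-number signal. For an individual with
one-allele (haploid-equivalent) depth λ₁, a gene present on both
haplotypes averages ≈ 2λ₁ over its exons, a hemizygous gene ≈ λ₁, and an
absent gene ≈ 0. `pavpan` turns per-base depth tracks and gene
annotations into per-gene allele-count calls and everything downstream of
them.

## What it computes

1. **Coverage matrix** — mean exonic depth per gene per individual, from
   bedGraph depth tracks and a GFF3/BED12 annotation
   (`read_annotation()`, `read_depth_track()`, `build_matrix()`).
2. **Calibration** — each individual's hemizygous/homozygous depth peaks
   (λ₁, λ₂ ≈ 2λ₁). Either anchored on genes with stable coverage across
   individuals (`select_stable_genes()`, `calibrate_individuals()`), or
   estimated from the bimodal depth distribution by KDE mode-pairing
   refined with a two-component over-dispersed mixture EM
   (`estimate_depth_peaks()`). `normalize_matrix()` rescales so 1.0 = one
   allele.
3. **Zygosity calls** — a gene is *absent* when normalized coverage does
   not exceed t_p = 0.25 (25% of the hemizygous expectation),
   *hemizygous* up to t_h = 1.5, *homozygous* above (`classify_gene()`,
   `call_matrix()`). Genes present in every individual are **core**;
   genes absent in one or more are **dispensable**
   (`partition_core_dispensable()`).
4. **Pan-genome growth and openness** — permutation-averaged gene
   accumulation curves (`growth_curve()`) and a Heaps-style power-law fit
   to the novel-gene increments, novel(N) = κ·N^(−α); α < 1 marks an open
   pan-genome (`fit_openness()`). A rule engine filters accessory contigs
   by taxonomy/GC/depth/length before their genes join the pan-genome
   (`filter_contigs()`).
5. **Mendelian segregation** — exact offspring copy-number expectations
   for crosses (a hemizygous × hemizygous cross loses the gene in 25% of
   offspring) and an exact two-sided binomial test of observed family PAV
   patterns (`mendelian_expectation()`, `test_family()`).
6. **Mapping-artifact bounds** — the fraction of length-L reads a
   mismatch-limited mapper retains under allelic divergence d,
   r = Σ_{k≤m} C(L,k)·d^k·(1−d)^(L−k), and the minimal divergence at
   which a truly present gene would be miscalled absent
   (`retention_analytic()`, `divergence_to_absence()`).
7. **Enrichment** — hypergeometric over/under-representation of
   annotation terms among dispensable genes with per-direction BH FDR
   control (`enrich_partition()`).

A synthetic-data module (`build_pangenome_model()`,
`sample_population()`, `simulate_cross()`, `simulate_coverage_matrix()`,
`emit_dataset()`) generates diploid pan-genomes whose dispensable genes
sit in co-inherited hemizygous blocks, with negative-binomial depth
noise, so the whole pipeline can be exercised and validated against a
known truth — no external data needed. `run_pipeline(demo_config())` runs
everything end-to-end on such a dataset.

## Worked example

```r
library(pavpan)

model <- build_pangenome_model(n_core = 300, n_dispensable = 100, seed = 1)
pop   <- sample_population(model, n_individuals = 8, seed = 2)
mat   <- simulate_coverage_matrix(pop, coverage_config(lambda = 40), seed = 3)

cal <- calibrate_individuals(mat, target_count = 1000)
cal[["ind001"]]
#> pav_calibration 'ind001': lambda1 = 40.55X, lambda2 = 81.10X (stable-median)

z <- call_matrix(normalize_matrix(mat, cal))
z
#> pav_zygosity: 400 genes x 8 individuals (t_p = 0.25, t_h = 1.5)
#>   calls: 0 (absent) 186 | 1 (hemizygous) 329 | 2 (homozygous) 2685

partition_core_dispensable(z)
#> pav_partition: 319 core, 81 dispensable (0 on accessory contigs)
#>   mean missing per individual: 23.2 genes (5.81%)

fit_openness(growth_curve(presence_sets(z), n_permutations = 100, seed = 4))
#> pav_heaps_fit: novel(N) = 308.1 * N^(-3.689)  [R^2 = 0.992] -> closed pan-genome

mean(z$calls == pop$gene_copies)   # call accuracy against the simulated truth
#> [1] 0.9925
```

The calibration recovers the simulated one-allele depth (true value
40.5X: 40X per haplotype plus 0.5X background mis-mapping), 99.25% of the
3,200 gene-by-individual calls match the simulated copy numbers, and the
core/dispensable split mirrors the planted 3:1 architecture. With only
eight individuals and common dispensable alleles the accumulation curve
saturates (α > 1, "closed"); skewed allele-frequency spectra with rare
and private genes push α below 1, the open-pan-genome regime.

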