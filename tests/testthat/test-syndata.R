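test_that("pan-genome models satisfy their structural invariants", {
  m <- small_model(60, 20, seed = 3)
  g <- m$genes

  expect_setequal(unique(g$category), c("core", "dispensable"))
  expect_equal(sum(g$category == "core"), 60)
  expect_equal(sum(g$category == "dispensable"), 20)
  expect_true(all(g$freq[g$category == "core"] == 1))
  expect_true(all(g$freq[g$category == "dispensable"] > 0 &
                    g$freq[g$category == "dispensable"] < 1))

  # genes within one block share frequency
  by_block <- tapply(g$freq, g$block_id, function(f) length(unique(f)))
  expect_true(all(by_block == 1))

  # gene intervals within a scaffold do not overlap; exons inside scaffold
  for (sc in unique(g$scaffold)) {
    gs <- g[g$scaffold == sc, ]
    gs <- gs[order(gs$start), ]
    if (nrow(gs) > 1) expect_true(all(gs$start[-1] > gs$end[-nrow(gs)]))
    L <- m$scaffolds$length[m$scaffolds$scaffold == sc]
    ex <- m$exons[m$exons$scaffold == sc, ]
    expect_true(all(ex$start >= 1 & ex$end <= L))
  }

  # exon totals match the recorded exonic length
  tot <- tapply(m$exons$end - m$exons$start + 1L, m$exons$gene_id, sum)
  expect_equal(as.vector(tot[g$gene_id]), g$exonic_length)
})

test_that("model generation is deterministic and handles degenerate inputs", {
  expect_identical(small_model(seed = 7), small_model(seed = 7))
  m0 <- build_pangenome_model(30, 0, seed = 1)
  expect_true(all(m0$genes$category == "core"))
  expect_error(build_pangenome_model(10, 5, freq_sampler = list(dist = "nope")),
               class = "pavpan_config_error")
})

test_that("population copy numbers follow Hardy-Weinberg proportions", {
  m <- build_pangenome_model(0, 40, freq_sampler = list(dist = "fixed", value = 0.5),
                             block_size_sampler = 1, seed = 5)
  pop <- sample_population(m, 500, seed = 6)
  expect_identical(pop$block_copies, pop$H1 + pop$H2)
  props <- tabulate(pop$gene_copies + 1L, 3L) / length(pop$gene_copies)
  se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / length(pop$gene_copies))
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 3 * se))

  # degenerate frequencies
  m1 <- build_pangenome_model(10, 0, seed = 2)
  p1 <- sample_population(m1, 20, seed = 3)
  expect_true(all(p1$gene_copies == 2L))
})

test_that("crosses transmit one haplotype per parent per block", {
  m <- build_pangenome_model(5, 5, seed = 9)
  disp <- m$blocks$category == "dispensable"
  hemi <- individual_genotype(m, h1 = 1, h2 = ifelse(disp, 0, 1))
  homo <- individual_genotype(m, h1 = 1, h2 = 1)
  null <- individual_genotype(m, h1 = ifelse(disp, 0, 1), h2 = ifelse(disp, 0, 1))

  f1 <- simulate_cross(homo, homo, 50, seed = 1)
  expect_true(all(f1$block_copies == 2L))
  f2 <- simulate_cross(null, homo, 50, seed = 1)
  expect_true(all(f2$block_copies[disp, ] == 1L))

  # hemizygous x hemizygous: 25% absent, within 3 binomial SE
  f3 <- simulate_cross(hemi, hemi, 4000, seed = 2)
  frac0 <- mean(f3$block_copies[disp, ] == 0L)
  n <- sum(disp) * 4000
  expect_lt(abs(frac0 - 0.25), 3 * sqrt(0.25 * 0.75 / n))

  # transmitted-haplotype frequency from a hemizygous parent is 1/2
  frac_h <- mean(f3$H1[disp, ])
  expect_lt(abs(frac_h - 0.5), 3 * sqrt(0.25 / (sum(disp) * 4000)))

  expect_error(individual_genotype(m, h1 = 0, h2 = 0),
               class = "pavpan_validation_error")
  expect_identical(simulate_cross(hemi, hemi, 10, seed = 4),
                   simulate_cross(hemi, hemi, 10, seed = 4))
})

test_that("simulated depth respects the c*lambda + epsilon expectation", {
  m <- build_pangenome_model(20, 10, seed = 21)
  pop <- sample_population(m, 4, seed = 22)
  cfg <- coverage_config(lambda = 41.5, dispersion = 0.05, epsilon = 0)
  mat <- simulate_coverage_matrix(pop, cfg, seed = 23)

  for (i in seq_along(pop$individual_ids)) {
    for (cc in 0:2) {
      idx <- pop$gene_copies[, i] == cc
      if (!any(idx)) next
      vals <- mat$raw[idx, i]
      if (cc == 0) {
        expect_true(all(vals == 0))  # epsilon = 0: absent means exactly zero
      } else {
        mu <- cc * 41.5
        se <- sd(vals) / sqrt(length(vals))
        expect_lt(abs(mean(vals) - mu), 3 * se + 1e-9)
      }
    }
  }
})

test_that("emitted datasets round-trip exactly through the coverage reader", {
  out <- withr::local_tempdir()
  m <- build_pangenome_model(15, 5, seed = 31)
  pop <- sample_population(m, 3, seed = 32)
  cfg <- coverage_config(lambda = 30, dispersion = 0.05, epsilon = 0.5)
  manifest <- emit_dataset(pop, cfg, out, seed = 33)

  expect_true(file.exists(file.path(out, "annotation.gff3")))
  expect_true(file.exists(file.path(out, "truth.tsv")))
  expect_true(file.exists(file.path(out, "manifest.json")))

  in_memory <- simulate_coverage_matrix(pop, cfg, seed = 33)
  ann <- read_annotation(file.path(out, "annotation.gff3"))
  tracks <- lapply(pop$individual_ids, function(id) {
    read_depth_track(file.path(out, paste0(id, ".bedgraph")), id)
  })
  reread <- build_matrix(tracks, ann[rownames(in_memory$raw)])
  expect_equal(reread$raw, in_memory$raw, tolerance = 1e-12)

  truth <- read.table(file.path(out, "truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(truth), nrow(pop$gene_copies) * 3)
})
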