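make_gff3 <- function(path, genes) {
  # genes: list of list(id, scaffold, strand, exons = matrix(start, end))
  lines <- "##gff-version 3"
  for (g in genes) {
    span <- c(min(g$exons[, 1]), max(g$exons[, 2]))
    lines <- c(lines,
      sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g$scaffold,
              span[1], span[2], g$strand, g$id),
      sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$scaffold, span[1], span[2], g$strand, g$id, g$id),
      sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
              g$scaffold, g$exons[, 1], g$exons[, 2], g$strand, g$id))
  }
  writeLines(lines, path)
  path
}

test_that("GFF3 and BED12 annotations parse to the same exon sets", {
  dir <- withr::local_tempdir()
  gff <- make_gff3(file.path(dir, "a.gff3"), list(
    list(id = "gA", scaffold = "s1", strand = "+",
         exons = rbind(c(101, 200), c(301, 400))),
    list(id = "gB", scaffold = "s2", strand = "-",
         exons = rbind(c(51, 150)))
  ))
  ann <- read_annotation(gff)
  expect_named(ann, c("gA", "gB"))
  expect_equal(sum(IRanges::width(ann)[["gA"]]), 200)
  expect_equal(GenomicRanges::start(ann[["gA"]]), c(101, 301))
  expect_equal(GenomicRanges::end(ann[["gA"]]), c(200, 400))

  # equivalent BED12 (0-based half-open with feature-relative blocks)
  bed <- file.path(dir, "a.bed")
  writeLines(c(
    "s1\t100\t400\tgA\t0\t+\t100\t400\t0\t2\t100,100\t0,200",
    "s2\t50\t150\tgB\t0\t-\t50\t150\t0\t1\t100\t0"
  ), bed)
  ann_bed <- read_annotation(bed)
  expect_equal(lapply(ann_bed, GenomicRanges::granges),
               lapply(ann, GenomicRanges::granges))
})

test_that("overlapping exon records are merged to their union", {
  dir <- withr::local_tempdir()
  gff <- make_gff3(file.path(dir, "o.gff3"), list(
    list(id = "gO", scaffold = "s1", strand = "+",
         exons = rbind(c(101, 250), c(200, 300), c(500, 600)))
  ))
  ann <- read_annotation(gff)
  expect_equal(GenomicRanges::start(ann[["gO"]]), c(101, 500))
  expect_equal(GenomicRanges::end(ann[["gO"]]), c(300, 600))
})

test_that("gene_mean_depth averages depth over exonic bases", {
  # uniform depth over a single exon
  tr <- track_from_runs(data.frame(scaffold = "s1", start = 1, end = 1000,
                                   depth = 10))
  g1 <- exon_annotation("g1", "s1", 201, 700)[[1]]
  expect_equal(gene_mean_depth(tr, g1), 10)

  # weighted mean over two exons: 100 bp at 8X and 300 bp at 12X
  tr2 <- track_from_runs(data.frame(scaffold = "s1",
                                    start = c(1, 101), end = c(100, 1000),
                                    depth = c(8, 12)))
  g2 <- exon_annotation(c("g", "g"), c("s1", "s1"), c(1, 101), c(100, 400))[[1]]
  expect_equal(gene_mean_depth(tr2, g2), (800 + 3600) / 400)

  # scaffold absent from the track: zero-fill
  g3 <- exon_annotation("g3", "sX", 1, 500)[[1]]
  expect_equal(gene_mean_depth(tr, g3), 0)
})

test_that("run-length computation agrees with naive per-base summation", {
  set.seed(42)
  for (rep in 1:10) {
    n_runs <- sample(3:8, 1)
    ends <- cumsum(sample(5:50, n_runs, replace = TRUE))
    starts <- c(1L, head(ends, -1) + 1L)
    keep <- runif(n_runs) > 0.3  # leave gaps (implicit zero)
    runs <- data.frame(scaffold = "s1", start = starts[keep],
                       end = ends[keep], depth = sample(0:30, sum(keep), TRUE))
    tr <- track_from_runs(runs)
    L <- max(ends)
    n_ex <- sample(1:3, 1)
    es <- sort(sample(seq_len(L + 20), 2 * n_ex))
    gene <- exon_annotation(rep("g", n_ex), rep("s1", n_ex),
                            es[seq(1, 2 * n_ex, 2)], es[seq(2, 2 * n_ex, 2)])[[1]]
    expect_equal(gene_mean_depth(tr, gene), naive_gene_mean(tr, gene))
  }
})

test_that("build_matrix fills every cell, is order-invariant and linear", {
  tr <- track_from_runs(data.frame(scaffold = "s1", start = 1, end = 500,
                                   depth = 6), "i1")
  ann <- exon_annotation(c("gA", "gB"), c("s1", "s1"), c(1, 201), c(100, 400))
  m <- build_matrix(list(tr), ann)
  expect_equal(dim(m$raw), c(2L, 1L))
  expect_equal(m$raw["gA", "i1"], gene_mean_depth(tr, ann[["gA"]]))

  # permuting gene order permutes rows only
  m2 <- build_matrix(list(tr), ann[c("gB", "gA")])
  expect_equal(m2$raw[c("gA", "gB"), , drop = FALSE], m$raw)

  # scaling all depths by k scales every entry by k
  tr3 <- track_from_runs(data.frame(scaffold = "s1", start = 1, end = 500,
                                    depth = 18), "i1")
  m3 <- build_matrix(list(tr3), ann)
  expect_equal(m3$raw, 3 * m$raw)

  dup <- track_from_runs(data.frame(scaffold = "s1", start = 1, end = 10,
                                    depth = 1), "i1")
  expect_error(build_matrix(list(tr, dup), ann),
               class = "pavpan_validation_error")
})
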