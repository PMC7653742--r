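# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# A small pan-genome model reused by several suites.
small_model <- function(n_core = 60, n_dispensable = 20, seed = 11) {
  build_pangenome_model(n_core, n_dispensable, seed = seed)
}

# Depth track from explicit (scaffold, start, end, depth) runs
# (1-based closed, non-overlapping).
track_from_runs <- function(runs, individual_id = "indA") {
  rles <- lapply(split(runs, runs$scaffold), function(df) {
    df <- df[order(df$start), , drop = FALSE]
    gap <- df$start - c(0L, df$end[-nrow(df)]) - 1L
    vals <- as.vector(rbind(0, df$depth))
    lens <- as.vector(rbind(gap, df$end - df$start + 1L))
    S4Vectors::Rle(vals[lens > 0], lens[lens > 0])
  })
  depth_track(rles, individual_id)
}

# One-gene exon annotation as a GRangesList element set.
exon_annotation <- function(gene_ids, scaffolds, starts, ends) {
  gr <- GenomicRanges::GRanges(scaffolds, IRanges::IRanges(starts, ends))
  S4Vectors::split(gr, factor(gene_ids, levels = unique(gene_ids)))
}

# Brute-force oracle: expand the track to a per-base vector and average
# depth over the exonic positions of one gene.
naive_gene_mean <- function(track, gene) {
  scafs <- as.character(GenomicRanges::seqnames(gene))
  starts <- GenomicRanges::start(gene)
  ends <- GenomicRanges::end(gene)
  total <- 0; bases <- 0
  for (i in seq_along(starts)) {
    rle <- track$depth[[scafs[i]]]
    vec <- if (is.null(rle)) numeric(0) else as.numeric(rle)
    pos <- starts[i]:ends[i]
    depth <- ifelse(pos <= length(vec), vec[pmin(pos, length(vec))], 0)
    depth[pos > length(vec)] <- 0
    total <- total + sum(depth)
    bases <- bases + length(pos)
  }
  total / bases
}

# Zygosity object built directly from a copies matrix (bypasses the
# coverage layer when only call-level logic is under test).
zygosity_from_copies <- function(copies, t_p = 0.25, t_h = 1.5) {
  structure(
    list(calls = copies, normalized = copies, genes = rownames(copies),
         individuals = colnames(copies), t_p = t_p, t_h = t_h),
    class = "pav_zygosity"
  )
}

# The default synthetic fixture: simulate, calibrate, call; returns truth
# and calls for accuracy checks. `matrix` carries both layers.
called_fixture <- function(n_core, n_dispensable, n_individuals, lambda,
                           seed, dispersion = 0.05, epsilon = 0.5) {
  m <- build_pangenome_model(n_core, n_dispensable, seed = seed)
  pop <- sample_population(m, n_individuals, seed = seed + 1L)
  cfg <- coverage_config(lambda = lambda, dispersion = dispersion,
                         epsilon = epsilon)
  mat <- simulate_coverage_matrix(pop, cfg, seed = seed + 2L)
  cal <- calibrate_individuals(mat, target_count = 1000)
  nmat <- normalize_matrix(mat, cal)
  z <- call_matrix(nmat)
  list(model = m, population = pop, matrix = nmat, zygosity = z,
       truth = pop$gene_copies)
}

# Exhaustive subset-enumeration oracle for hypergeometric tails on small
# universes: counts over all C(N, n) draws.
hyper_enum_oracle <- function(N, K, n, x) {
  draws <- utils::combn(N, n)
  carriers <- seq_len(K)
  cnt <- apply(draws, 2, function(s) sum(s %in% carriers))
  list(p_over = mean(cnt >= x), p_under = mean(cnt <= x))
}
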