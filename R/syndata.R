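# Synthetic diploid pan-genomes with hemizygous blocks and over-dispersed
# depth tracks. Dispensable genes live in blocks that segregate as units:
# each haplotype carries a block with probability f, so per-individual gene
# copy number is 0, 1 or 2 and per-base depth scales with copy number.

# ---- distribution specs -----------------------------------------------------

# A sampler spec is either a function(n) or a list with a `dist` element:
# uniform(min,max), beta(shape1,shape2), loguniform(min,max), fixed(value).
make_sampler <- function(spec, what) {
  if (is.function(spec)) return(spec)
  if (is.numeric(spec) && length(spec) == 1L && !is.na(spec)) {
    v <- spec
    return(function(n) rep(v, n))
  }
  if (is.list(spec) && !is.null(spec$dist)) {
    switch(as.character(spec$dist),
      uniform = {
        lo <- spec$min %||% 0; hi <- spec$max %||% 1
        if (!is.numeric(lo) || !is.numeric(hi) || hi < lo) {
          abort_config(sprintf("invalid uniform bounds in `%s`", what))
        }
        return(function(n) runif(n, lo, hi))
      },
      beta = {
        s1 <- spec$shape1; s2 <- spec$shape2
        if (is.null(s1) || is.null(s2) || s1 <= 0 || s2 <= 0) {
          abort_config(sprintf("invalid beta shapes in `%s`", what))
        }
        return(function(n) stats::rbeta(n, s1, s2))
      },
      loguniform = {
        lo <- spec$min %||% 1; hi <- spec$max %||% 25
        if (lo <= 0 || hi < lo) {
          abort_config(sprintf("invalid loguniform bounds in `%s`", what))
        }
        return(function(n) exp(runif(n, log(lo), log(hi))))
      },
      fixed = {
        v <- spec$value
        if (is.null(v) || !is.numeric(v)) {
          abort_config(sprintf("invalid fixed value in `%s`", what))
        }
        return(function(n) rep(v, n))
      },
      abort_config(sprintf("unknown distribution `%s` in `%s`", spec$dist, what))
    )
  }
  abort_config(sprintf("`%s` must be a function(n) or a distribution spec list", what))
}

# ---- pan-genome model -------------------------------------------------------

#' Build a synthetic pan-genome model
#'
#' Generates a diploid pan-genome layout: core genes (haplotype allele
#' frequency f = 1) and dispensable genes (0 < f < 1) arranged in blocks of
#' contiguous co-inherited genes along scaffolds. This emulates genomes in
#' which dispensable genes cluster in multi-gene hemizygous blocks (tens of
#' kilobases) rather than being scattered singly.
#'
#' @param n_core number of core genes.
#' @param n_dispensable number of dispensable genes.
#' @param freq_sampler sampler spec for per-block haplotype allele
#'   frequencies of dispensable blocks: a `function(n)` or a list such as
#'   `list(dist = "uniform", min = 0.1, max = 0.9)` (the default) or
#'   `list(dist = "beta", shape1, shape2)` for skewed spectra with
#'   singletons. Sampled values are clamped to (0.001, 0.999).
#' @param block_size_sampler sampler spec for genes per block; default
#'   log-uniform on \[1, 25\] genes, echoing multi-gene dispensable blocks.
#' @param seed integer seed; identical seeds give identical models.
#' @param blocks_per_scaffold blocks laid on each scaffold before a new
#'   scaffold is started.
#'
#' @return An object of class `pangenome_model`: a list with data frames
#'   `genes` (gene_id, category, freq, block_id, scaffold, start, end,
#'   strand, gc, exonic_length, n_exons), `exons`, `blocks` and `scaffolds`
#'   (1-based closed coordinates, as in GFF3/GRanges).
#' @export
#' @examples
#' m <- build_pangenome_model(60, 20, seed = 1)
#' table(m$genes$category)
build_pangenome_model <- function(n_core,
                                  n_dispensable,
                                  freq_sampler = list(dist = "uniform", min = 0.1, max = 0.9),
                                  block_size_sampler = list(dist = "loguniform", min = 1, max = 25),
                                  seed = NULL,
                                  blocks_per_scaffold = 25L) {
  n_core <- check_count(n_core, "n_core")
  n_dispensable <- check_count(n_dispensable, "n_dispensable")
  if (n_core + n_dispensable < 1L) abort_config("model must contain at least one gene")
  fs <- make_sampler(freq_sampler, "freq_sampler")
  bs <- make_sampler(block_size_sampler, "block_size_sampler")
  blocks_per_scaffold <- check_count(blocks_per_scaffold, "blocks_per_scaffold", min = 1L)

  with_seed(seed, {
    draw_blocks <- function(n_genes) {
      if (n_genes == 0L) return(integer(0))
      sizes <- integer(0)
      while (sum(sizes) < n_genes) {
        s <- pmax(1L, as.integer(round(bs(max(8L, n_genes %/% 4L)))))
        if (any(is.na(s))) abort_config("block_size_sampler produced NA")
        sizes <- c(sizes, s)
      }
      k <- which(cumsum(sizes) >= n_genes)[1L]
      sizes <- sizes[seq_len(k)]
      sizes[k] <- sizes[k] - (sum(sizes) - n_genes)
      sizes[sizes > 0L]
    }
    core_sizes <- draw_blocks(n_core)
    disp_sizes <- draw_blocks(n_dispensable)

    freqs <- if (length(disp_sizes)) pmin(0.999, pmax(0.001, fs(length(disp_sizes)))) else numeric(0)
    if (any(is.na(freqs))) abort_config("freq_sampler produced NA")

    blocks <- data.frame(
      category = c(rep("core", length(core_sizes)), rep("dispensable", length(disp_sizes))),
      n_genes = c(core_sizes, disp_sizes),
      freq = c(rep(1, length(core_sizes)), freqs),
      stringsAsFactors = FALSE
    )
    blocks <- blocks[sample.int(nrow(blocks)), , drop = FALSE]  # interleave along genome
    blocks$block_id <- sprintf("b%05d", seq_len(nrow(blocks)))

    # gene structures
    n_genes <- sum(blocks$n_genes)
    n_ex <- sample(1:5, n_genes, replace = TRUE)
    intron_len <- 200L; gene_gap <- 500L; block_gap <- 1000L

    gene_rows <- vector("list", n_genes)
    exon_rows <- vector("list", n_genes)
    gi <- 0L
    scaffold_of_block <- character(nrow(blocks))
    block_start <- integer(nrow(blocks)); block_end <- integer(nrow(blocks))
    cursor <- 1L; scaf_idx <- 1L
    scaf_len <- integer(0)
    for (bi in seq_len(nrow(blocks))) {
      if (bi > 1L && (bi - 1L) %% blocks_per_scaffold == 0L) {
        scaf_len[scaf_idx] <- cursor + block_gap
        scaf_idx <- scaf_idx + 1L
        cursor <- 1L
      }
      scaf <- sprintf("s%04d", scaf_idx)
      scaffold_of_block[bi] <- scaf
      bstart <- cursor + block_gap
      cur <- bstart
      for (g in seq_len(blocks$n_genes[bi])) {
        gi <- gi + 1L
        k <- n_ex[gi]
        ex_len <- as.integer(round(runif(k, 150, 400)))
        ex_start <- integer(k); ex_end <- integer(k)
        p <- cur
        for (e in seq_len(k)) {
          ex_start[e] <- p
          ex_end[e] <- p + ex_len[e] - 1L
          p <- ex_end[e] + 1L + intron_len
        }
        gene_rows[[gi]] <- data.frame(
          gene_id = sprintf("g%05d", gi),
          category = blocks$category[bi],
          freq = blocks$freq[bi],
          block_id = blocks$block_id[bi],
          scaffold = scaf,
          start = ex_start[1L],
          end = ex_end[k],
          strand = sample(c("+", "-"), 1L),
          gc = runif(1, 0.26, 0.38),
          exonic_length = sum(ex_len),
          n_exons = k,
          stringsAsFactors = FALSE
        )
        exon_rows[[gi]] <- data.frame(
          gene_id = sprintf("g%05d", gi), scaffold = scaf,
          start = ex_start, end = ex_end, stringsAsFactors = FALSE
        )
        cur <- ex_end[k] + 1L + gene_gap
      }
      block_start[bi] <- bstart
      block_end[bi] <- cur - gene_gap - 1L
      cursor <- cur
    }
    scaf_len[scaf_idx] <- cursor + block_gap

    genes <- do.call(rbind, gene_rows)
    exons <- do.call(rbind, exon_rows)
    blocks$scaffold <- scaffold_of_block
    blocks$start <- block_start
    blocks$end <- block_end
    blocks <- blocks[, c("block_id", "category", "freq", "n_genes",
                         "scaffold", "start", "end")]
    scaffolds <- data.frame(
      scaffold = sprintf("s%04d", seq_along(scaf_len)),
      length = scaf_len, stringsAsFactors = FALSE
    )
    structure(
      list(genes = genes, exons = exons, blocks = blocks, scaffolds = scaffolds,
           params = list(n_core = n_core, n_dispensable = n_dispensable, seed = seed)),
      class = "pangenome_model"
    )
  })
}

#' @export
print.pangenome_model <- function(x, ...) {
  cat(sprintf(
    "pangenome_model: %d genes (%d core, %d dispensable) in %d blocks on %d scaffolds\n",
    nrow(x$genes), sum(x$genes$category == "core"),
    sum(x$genes$category == "dispensable"), nrow(x$blocks), nrow(x$scaffolds)
  ))
  invisible(x)
}

#' Exon annotation of a synthetic model as a GRangesList
#'
#' @param model a [build_pangenome_model()] result.
#' @return A `GRangesList`, one element per gene (named by gene id), holding
#'   that gene's exon ranges — the same container [read_annotation()] returns.
#' @export
annotation_granges <- function(model) {
  stopifnot(inherits(model, "pangenome_model"))
  ex <- model$exons
  st <- model$genes$strand[match(ex$gene_id, model$genes$gene_id)]
  gr <- GenomicRanges::GRanges(ex$scaffold, IRanges::IRanges(ex$start, ex$end),
                               strand = st)
  S4Vectors::split(gr, factor(ex$gene_id, levels = unique(ex$gene_id)))
}

# ---- populations and crosses ------------------------------------------------

#' Sample a population of diploid genotypes from a pan-genome model
#'
#' For each dispensable block, each of an individual's two haplotypes
#' carries the block independently with probability f (the block's
#' haplotype allele frequency); copy number is the sum of the two
#' indicators, so at frequency f the copy-number classes 0/1/2 follow
#' Hardy-Weinberg proportions ((1-f)^2, 2f(1-f), f^2). Core blocks are
#' always carried on both haplotypes.
#'
#' @param model a [build_pangenome_model()] result.
#' @param n_individuals number of individuals.
#' @param seed integer seed.
#' @return An object of class `pav_population`: haplotype matrices `H1`,
#'   `H2` (blocks x individuals, 0/1), `block_copies`, and `gene_copies`
#'   (genes x individuals, values 0/1/2), plus the model.
#' @export
sample_population <- function(model, n_individuals, seed = NULL) {
  stopifnot(inherits(model, "pangenome_model"))
  n_individuals <- check_count(n_individuals, "n_individuals", min = 1L)
  nb <- nrow(model$blocks)
  with_seed(seed, {
    f <- model$blocks$freq
    H1 <- matrix(rbinom(nb * n_individuals, 1L, rep(f, n_individuals)),
                 nrow = nb, ncol = n_individuals)
    H2 <- matrix(rbinom(nb * n_individuals, 1L, rep(f, n_individuals)),
                 nrow = nb, ncol = n_individuals)
    core <- model$blocks$category == "core"
    H1[core, ] <- 1L; H2[core, ] <- 1L
    ids <- sprintf("ind%03d", seq_len(n_individuals))
    dimnames(H1) <- dimnames(H2) <- list(model$blocks$block_id, ids)
    new_population(model, H1, H2, ids)
  })
}

new_population <- function(model, H1, H2, ids) {
  bc <- H1 + H2
  gidx <- match(model$genes$block_id, model$blocks$block_id)
  gc_mat <- bc[gidx, , drop = FALSE]
  dimnames(gc_mat) <- list(model$genes$gene_id, ids)
  structure(
    list(model = model, individual_ids = ids, H1 = H1, H2 = H2,
         block_copies = bc, gene_copies = gc_mat),
    class = "pav_population"
  )
}

#' @export
print.pav_population <- function(x, ...) {
  cat(sprintf("pav_population: %d individuals x %d genes (%d blocks)\n",
              length(x$individual_ids), nrow(x$gene_copies), nrow(x$H1)))
  invisible(x)
}

#' Extract or construct a single diploid genotype
#'
#' `genotype()` pulls one individual out of a population;
#' `individual_genotype()` builds one from explicit per-block haplotype
#' indicators (useful for designing crosses). Core blocks must be carried
#' on both haplotypes.
#'
#' @param population a [sample_population()] result.
#' @param individual individual id or index.
#' @return An object of class `individual_genotype` with per-block
#'   haplotype indicators `h1`, `h2` and derived `copies = h1 + h2`.
#' @export
genotype <- function(population, individual) {
  stopifnot(inherits(population, "pav_population"))
  if (is.character(individual)) {
    individual <- match(individual, population$individual_ids)
  }
  if (is.na(individual) || individual < 1L || individual > length(population$individual_ids)) {
    abort_validation("unknown individual")
  }
  individual_genotype(population$model,
                      h1 = population$H1[, individual],
                      h2 = population$H2[, individual],
                      individual_id = population$individual_ids[individual])
}

#' @rdname genotype
#' @param model a [build_pangenome_model()] result.
#' @param h1,h2 0/1 vectors of per-block haplotype indicators, in block
#'   order (recycled if length 1).
#' @param individual_id id string for the genotype.
#' @export
individual_genotype <- function(model, h1, h2, individual_id = "ind") {
  stopifnot(inherits(model, "pangenome_model"))
  nb <- nrow(model$blocks)
  h1 <- as.integer(rep_len(h1, nb)); h2 <- as.integer(rep_len(h2, nb))
  if (!all(h1 %in% 0:1) || !all(h2 %in% 0:1)) {
    abort_validation("haplotype indicators must be 0 or 1")
  }
  core <- model$blocks$category == "core"
  if (!all(h1[core] == 1L & h2[core] == 1L)) {
    abort_validation("core blocks must be carried on both haplotypes")
  }
  structure(
    list(individual_id = individual_id, model = model,
         block_id = model$blocks$block_id, h1 = h1, h2 = h2,
         copies = h1 + h2),
    class = "individual_genotype"
  )
}

#' Simulate a cross between two diploid parents
#'
#' Each offspring receives, independently for every block, one uniformly
#' chosen haplotype from each parent. For a dispensable gene carried in
#' single copy by both parents (hemizygous x hemizygous), the offspring
#' copy-number distribution is (1/4, 1/2, 1/4) for 0/1/2 copies, so the
#' gene is expected to be entirely absent in 25% of the offspring.
#'
#' @param parent1,parent2 `individual_genotype` objects from the same model.
#' @param n_offspring number of offspring.
#' @param seed integer seed.
#' @return A `pav_population` of offspring genotypes.
#' @export
#' @examples
#' m <- build_pangenome_model(5, 5, seed = 1)
#' p <- individual_genotype(m, h1 = 1, h2 = ifelse(m$blocks$category == "core", 1, 0))
#' f1 <- simulate_cross(p, p, 1000, seed = 2)
#' mean(f1$block_copies[m$blocks$category == "dispensable", ] == 0)  # ~0.25
simulate_cross <- function(parent1, parent2, n_offspring, seed = NULL) {
  stopifnot(inherits(parent1, "individual_genotype"),
            inherits(parent2, "individual_genotype"))
  if (!identical(parent1$block_id, parent2$block_id)) {
    abort_validation("parents must come from the same pan-genome model")
  }
  n_offspring <- check_count(n_offspring, "n_offspring", min = 1L)
  nb <- length(parent1$block_id)
  with_seed(seed, {
    pick1 <- matrix(rbinom(nb * n_offspring, 1L, 0.5), nb, n_offspring)
    pick2 <- matrix(rbinom(nb * n_offspring, 1L, 0.5), nb, n_offspring)
    H1 <- ifelse(pick1 == 1L, parent1$h1, parent1$h2)
    H2 <- ifelse(pick2 == 1L, parent2$h1, parent2$h2)
    ids <- sprintf("off%04d", seq_len(n_offspring))
    dimnames(H1) <- dimnames(H2) <- list(parent1$block_id, ids)
    new_population(parent1$model, H1, H2, ids)
  })
}

# ---- depth emission ---------------------------------------------------------

#' Depth-simulation configuration
#'
#' Expected per-base depth in a region carried in c copies is
#' `c * lambda + epsilon`, where `lambda` is the per-haplotype mean depth
#' and `epsilon` a background mis-mapping depth that keeps copy-0 regions
#' slightly above zero (set `epsilon = 0` for a clean zero peak). Noise is
#' negative-binomial per window of `window` bp (a read-length proxy that
#' emulates read-level autocorrelation) with variance
#' `mu + dispersion * mu^2`; `dispersion = 0` gives Poisson noise.
#'
#' @param lambda per-haplotype mean depth (X); the homozygous expectation
#'   is `2 * lambda`.
#' @param dispersion negative-binomial overdispersion (>= 0).
#' @param epsilon background mis-mapping depth (X) added everywhere.
#' @param window window size in bp over which one depth value is drawn.
#' @return A list of class `coverage_config`.
#' @export
coverage_config <- function(lambda = 41.5, dispersion = 0.05, epsilon = 0.5,
                            window = 100L) {
  if (!is.numeric(lambda) || lambda <= 0) abort_config("`lambda` must be > 0")
  if (!is.numeric(dispersion) || dispersion < 0) abort_config("`dispersion` must be >= 0")
  if (!is.numeric(epsilon) || epsilon < 0) abort_config("`epsilon` must be >= 0")
  window <- check_count(window, "window", min = 1L)
  structure(list(lambda = lambda, dispersion = dispersion,
                 epsilon = epsilon, window = window),
            class = "coverage_config")
}

rdepth <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(rpois(n, mu))
  out <- integer(n)
  pos <- mu > 0
  out[pos] <- rnbinom(sum(pos), mu = mu[pos], size = 1 / dispersion)
  out
}

# Window-level depth runs for one individual over all scaffolds.
# block_copies: named vector (block_id -> 0/1/2). Non-block background is
# homozygous (copy 2). Windows are tiled within each copy-number segment
# (segment boundaries = block boundaries), so a window never mixes two
# copy states and a copy-0 block has exactly zero depth when epsilon = 0.
# Returns data.frame(scaffold, start, end, depth), 1-based closed,
# contiguous windows.
simulate_depth_runs <- function(model, block_copies, cfg) {
  w <- cfg$window
  out <- vector("list", nrow(model$scaffolds))
  for (si in seq_len(nrow(model$scaffolds))) {
    scaf <- model$scaffolds$scaffold[si]
    len <- model$scaffolds$length[si]
    bl <- model$blocks[model$blocks$scaffold == scaf, , drop = FALSE]
    bl <- bl[order(bl$start), , drop = FALSE]
    seg_start <- integer(0); seg_end <- integer(0); seg_copy <- integer(0)
    cur <- 1L
    for (bi in seq_len(nrow(bl))) {
      if (bl$start[bi] > cur) {
        seg_start <- c(seg_start, cur)
        seg_end <- c(seg_end, bl$start[bi] - 1L)
        seg_copy <- c(seg_copy, 2L)
      }
      seg_start <- c(seg_start, bl$start[bi])
      seg_end <- c(seg_end, bl$end[bi])
      seg_copy <- c(seg_copy, block_copies[[bl$block_id[bi]]])
      cur <- bl$end[bi] + 1L
    }
    if (cur <= len) {
      seg_start <- c(seg_start, cur); seg_end <- c(seg_end, len)
      seg_copy <- c(seg_copy, 2L)
    }
    starts <- integer(0); ends <- integer(0); copy <- integer(0)
    for (k in seq_along(seg_start)) {
      s <- seq.int(seg_start[k], seg_end[k], by = w)
      e <- pmin(s + w - 1L, seg_end[k])
      starts <- c(starts, s); ends <- c(ends, e)
      copy <- c(copy, rep(seg_copy[k], length(s)))
    }
    mu <- copy * cfg$lambda + cfg$epsilon
    out[[si]] <- data.frame(scaffold = scaf, start = starts, end = ends,
                            depth = rdepth(length(mu), mu, cfg$dispersion),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

runs_to_track <- function(runs, individual_id, scaffold_lengths) {
  rles <- lapply(split(runs, runs$scaffold), function(df) {
    df <- df[order(df$start), , drop = FALSE]
    S4Vectors::Rle(as.numeric(df$depth), df$end - df$start + 1L)
  })
  depth_track(rles, individual_id)
}

#' Simulate per-gene coverage for a whole population
#'
#' Draws window-level depth tracks for every individual (copy number per
#' block from the population's genotypes, background homozygous) and
#' summarizes them into a genes x individuals mean-exonic-depth matrix via
#' the same machinery used for real depth tracks ([build_matrix()]).
#'
#' @param population a [sample_population()] or [simulate_cross()] result.
#' @param cfg a [coverage_config()].
#' @param seed integer seed.
#' @return A `pav_coverage_matrix` (raw layer filled).
#' @export
simulate_coverage_matrix <- function(population, cfg = coverage_config(),
                                     seed = NULL) {
  stopifnot(inherits(population, "pav_population"),
            inherits(cfg, "coverage_config"))
  model <- population$model
  ann <- annotation_granges(model)
  with_seed(seed, {
    tracks <- lapply(seq_along(population$individual_ids), function(i) {
      runs <- simulate_depth_runs(model, population$block_copies[, i], cfg)
      runs_to_track(runs, population$individual_ids[i],
                    setNames(model$scaffolds$length, model$scaffolds$scaffold))
    })
    build_matrix(tracks, ann)
  })
}

#' Sample a per-site depth distribution from a diploid mixture
#'
#' Draws depth values from a genome in which a fraction of sites is
#' hemizygous (one haplotype, mean `lambda_hap`) and the rest homozygous
#' (mean `2 * lambda_hap`), optionally with a spike of unmappable sites at
#' depth ~0. Used to exercise depth-peak calibration on distributions with
#' hemizygous and homozygous coverage modes.
#'
#' @param n number of depth values.
#' @param lambda_hap per-haplotype mean depth (X).
#' @param hemi_frac fraction of (mappable) sites that are hemizygous.
#' @param zero_frac fraction of sites with no unique mapping (depth drawn
#'   with copy 0).
#' @param dispersion,epsilon as in [coverage_config()].
#' @param seed integer seed.
#' @return Numeric vector of depth values.
#' @export
simulate_depth_values <- function(n, lambda_hap = 41.5, hemi_frac = 0.3,
                                  zero_frac = 0, dispersion = 0.05,
                                  epsilon = 0, seed = NULL) {
  n <- check_count(n, "n", min = 1L)
  hemi_frac <- check_fraction(hemi_frac, "hemi_frac")
  zero_frac <- check_fraction(zero_frac, "zero_frac")
  with_seed(seed, {
    u <- runif(n)
    copy <- ifelse(u < zero_frac, 0L,
                   ifelse(u < zero_frac + (1 - zero_frac) * hemi_frac, 1L, 2L))
    mu <- copy * lambda_hap + epsilon
    as.numeric(rdepth(n, mu, dispersion))
  })
}

# ---- dataset emission -------------------------------------------------------

#' Write a synthetic dataset to disk
#'
#' Emits the file set the analysis pipeline consumes: a GFF3 gene
#' annotation, one bedGraph depth track per individual, a truth table of
#' per-gene copy numbers, and a JSON manifest recording parameters and
#' seeds. Re-reading the bedGraph tracks with [read_depth_track()]
#' reproduces the simulated depth values exactly.
#'
#' @param population a `pav_population`.
#' @param cfg a [coverage_config()].
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for the depth noise.
#' @return Invisibly, the manifest list (also written to `manifest.json`).
#' @export
emit_dataset <- function(population, cfg = coverage_config(), out_dir,
                         seed = NULL) {
  stopifnot(inherits(population, "pav_population"),
            inherits(cfg, "coverage_config"))
  model <- population$model
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    abort_io(sprintf("cannot create output directory: %s", out_dir))
  }

  gff_path <- file.path(out_dir, "annotation.gff3")
  write_model_gff3(model, gff_path)

  track_files <- character(0)
  with_seed(seed, {
    for (i in seq_along(population$individual_ids)) {
      id <- population$individual_ids[i]
      runs <- simulate_depth_runs(model, population$block_copies[, i], cfg)
      gr <- GenomicRanges::GRanges(runs$scaffold,
                                   IRanges::IRanges(runs$start, runs$end),
                                   score = runs$depth)
      path <- file.path(out_dir, paste0(id, ".bedgraph"))
      rtracklayer::export(gr, path, format = "bedGraph")
      track_files[id] <- basename(path)
    }
  })

  truth <- data.frame(
    individual_id = rep(population$individual_ids,
                        each = nrow(population$gene_copies)),
    gene_id = rep(rownames(population$gene_copies),
                  times = length(population$individual_ids)),
    copies = as.vector(population$gene_copies),
    stringsAsFactors = FALSE
  )
  truth_path <- file.path(out_dir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = seed,
    coverage = unclass(cfg),
    model = model$params,
    n_individuals = length(population$individual_ids),
    files = c(list(annotation = basename(gff_path), truth = basename(truth_path)),
              list(tracks = as.list(track_files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_model_gff3 <- function(model, path) {
  g <- model$genes; e <- model$exons
  gene_gr <- GenomicRanges::GRanges(g$scaffold, IRanges::IRanges(g$start, g$end),
                                    strand = g$strand)
  S4Vectors::mcols(gene_gr)$type <- "gene"
  S4Vectors::mcols(gene_gr)$ID <- g$gene_id
  mrna_gr <- gene_gr
  S4Vectors::mcols(mrna_gr)$type <- "mRNA"
  S4Vectors::mcols(mrna_gr)$ID <- paste0(g$gene_id, ".t1")
  S4Vectors::mcols(mrna_gr)$Parent <- g$gene_id
  st <- g$strand[match(e$gene_id, g$gene_id)]
  exon_gr <- GenomicRanges::GRanges(e$scaffold, IRanges::IRanges(e$start, e$end),
                                    strand = st)
  S4Vectors::mcols(exon_gr)$type <- "exon"
  S4Vectors::mcols(exon_gr)$Parent <- paste0(e$gene_id, ".t1")
  all_gr <- suppressWarnings(c(gene_gr, mrna_gr, exon_gr))
  rtracklayer::export(all_gr, path, format = "gff3")
  invisible(path)
}
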