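# Pan-genome growth: accumulate novel gene content across individuals,
# quantify openness with a power-law fit to the novel-gene increments, and
# filter accessory contigs with a coverage/GC/taxonomy rule engine.

#' Accumulate novel gene content across individuals
#'
#' Set-level abstraction of recursive pan-genome construction: starting
#' from the reference gene set, each individual's present-gene set is
#' unioned in turn; the genes it contributes beyond the current pan-genome
#' are its novel set.
#'
#' @param presence_sets ordered (named) list of character vectors, one
#'   per individual, of present gene ids.
#' @param reference_set character vector of reference gene ids (may be
#'   empty).
#' @return A list with `steps` (data frame: step, individual, set_size,
#'   n_novel, pan_size), `novel` (list of per-step novel gene vectors)
#'   and `reference_size`.
#' @export
#' @examples
#' recursive_accumulate(list(a = c("a", "b"), b = c("b", "c"),
#'                           c = c("c", "d")), character(0))$steps$pan_size
recursive_accumulate <- function(presence_sets, reference_set = character(0)) {
  if (!is.list(presence_sets) || length(presence_sets) == 0L) {
    abort_validation("`presence_sets` must be a non-empty list of gene id vectors")
  }
  ids <- names(presence_sets) %||% paste0("ind", seq_along(presence_sets))
  pan <- unique(as.character(reference_set))
  novel <- vector("list", length(presence_sets))
  rows <- vector("list", length(presence_sets))
  for (i in seq_along(presence_sets)) {
    s <- unique(as.character(presence_sets[[i]]))
    nv <- setdiff(s, pan)
    pan <- c(pan, nv)
    novel[[i]] <- nv
    rows[[i]] <- data.frame(step = i, individual = ids[i],
                            set_size = length(s), n_novel = length(nv),
                            pan_size = length(pan), stringsAsFactors = FALSE)
  }
  list(steps = do.call(rbind, rows), novel = novel,
       reference_size = length(unique(as.character(reference_set))))
}

#' Present-gene sets from a zygosity matrix
#'
#' @param z a `pav_zygosity` object.
#' @return Named list of present-gene id vectors (call >= 1), one per
#'   individual.
#' @export
presence_sets <- function(z) {
  stopifnot(inherits(z, "pav_zygosity"))
  setNames(lapply(z$individuals, function(i) z$genes[z$calls[, i] >= 1L]),
           z$individuals)
}

#' Permutation-averaged pan-genome growth curve
#'
#' Averages [recursive_accumulate()] over uniformly random orderings of
#' the individuals, giving the mean cumulative gene count and the mean
#' novel-gene increment at each number of genomes added.
#'
#' @inheritParams recursive_accumulate
#' @param n_permutations number of random orderings.
#' @param seed integer seed.
#' @return Object of class `pav_growth_curve`: `summary` data frame
#'   (N, mean_pan_size, sd_pan_size, mean_novel), per-permutation
#'   `pan_sizes` matrix (N x permutations), `reference_size`.
#' @export
growth_curve <- function(presence_sets, reference_set = character(0),
                         n_permutations = 100L, seed = NULL) {
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1L)
  n <- length(presence_sets)
  if (n < 1L) abort_validation("need at least one presence set")
  with_seed(seed, {
    sizes <- matrix(NA_real_, nrow = n, ncol = n_permutations)
    novel <- matrix(NA_real_, nrow = n, ncol = n_permutations)
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(n)
      acc <- recursive_accumulate(presence_sets[ord], reference_set)
      sizes[, p] <- acc$steps$pan_size
      novel[, p] <- acc$steps$n_novel
    }
    summary <- data.frame(
      N = seq_len(n),
      mean_pan_size = rowMeans(sizes),
      sd_pan_size = apply(sizes, 1L, sd),
      mean_novel = rowMeans(novel)
    )
    structure(
      list(summary = summary, pan_sizes = sizes, mean_novel = rowMeans(novel),
           reference_size = length(unique(as.character(reference_set))),
           n_permutations = n_permutations),
      class = "pav_growth_curve"
    )
  })
}

#' @export
print.pav_growth_curve <- function(x, ...) {
  n <- nrow(x$summary)
  cat(sprintf("pav_growth_curve: %d genomes, %d permutations; pan size %.0f -> %.0f\n",
              n, x$n_permutations, x$summary$mean_pan_size[1L],
              x$summary$mean_pan_size[n]))
  invisible(x)
}

#' @method plot pav_growth_curve
#' @export
plot.pav_growth_curve <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$N, s$mean_pan_size, type = "b", pch = 16,
                 xlab = "genomes added (N)", ylab = "mean pan-genome gene count",
                 main = "Pan-genome accumulation", ...)
  graphics::arrows(s$N, s$mean_pan_size - s$sd_pan_size,
                   s$N, s$mean_pan_size + s$sd_pan_size,
                   length = 0.03, angle = 90, code = 3, col = "grey40")
  invisible(x)
}

#' Power-law openness fit to novel-gene increments
#'
#' Fits the mean novel-gene increments to `novel(N) = kappa * N^(-alpha)`
#' by least squares on the log-log scale (the Heaps/Tettelin form). An
#' exponent `alpha < 1` means the cumulative gene count diverges as more
#' genomes are added: the pan-genome is open. Steps with zero mean
#' increment are excluded from the fit and reported.
#'
#' @param curve a `pav_growth_curve`, or a numeric vector of mean
#'   increments at N = 1, 2, ...
#' @return Object of class `pav_heaps_fit`: `kappa`, `alpha`, `r_squared`
#'   (log-log), `open` (alpha < 1), `n_points`, `excluded_steps`.
#' @export
fit_openness <- function(curve) {
  inc <- if (inherits(curve, "pav_growth_curve")) curve$mean_novel
         else as.numeric(curve)
  if (any(is.na(inc)) || any(inc < 0)) abort_validation("increments must be >= 0")
  N <- seq_along(inc)
  keep <- inc > 0
  if (sum(keep) < 3L) {
    abort_calibration("need at least 3 steps with positive mean increments to fit")
  }
  fit <- lm(log(inc[keep]) ~ log(N[keep]))
  alpha <- -unname(coef(fit)[2L])
  kappa <- exp(unname(coef(fit)[1L]))
  ss_tot <- sum((log(inc[keep]) - mean(log(inc[keep])))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(kappa = kappa, alpha = alpha, r_squared = r2, open = alpha < 1,
         n_points = sum(keep), excluded_steps = N[!keep]),
    class = "pav_heaps_fit"
  )
}

#' @export
print.pav_heaps_fit <- function(x, ...) {
  cat(sprintf(
    "pav_heaps_fit: novel(N) = %.1f * N^(-%.3f)  [R^2 = %.3f] -> %s pan-genome\n",
    x$kappa, x$alpha, x$r_squared, if (x$open) "OPEN" else "closed"))
  invisible(x)
}

#' Simulate power-law novel-gene increments
#'
#' Draws increments `kappa * N^(-alpha)` with multiplicative log-normal
#' noise; used to check that [fit_openness()] recovers a known exponent.
#'
#' @param kappa,alpha power-law scale and decay exponent.
#' @param n_steps number of genomes.
#' @param sdlog log-scale standard deviation of the noise.
#' @param seed integer seed.
#' @return Numeric vector of increments.
#' @export
simulate_power_increments <- function(kappa, alpha, n_steps, sdlog = 0.1,
                                      seed = NULL) {
  n_steps <- check_count(n_steps, "n_steps", min = 1L)
  with_seed(seed, kappa * seq_len(n_steps)^(-alpha) * exp(rnorm(n_steps, 0, sdlog)))
}

#' Filter accessory contigs by taxonomy, GC, depth and length
#'
#' Rule engine over precomputed contig metadata, emulating the strict
#' decontamination applied before accessory contigs join a pan-genome:
#' a contig is kept iff its taxonomy label is not "contaminant", its GC
#' fraction and mean depth fall within bounds, and it is long enough.
#' Each removed contig carries the first failing rule (checked in the
#' order taxonomy, gc, depth, length).
#'
#' @param contigs data frame with columns `contig_id`, `length`, `gc`,
#'   `depth`, `taxonomy_label` (values "target", "contaminant" or
#'   "unknown").
#' @param gc_bounds allowed GC interval.
#' @param depth_bounds allowed mean-depth interval (X).
#' @param min_length minimum contig length (bp).
#' @return List with `kept` and `removed` data frames; `removed` has a
#'   `reason` column.
#' @export
filter_contigs <- function(contigs, gc_bounds = c(0.20, 0.50),
                           depth_bounds = c(1, Inf), min_length = 500) {
  need <- c("contig_id", "length", "gc", "depth", "taxonomy_label")
  if (!is.data.frame(contigs) || !all(need %in% names(contigs))) {
    abort_validation(sprintf("`contigs` must have columns: %s",
                             paste(need, collapse = ", ")))
  }
  if (gc_bounds[1L] > gc_bounds[2L] || depth_bounds[1L] > depth_bounds[2L]) {
    abort_config("bounds must be well-ordered")
  }
  reason <- rep(NA_character_, nrow(contigs))
  fail <- function(cond, tag) {
    hit <- is.na(reason) & cond
    reason[hit] <<- tag
  }
  fail(contigs$taxonomy_label == "contaminant", "taxonomy")
  fail(contigs$gc < gc_bounds[1L] | contigs$gc > gc_bounds[2L], "gc")
  fail(contigs$depth < depth_bounds[1L] | contigs$depth > depth_bounds[2L], "depth")
  fail(contigs$length < min_length, "length")
  removed <- contigs[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(kept = contigs[is.na(reason), , drop = FALSE], removed = removed)
}
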