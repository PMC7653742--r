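# Per-individual depth calibration: locate the hemizygous (one-allele) and
# homozygous (two-allele) peaks of the depth distribution, anchored by a set
# of genes with stable coverage across individuals, and normalize the
# coverage matrix so that 1.0 equals the one-allele expectation.

#' Select genes with stable coverage across individuals
#'
#' Calibration anchors: genes whose depth varies little across individuals
#' (and is never unusually low in any individual) are almost surely present
#' in two copies everywhere, so their depth tracks the homozygous
#' expectation. A gene qualifies when its across-individual coefficient of
#' variation is at most `cv_max` and its minimum relative depth (depth in
#' an individual divided by that individual's median gene depth) is at
#' least `min_relative_depth`. If more than `target_count` genes qualify,
#' the `target_count` lowest-CV genes are kept.
#'
#' @param x a `pav_coverage_matrix` with at least 2 individuals.
#' @param cv_max maximum across-individual coefficient of variation.
#' @param min_relative_depth minimum per-individual relative depth.
#' @param target_count maximum number of genes to keep.
#' @return Character vector of stable gene ids (lowest CV first).
#' @export
select_stable_genes <- function(x, cv_max = 0.2, min_relative_depth = 0.5,
                                target_count = 4000) {
  stopifnot(inherits(x, "pav_coverage_matrix"))
  raw <- x$raw
  if (ncol(raw) < 2L) abort_validation("stable-gene selection needs >= 2 individuals")
  cv_max <- check_fraction(cv_max, "cv_max", lo = 0, hi = Inf, open_lo = TRUE)
  min_relative_depth <- check_fraction(min_relative_depth, "min_relative_depth",
                                       lo = 0, hi = Inf)
  target_count <- check_count(target_count, "target_count", min = 1L)

  mu <- rowMeans(raw)
  s <- apply(raw, 1L, sd)
  cv <- ifelse(mu > 0, s / mu, Inf)
  med <- apply(raw, 2L, median)
  if (any(med <= 0)) abort_calibration("an individual has zero median gene depth")
  rel_min <- apply(sweep(raw, 2L, med, "/"), 1L, min)
  ok <- which(cv <= cv_max & rel_min >= min_relative_depth)
  if (length(ok) < 50L) {
    abort_calibration(sprintf(
      "only %d genes qualify as coverage-stable; relax cv_max/min_relative_depth",
      length(ok)
    ))
  }
  ok <- ok[order(cv[ok])]
  rownames(raw)[head(ok, target_count)]
}

#' Estimate the hemizygous and homozygous depth peaks
#'
#' Finds the two dominant modes of a depth distribution. Values at or near
#' zero (the unmappable-sequence spike) are excluded, candidate modes are
#' located on a Gaussian kernel density estimate (Silverman bandwidth),
#' mode pairs are scored by how close their ratio is to the expected 2:1
#' (homozygous:hemizygous), and the winning pair is refined by a
#' two-component normal mixture EM, which reports the component means as
#' the peak locations. The lower peak is the one-allele depth `lambda1`,
#' the higher the two-allele depth `lambda2`.
#'
#' With `ratio_constraint = TRUE` (default) the pair must satisfy
#' `lambda2/lambda1` within `ratio_bounds`; unimodal input is then an
#' error unless `prior_stable_mean` disambiguates it. A single mode is
#' interpreted via `prior_stable_mean` (mode close to the prior = the
#' homozygous peak) or, with the constraint disabled, as the homozygous
#' peak, yielding `(mode/2, mode)`.
#'
#' @param values numeric depth values (per-base or per-gene), at least
#'   `min_values` of them.
#' @param prior_stable_mean optional prior for the homozygous peak (X),
#'   e.g. the median depth of coverage-stable genes.
#' @param ratio_constraint require the peak ratio to fall in `ratio_bounds`.
#' @param ratio_bounds allowed range for `lambda2/lambda1`.
#' @param min_values minimum sample size.
#' @param zero_exclusion values below `zero_exclusion * median(positive)`
#'   are treated as the zero peak and ignored.
#' @return Object of class `pav_depth_peaks`: `lambda1`, `lambda2`,
#'   `ratio`, `method`, KDE `modes`, bandwidth `bw`, `n_used`.
#' @export
estimate_depth_peaks <- function(values, prior_stable_mean = NULL,
                                 ratio_constraint = TRUE,
                                 ratio_bounds = c(1.8, 2.2),
                                 min_values = 1000L,
                                 zero_exclusion = 0.15) {
  if (!is.numeric(values)) abort_validation("`values` must be numeric")
  values <- values[!is.na(values)]
  if (length(values) < min_values) {
    abort_validation(sprintf("need at least %d depth values, got %d",
                             min_values, length(values)))
  }
  if (any(values < 0)) abort_validation("depth values must be >= 0")

  pos <- values[values > 0]
  if (length(pos) < 10L) abort_calibration("almost all depth values are zero")
  cut <- zero_exclusion * median(pos)
  v <- pos[pos >= cut]
  n_excluded <- length(values) - length(v)

  if (sd(v) == 0) {
    return(single_mode_result(v[1L], prior_stable_mean, ratio_constraint,
                              n_used = length(v), n_excluded = n_excluded,
                              v = v))
  }

  d <- density(v, bw = "nrd0")
  y <- d$y
  is_max <- c(FALSE, y[2:(length(y) - 1L)] > y[1:(length(y) - 2L)] &
                y[2:(length(y) - 1L)] >= y[3:length(y)], FALSE)
  is_max <- is_max & y > 0.02 * max(y)
  modes <- d$x[is_max]
  heights <- y[is_max]
  modes_keep <- modes > 0
  modes <- modes[modes_keep]; heights <- heights[modes_keep]

  if (length(modes) < 2L) {
    m <- if (length(modes) == 1L) modes[1L] else median(v)
    return(single_mode_result(m, prior_stable_mean, ratio_constraint,
                              n_used = length(v), n_excluded = n_excluded,
                              bw = d$bw, v = v))
  }

  # Soft ratio constraint: candidate KDE mode pairs are scored by distance
  # of their ratio from 2 (raw modes of skewed components can sit slightly
  # off 2:1); the hard bounds are enforced on the EM-refined means.
  pairs <- expand.grid(i = seq_along(modes), j = seq_along(modes))
  pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
  ratio <- modes[pairs$j] / modes[pairs$i]
  score <- abs(log(ratio) - log(2))
  if (!is.null(prior_stable_mean)) {
    score <- score + 0.5 * abs(log(modes[pairs$j] / prior_stable_mean))
  }
  loose <- if (ratio_constraint) ratio >= 1.4 & ratio <= 2.9
           else rep(TRUE, length(ratio))
  if (!any(loose)) {
    if (!is.null(prior_stable_mean)) {
      anchor <- modes[which.min(abs(log(modes / prior_stable_mean)))]
      return(single_mode_result(anchor, prior_stable_mean, ratio_constraint = FALSE,
                                n_used = length(v), n_excluded = n_excluded,
                                bw = d$bw, v = v))
    }
    abort_calibration(sprintf(
      "no mode pair with a plausible homozygous:hemizygous ratio; detected modes: %s",
      paste(sprintf("%.1f", modes), collapse = ", ")
    ))
  }
  sc <- ifelse(loose, score, Inf)
  mass <- heights[pairs$i] * heights[pairs$j]
  best <- order(sc, -mass)[1L]
  kde_pair <- c(modes[pairs$i[best]], modes[pairs$j[best]])

  em <- mixture_em(v, kde_pair)
  lam <- sort(em$mu)
  method <- "kde+em"
  bad <- function(l) l[2L] / l[1L] < ratio_bounds[1L] | l[2L] / l[1L] > ratio_bounds[2L]
  if (ratio_constraint && bad(lam)) {
    if (!bad(kde_pair)) {
      lam <- kde_pair  # EM wandered off the 2:1 structure; keep the KDE modes
      method <- "kde"
    } else {
      abort_calibration(sprintf(
        "estimated peaks %.2f / %.2f violate the ratio constraint [%.2f, %.2f]",
        lam[1L], lam[2L], ratio_bounds[1L], ratio_bounds[2L]))
    }
  }
  structure(
    list(lambda1 = lam[1L], lambda2 = lam[2L], ratio = lam[2L] / lam[1L],
         method = method, modes = modes, bw = d$bw, n_used = length(v),
         n_excluded = n_excluded, em_iterations = em$iterations),
    class = "pav_depth_peaks"
  )
}

single_mode_result <- function(mode, prior, ratio_constraint, n_used,
                               n_excluded, bw = NA_real_, v = NULL) {
  if (is.null(prior) && ratio_constraint) {
    abort_calibration(sprintf(
      "depth distribution is unimodal (mode %.2f); cannot separate hemizygous and homozygous peaks",
      mode
    ))
  }
  # the raw KDE mode of a right-skewed depth component sits below its
  # mean; refine with a local window mean around the mode
  if (!is.null(v)) {
    win <- v[v >= mode / 1.5 & v <= mode * 1.5]
    if (length(win) >= 100L) mode <- mean(win)
  }
  homo <- if (!is.null(prior)) {
    abs(log(mode / prior)) <= abs(log(mode / (prior / 2)))
  } else TRUE  # documented fallback: single mode = homozygous
  lam <- if (homo) c(mode / 2, mode) else c(mode, 2 * mode)
  structure(
    list(lambda1 = lam[1L], lambda2 = lam[2L], ratio = 2,
         method = "single-mode-fallback", modes = mode, bw = bw,
         n_used = n_used, n_excluded = n_excluded, em_iterations = 0L),
    class = "pav_depth_peaks"
  )
}

#' @export
print.pav_depth_peaks <- function(x, ...) {
  cat(sprintf("pav_depth_peaks: lambda1 = %.2fX, lambda2 = %.2fX (ratio %.2f, %s)\n",
              x$lambda1, x$lambda2, x$ratio, x$method))
  invisible(x)
}

# Two-component mixture EM with free means/variances/weights, initialized
# at the KDE mode pair. Sequencing depth is right-skewed and over-dispersed,
# so integer (per-base count) input is modeled with negative-binomial
# components — a normal mixture would let the wide homozygous component
# absorb the hemizygous right tail and bias both means low. Continuous
# input (per-gene mean depths, central-limit averaged and nearly
# symmetric) uses moment-matched gamma components. M-steps update means
# and variances by weighted moments.
mixture_em <- function(v, init_mu, max_iter = 100L, tol = 1e-6) {
  counts <- all(v == round(v))
  if (counts) {
    # counts may sit on a lattice c*Z (e.g. rescaled tracks); fit NB on
    # the unit lattice and scale back, keeping the estimator
    # scale-equivariant
    gcd2 <- function(a, b) { while (b) { t <- b; b <- a %% b; a <- t }; a }
    step <- Reduce(gcd2, unique(round(v)))
    if (step > 1) {
      out <- mixture_em(v / step, init_mu / step, max_iter, tol)
      out$mu <- out$mu * step
      out$va <- out$va * step^2
      return(out)
    }
  }
  mu <- as.numeric(init_mu)
  va <- rep(max((diff(init_mu) / 4)^2, 1e-6), 2L)
  w <- c(0.5, 0.5)
  comp_density <- function(k) {
    if (counts && va[k] > mu[k]) {
      dnbinom(v, mu = mu[k], size = mu[k]^2 / (va[k] - mu[k]))
    } else {
      dgamma(v, shape = mu[k]^2 / va[k], rate = mu[k] / va[k])
    }
  }
  for (it in seq_len(max_iter)) {
    d1 <- w[1L] * comp_density(1L)
    d2 <- w[2L] * comp_density(2L)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 2 || n2 < 2) break
    mu_new <- c(sum(r1 * v) / n1, sum(r2 * v) / n2)
    va <- pmax(c(sum(r1 * (v - mu_new[1L])^2) / n1,
                 sum(r2 * (v - mu_new[2L])^2) / n2), 1e-6)
    w <- c(n1, n2) / length(v)
    delta <- max(abs(mu_new - mu) / pmax(mu, 1e-12))
    mu <- mu_new
    if (delta < tol) break
  }
  list(mu = mu, va = va, w = w, iterations = it)
}

#' Calibrate every individual of a coverage matrix
#'
#' Estimates each individual's hemizygous (`lambda1`) and homozygous
#' (`lambda2`) depth expectations, anchored on a set of coverage-stable
#' genes. Genes that are coverage-stable across all individuals sit in
#' homozygous regions everywhere, so with `method = "stable-median"`
#' (default) an individual's median stable-gene depth is its homozygous
#' expectation and `lambda1 = lambda2 / 2` — a nearly unbiased anchor.
#' With `method = "peaks"` the peaks are instead estimated from the
#' individual's per-gene depth distribution with
#' [estimate_depth_peaks()], using the stable-gene median as prior.
#'
#' @param x a `pav_coverage_matrix`.
#' @param stable_genes optional precomputed stable gene ids; default:
#'   [select_stable_genes()] with the given parameters.
#' @param method `"stable-median"` or `"peaks"`.
#' @inheritParams select_stable_genes
#' @inheritParams estimate_depth_peaks
#' @return Named list (by individual) of `pav_calibration` objects, each
#'   with `individual_id`, `lambda1`, `lambda2`, `stable_gene_ids` and
#'   method metadata.
#' @export
calibrate_individuals <- function(x, stable_genes = NULL,
                                  method = c("stable-median", "peaks"),
                                  cv_max = 0.2, min_relative_depth = 0.5,
                                  target_count = 4000,
                                  ratio_constraint = TRUE,
                                  ratio_bounds = c(1.8, 2.2)) {
  stopifnot(inherits(x, "pav_coverage_matrix"))
  method <- match.arg(method)
  if (is.null(stable_genes)) {
    stable_genes <- select_stable_genes(x, cv_max, min_relative_depth, target_count)
  }
  missing_ids <- setdiff(stable_genes, rownames(x$raw))
  if (length(missing_ids)) abort_validation("stable gene ids not in matrix")
  out <- lapply(x$individuals, function(id) {
    prior <- median(x$raw[stable_genes, id])
    if (method == "stable-median") {
      if (prior <= 0) abort_calibration(sprintf("zero stable-gene depth for '%s'", id))
      res <- list(lambda1 = prior / 2, lambda2 = prior,
                  method = "stable-median", bw = NA_real_, em_iterations = 0L)
    } else {
      peaks <- estimate_depth_peaks(x$raw[, id], prior_stable_mean = prior,
                                    ratio_constraint = ratio_constraint,
                                    ratio_bounds = ratio_bounds,
                                    min_values = min(1000L, nrow(x$raw)))
      res <- list(lambda1 = peaks$lambda1, lambda2 = peaks$lambda2,
                  method = peaks$method, bw = peaks$bw,
                  em_iterations = peaks$em_iterations)
    }
    structure(
      c(list(individual_id = id), res,
        list(stable_gene_ids = stable_genes, prior_stable_mean = prior)),
      class = "pav_calibration"
    )
  })
  names(out) <- x$individuals
  out
}

#' @export
print.pav_calibration <- function(x, ...) {
  cat(sprintf("pav_calibration '%s': lambda1 = %.2fX, lambda2 = %.2fX (%s)\n",
              x$individual_id, x$lambda1, x$lambda2, x$method))
  invisible(x)
}

#' Normalize a coverage matrix to one-allele units
#'
#' Divides each individual's raw per-gene depths by that individual's
#' one-allele depth `lambda1`, so a normalized value of 1.0 means the
#' depth expected for a gene in a hemizygous region and 2.0 the depth
#' expected for a homozygous gene.
#'
#' @param x a `pav_coverage_matrix`.
#' @param calibrations named list of `pav_calibration` objects (one per
#'   individual), e.g. from [calibrate_individuals()].
#' @return The matrix with its `normalized` layer filled.
#' @export
normalize_matrix <- function(x, calibrations) {
  stopifnot(inherits(x, "pav_coverage_matrix"))
  if (inherits(calibrations, "pav_calibration")) calibrations <- list(calibrations)
  ids <- vapply(calibrations, function(c) c$individual_id, character(1))
  names(calibrations) <- ids
  missing_ids <- setdiff(x$individuals, ids)
  if (length(missing_ids)) {
    abort_validation(sprintf("missing calibration for: %s",
                             paste(missing_ids, collapse = ", ")))
  }
  lam1 <- vapply(x$individuals, function(id) calibrations[[id]]$lambda1, numeric(1))
  if (any(lam1 <= 0)) abort_validation("lambda1 must be > 0")
  norm <- sweep(x$raw, 2L, lam1, "/")
  meta <- x$meta
  meta$lambda1 <- setNames(lam1, x$individuals)
  meta$lambda2 <- vapply(x$individuals, function(id) calibrations[[id]]$lambda2,
                         numeric(1))
  new_coverage_matrix(x$raw, normalized = norm, meta = meta)
}
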