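# Zygosity calling: classify each gene in each individual as absent (0),
# hemizygous (1) or homozygous (2) from normalized coverage, and partition
# the gene complement into core and dispensable sets.

#' Classify normalized coverage into allele counts
#'
#' A gene is called absent when its normalized coverage does not exceed the
#' presence threshold `t_p` (default 0.25, i.e. less than 25% of the depth
#' expected for a gene in a hemizygous region; equality counts as absent),
#' hemizygous when it lies in (`t_p`, `t_h`\], and homozygous above `t_h`
#' (default 1.5, the midpoint of the one- and two-allele expectations).
#'
#' @param normalized_coverage numeric vector of normalized coverage values
#'   (1.0 = one-allele expectation); must be >= 0.
#' @param t_p presence threshold.
#' @param t_h hemizygous/homozygous boundary (> `t_p`).
#' @return Integer vector of calls in \{0, 1, 2\}.
#' @export
#' @examples
#' classify_gene(c(0, 0.2, 0.25, 1.0, 1.6))  # 0 0 0 1 2
classify_gene <- function(normalized_coverage, t_p = 0.25, t_h = 1.5) {
  if (!is.numeric(normalized_coverage)) abort_validation("coverage must be numeric")
  if (any(is.na(normalized_coverage)) || any(normalized_coverage < 0)) {
    abort_validation("normalized coverage must be >= 0 and non-missing")
  }
  if (!is.numeric(t_p) || !is.numeric(t_h) || t_p <= 0 || t_h <= t_p) {
    abort_config("thresholds must satisfy 0 < t_p < t_h")
  }
  ifelse(normalized_coverage <= t_p, 0L,
         ifelse(normalized_coverage <= t_h, 1L, 2L))
}

#' Call zygosity for a whole coverage matrix
#'
#' Applies [classify_gene()] elementwise to the normalized layer; the
#' thresholds used are recorded in the result.
#'
#' @param x a `pav_coverage_matrix` with the normalized layer filled
#'   (see [normalize_matrix()]).
#' @inheritParams classify_gene
#' @return An object of class `pav_zygosity`: `calls` (genes x individuals,
#'   values 0/1/2), the `normalized` layer, and `t_p`, `t_h`.
#' @export
call_matrix <- function(x, t_p = 0.25, t_h = 1.5) {
  stopifnot(inherits(x, "pav_coverage_matrix"))
  if (is.null(x$normalized)) {
    abort_validation("matrix has no normalized layer; run normalize_matrix() first")
  }
  calls <- matrix(classify_gene(as.vector(x$normalized), t_p, t_h),
                  nrow = nrow(x$normalized),
                  dimnames = dimnames(x$normalized))
  structure(
    list(calls = calls, normalized = x$normalized,
         genes = rownames(calls), individuals = colnames(calls),
         t_p = t_p, t_h = t_h),
    class = "pav_zygosity"
  )
}

#' @export
print.pav_zygosity <- function(x, ...) {
  cat(sprintf("pav_zygosity: %d genes x %d individuals (t_p = %g, t_h = %g)\n",
              nrow(x$calls), ncol(x$calls), x$t_p, x$t_h))
  tab <- table(factor(x$calls, levels = 0:2))
  cat(sprintf("  calls: 0 (absent) %d | 1 (hemizygous) %d | 2 (homozygous) %d\n",
              tab[1L], tab[2L], tab[3L]))
  invisible(x)
}

#' Partition genes into core and dispensable sets
#'
#' A gene is core when it is present (call >= 1) in every individual and
#' dispensable when it is absent in one or more individuals. Genes
#' annotated on accessory contigs — sequence absent from the reference
#' assembly — are dispensable by definition and are supplied as extra ids
#' via `accessory_genes`; they must not collide with ids already in the
#' call matrix.
#'
#' @param z a `pav_zygosity` object.
#' @param accessory_genes optional character vector of accessory-contig
#'   gene ids (not present in the reference annotation).
#' @return An object of class `pav_partition`: `core`, `dispensable`
#'   (including accessory genes), `accessory`, per-gene `absence_count`
#'   (NA for accessory genes, which are not covered by the call matrix),
#'   and a `per_individual` data frame of missing-gene counts/fractions.
#' @export
partition_core_dispensable <- function(z, accessory_genes = NULL) {
  stopifnot(inherits(z, "pav_zygosity"))
  if (ncol(z$calls) < 2L) {
    warning("partition computed from a single individual: core/dispensable degenerates to present/absent")
  }
  accessory_genes <- unique(as.character(accessory_genes %||% character(0)))
  clash <- intersect(accessory_genes, z$genes)
  if (length(clash)) {
    abort_validation(sprintf("accessory gene ids collide with reference gene ids: %s",
                             paste(head(clash, 5L), collapse = ", ")))
  }
  absence <- rowSums(z$calls == 0L)
  core <- z$genes[absence == 0L]
  dispensable <- c(z$genes[absence > 0L], accessory_genes)
  absence_count <- c(absence, setNames(rep(NA_integer_, length(accessory_genes)),
                                       accessory_genes))
  n_genes <- nrow(z$calls)
  per_individual <- data.frame(
    individual_id = z$individuals,
    n_missing = colSums(z$calls == 0L),
    fraction_missing = colSums(z$calls == 0L) / n_genes,
    stringsAsFactors = FALSE, row.names = NULL
  )
  stopifnot(length(intersect(core, dispensable)) == 0L,
            setequal(c(core, dispensable), c(z$genes, accessory_genes)))
  structure(
    list(core = core, dispensable = dispensable, accessory = accessory_genes,
         absence_count = absence_count, per_individual = per_individual,
         t_p = z$t_p, t_h = z$t_h),
    class = "pav_partition"
  )
}

#' @export
print.pav_partition <- function(x, ...) {
  cat(sprintf("pav_partition: %d core, %d dispensable (%d on accessory contigs)\n",
              length(x$core), length(x$dispensable), length(x$accessory)))
  cat(sprintf("  mean missing per individual: %.1f genes (%.2f%%)\n",
              mean(x$per_individual$n_missing),
              100 * mean(x$per_individual$fraction_missing)))
  invisible(x)
}

#' Cross-tabulate zygosity states against a reference individual
#'
#' For each zygosity state a gene has in the reference individual, computes
#' the mean fraction of each state the same genes show in the other
#' individuals. Rows (reference states) sum to 1. This summarizes, e.g.,
#' how often genes hemizygous in the reference are absent, hemizygous or
#' homozygous elsewhere.
#'
#' @param z a `pav_zygosity` object.
#' @param reference_individual id of the reference individual.
#' @return A 3 x 3 matrix (reference state x other-individual state) of
#'   mean fractions.
#' @export
zygosity_crosstab <- function(z, reference_individual) {
  stopifnot(inherits(z, "pav_zygosity"))
  if (!reference_individual %in% z$individuals) {
    abort_validation(sprintf("unknown reference individual '%s'", reference_individual))
  }
  others <- setdiff(z$individuals, reference_individual)
  if (length(others) == 0L) others <- reference_individual
  ref <- z$calls[, reference_individual]
  out <- matrix(NA_real_, 3L, 3L,
                dimnames = list(reference = 0:2, other = 0:2))
  for (s in 0:2) {
    idx <- ref == s
    if (!any(idx)) next
    frac <- sapply(others, function(o) {
      tabulate(z$calls[idx, o] + 1L, nbins = 3L) / sum(idx)
    })
    out[s + 1L, ] <- rowMeans(frac)
  }
  out
}

#' Write zygosity calls and partition tables as TSV
#'
#' @param z a `pav_zygosity` object.
#' @param path output path.
#' @export
write_zygosity <- function(z, path) {
  stopifnot(inherits(z, "pav_zygosity"))
  df <- data.frame(gene_id = rownames(z$calls), z$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_zygosity
#' @param p a `pav_partition` object.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "pav_partition"))
  genes <- c(p$core, p$dispensable)
  df <- data.frame(
    gene_id = genes,
    status = c(rep("core", length(p$core)), rep("dispensable", length(p$dispensable))),
    accessory = genes %in% p$accessory,
    absence_count = p$absence_count[genes],
    stringsAsFactors = FALSE, row.names = NULL
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
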