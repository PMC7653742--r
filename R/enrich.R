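# Hypergeometric over/under-representation of annotation terms among
# dispensable genes, with Benjamini-Hochberg FDR control per direction.

#' Exact hypergeometric tail probabilities
#'
#' For a universe of `N` genes of which `K` carry a term, and a drawn set
#' of `n` genes of which `x` carry it: `p_over = P[X >= x]` and
#' `p_under = P[X <= x]` under the hypergeometric null. The two tails
#' overlap in the observed outcome, so `p_over + p_under = 1 + P[X = x]`.
#'
#' @param N universe size (genes).
#' @param K genes in the universe carrying the term.
#' @param n size of the tested set (e.g. dispensable genes).
#' @param x genes in the tested set carrying the term.
#' @return A list: `p_over`, `p_under`.
#' @export
#' @examples
#' hypergeom_tail(10, 4, 5, 4)$p_over  # 6/252
hypergeom_tail <- function(N, K, n, x) {
  N <- check_count(N, "N"); K <- check_count(K, "K")
  n <- check_count(n, "n"); x <- check_count(x, "x")
  if (K > N || n > N) abort_validation("K and n must not exceed N")
  if (x > min(K, n) || x < max(0L, n + K - N)) {
    abort_validation("x outside the feasible hypergeometric range")
  }
  list(p_over = phyper(x - 1L, K, N - K, n, lower.tail = FALSE),
       p_under = phyper(x, K, N - K, n))
}

#' Benjamini-Hochberg step-up q-values
#'
#' FDR adjustment with monotonicity enforcement; the input order is
#' preserved in the output.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues < 0 | pvalues > 1)) {
    abort_validation("p-values must be numbers in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Term enrichment of the dispensable gene set
#'
#' One hypergeometric test per annotation term: the universe is every gene
#' in the partition (genes without annotated terms stay in the universe),
#' the drawn set is the dispensable genes. Over- and under-representation
#' tails are FDR-adjusted as separate families; a term gets a direction
#' when its q-value for that tail is at most `alpha` and its fold change
#' points the same way.
#'
#' @param partition a `pav_partition` ([partition_core_dispensable()]).
#' @param annotation data frame with columns `gene_id`, `term` (one row
#'   per gene-term association; genes may carry several terms).
#' @param alpha FDR threshold for assigning a direction.
#' @param min_term_size smallest term (genes in universe) tested.
#' @return Data frame sorted by q-value: `term`, `N`, `K`, `n`, `x`,
#'   `fold`, `p_over`, `p_under`, `q_over`, `q_under`, `direction`.
#' @export
enrich_partition <- function(partition, annotation, alpha = 0.05,
                             min_term_size = 5L) {
  stopifnot(inherits(partition, "pav_partition"))
  if (!is.data.frame(annotation) ||
      !all(c("gene_id", "term") %in% names(annotation))) {
    abort_validation("`annotation` must have columns gene_id and term")
  }
  alpha <- check_fraction(alpha, "alpha", open_lo = TRUE)
  min_term_size <- check_count(min_term_size, "min_term_size", min = 1L)

  universe <- c(partition$core, partition$dispensable)
  disp <- partition$dispensable
  if (length(disp) == 0L) {
    warning("empty dispensable set; no enrichment computed")
    return(data.frame())
  }
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term")])
  N <- length(universe)
  n <- length(disp)
  K_tab <- table(ann$term)
  terms <- names(K_tab)[K_tab >= min_term_size]
  if (length(terms) == 0L) return(data.frame())
  x_tab <- table(factor(ann$term[ann$gene_id %in% disp], levels = terms))

  rows <- lapply(terms, function(tm) {
    K <- as.integer(K_tab[[tm]]); x <- as.integer(x_tab[[tm]])
    tails <- hypergeom_tail(N, K, n, x)
    data.frame(term = tm, N = N, K = K, n = n, x = x,
               fold = (x / n) / (K / N),
               p_over = tails$p_over, p_under = tails$p_under,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_over <- bh_fdr(res$p_over)
  res$q_under <- bh_fdr(res$p_under)
  res$direction <- ifelse(res$q_over <= alpha & res$fold > 1, "over",
                   ifelse(res$q_under <= alpha & res$fold < 1, "under", "none"))
  res[order(pmin(res$q_over, res$q_under)), , drop = FALSE]
}
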