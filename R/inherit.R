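# Mendelian segregation of dispensable genes in controlled crosses.
# A gene carried in c copies by a parent is transmitted with probability
# c/2; offspring copy number is the convolution of the two transmissions.

#' Mendelian offspring copy-number expectation for a cross
#'
#' Each parent transmits the gene with probability `copies / 2` (0, 1/2 or
#' 1 for 0, 1 or 2 copies). The offspring copy-number distribution is the
#' product convolution of the two transmissions; all probabilities are
#' multiples of 1/4 and exact. For two hemizygous parents (1, 1) the
#' distribution is (1/4, 1/2, 1/4), so the gene is expected to be entirely
#' absent — PAV — in 25% of the offspring.
#'
#' @param c1,c2 parental copy numbers, each in \{0, 1, 2\}.
#' @return Object of class `cross_expectation`: `p` (named probabilities
#'   for 0/1/2 copies), `p_absent` (= p\["0"\]), `parents`.
#' @export
#' @examples
#' mendelian_expectation(1, 1)$p_absent  # 0.25
mendelian_expectation <- function(c1, c2) {
  for (c in list(c1, c2)) {
    if (!is.numeric(c) || length(c) != 1L || is.na(c) || !(c %in% 0:2)) {
      abort_validation("parental copy numbers must be 0, 1 or 2")
    }
  }
  t1 <- c1 / 2; t2 <- c2 / 2
  p <- c("0" = (1 - t1) * (1 - t2),
         "1" = t1 * (1 - t2) + (1 - t1) * t2,
         "2" = t1 * t2)
  stopifnot(sum(p) == 1)
  structure(list(p = p, p_absent = unname(p["0"]), parents = c(c1, c2)),
            class = "cross_expectation")
}

#' @export
print.cross_expectation <- function(x, ...) {
  cat(sprintf(
    "cross_expectation (%d x %d copies): P(0) = %g, P(1) = %g, P(2) = %g\n",
    x$parents[1L], x$parents[2L], x$p["0"], x$p["1"], x$p["2"]))
  invisible(x)
}

# Exact two-sided binomial p-value, minlike convention: the sum of the
# probabilities of all outcomes no more likely than the observed one.
binom_minlike_p <- function(x, n, p0) {
  if (p0 == 0) return(if (x == 0L) 1 else 0)
  if (p0 == 1) return(if (x == n) 1 else 0)
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[x + 1L] * (1 + 1e-7)])
}

#' Exact test of observed family PAV counts against a Mendelian expectation
#'
#' Tests the number of offspring entirely lacking the gene against the
#' Mendelian absence probability with an exact two-sided binomial test
#' (appropriate for the very small families typical of controlled
#' crosses). The two-sided p-value follows the minimum-likelihood
#' convention: the sum of the probabilities of all outcomes whose
#' probability does not exceed that of the observed one. The observation
#' is called "compatible" with Mendelian inheritance when p >= `alpha`.
#'
#' @param n_absent number of offspring in which the gene is absent.
#' @param n_offspring total number of offspring scored.
#' @param expectation a [mendelian_expectation()] result (or a bare
#'   absence probability).
#' @param alpha significance level for the verdict.
#' @return A list: `p_value`, `verdict` ("compatible"/"incompatible"),
#'   `p_absent`, `n_absent`, `n_offspring`.
#' @export
#' @examples
#' test_family(1, 3, mendelian_expectation(1, 1))  # p = 1: 1/3 absent vs 25%
test_family <- function(n_absent, n_offspring, expectation, alpha = 0.05) {
  n_absent <- check_count(n_absent, "n_absent")
  n_offspring <- check_count(n_offspring, "n_offspring", min = 1L)
  if (n_absent > n_offspring) abort_validation("n_absent exceeds n_offspring")
  p0 <- if (inherits(expectation, "cross_expectation")) expectation$p_absent
        else check_fraction(expectation, "expectation")
  p <- binom_minlike_p(n_absent, n_offspring, p0)
  list(p_value = p,
       verdict = if (p >= alpha) "compatible" else "incompatible",
       p_absent = p0, n_absent = n_absent, n_offspring = n_offspring)
}

#' Test a table of family observations
#'
#' Convenience wrapper over [mendelian_expectation()] and [test_family()]
#' for a table with one row per (family, gene).
#'
#' @param families data frame with columns `family_id`, `gene_id`,
#'   `parent1_call`, `parent2_call`, `n_present`, `n_absent`.
#' @param alpha significance level.
#' @return The input with `p_absent_expected`, `p_value` and `verdict`
#'   columns appended.
#' @export
test_families <- function(families, alpha = 0.05) {
  need <- c("family_id", "gene_id", "parent1_call", "parent2_call",
            "n_present", "n_absent")
  if (!is.data.frame(families) || !all(need %in% names(families))) {
    abort_validation(sprintf("`families` must have columns: %s",
                             paste(need, collapse = ", ")))
  }
  if (any(families$n_present + families$n_absent < 1L)) {
    abort_validation("each family must have at least one scored offspring")
  }
  res <- lapply(seq_len(nrow(families)), function(i) {
    e <- mendelian_expectation(families$parent1_call[i], families$parent2_call[i])
    t <- test_family(families$n_absent[i],
                     families$n_present[i] + families$n_absent[i], e, alpha)
    data.frame(p_absent_expected = t$p_absent, p_value = t$p_value,
               verdict = t$verdict, stringsAsFactors = FALSE)
  })
  cbind(families, do.call(rbind, res))
}
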