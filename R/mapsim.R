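# Mapping-artifact simulation: could allelic sequence divergence, under a
# mismatch-limited end-to-end mapper, depress coverage enough to mimic gene
# absence? Reads are modeled as fixed-length with independent per-base
# substitutions; a read is retained iff its mismatch count is <= the
# mapper's tolerance.

#' Analytic read-retention fraction under divergence
#'
#' The fraction of length-`L` reads retained by a mapper tolerating at
#' most `m` mismatches, when the template diverges from the reference by
#' a per-base substitution probability `d`:
#' `r = sum_{k=0..m} C(L,k) d^k (1-d)^(L-k)` — the binomial(L, d) lower
#' tail, computed stably for large L.
#'
#' @param L read length (bp).
#' @param d per-base divergence in \[0, 1).
#' @param m mismatch tolerance (0..L).
#' @return Retention fraction in \[0, 1\].
#' @export
#' @examples
#' retention_analytic(100, 0.01, 2)  # ~0.9206
retention_analytic <- function(L, d, m) {
  L <- check_count(L, "L", min = 1L)
  d <- check_fraction(d, "d", open_hi = TRUE)
  m <- check_count(m, "m")
  if (m > L) abort_validation("`m` must be <= L")
  pbinom(m, L, d)
}

#' Monte-Carlo read-retention estimate
#'
#' Stochastic cross-check of [retention_analytic()]: draws per-read
#' mismatch counts from Binomial(L, d) and reports the retained fraction
#' with its binomial standard error.
#'
#' @inheritParams retention_analytic
#' @param n_reads number of simulated reads.
#' @param seed integer seed.
#' @return A list: `retention`, `se`, `n_reads`.
#' @export
retention_montecarlo <- function(L, d, m, n_reads, seed = NULL) {
  L <- check_count(L, "L", min = 1L)
  d <- check_fraction(d, "d", open_hi = TRUE)
  m <- check_count(m, "m")
  if (m > L) abort_validation("`m` must be <= L")
  n_reads <- check_count(n_reads, "n_reads", min = 1L)
  with_seed(seed, {
    mism <- rbinom(n_reads, L, d)
    r <- mean(mism <= m)
    list(retention = r, se = sqrt(r * (1 - r) / n_reads), n_reads = n_reads)
  })
}

#' Minimal divergence at which a present gene is miscalled absent
#'
#' Observed normalized coverage of a gene present in `copies` copies whose
#' alleles diverge from the reference by `d` is `copies * retention(L, d,
#' m)`. This solves for the smallest `d` at which that value drops to the
#' presence threshold `t_p`, i.e. the divergence a truly present gene
#' would need before coverage-based calling declares it absent. Values far
#' above plausible allelic divergence indicate that observed absences are
#' not mapping artifacts.
#'
#' @inheritParams retention_analytic
#' @param copies gene copy number (1 = hemizygous, 2 = homozygous).
#' @param t_p presence threshold on normalized coverage.
#' @param tol bisection tolerance on `d`.
#' @return A list: `d_star` (minimal divergence, or NA), `status`
#'   ("ok", "zero" when the gene is already below threshold, or
#'   "unreachable" when retention never drops to the threshold).
#' @export
divergence_to_absence <- function(L, m, copies, t_p = 0.25, tol = 1e-6) {
  L <- check_count(L, "L", min = 1L)
  m <- check_count(m, "m")
  if (m > L) abort_validation("`m` must be <= L")
  if (!copies %in% c(1, 2)) abort_validation("`copies` must be 1 or 2")
  t_p <- check_fraction(t_p, "t_p", lo = 0, hi = Inf, open_lo = TRUE)
  f <- function(d) copies * retention_analytic(L, d, m)
  if (t_p >= copies) return(list(d_star = 0, status = "zero"))
  if (m == L) return(list(d_star = NA_real_, status = "unreachable"))
  # f is continuous and strictly decreasing from `copies` to ~0 on [0, 1)
  lo <- 0; hi <- 1 - 1e-12
  if (f(hi) > t_p) return(list(d_star = NA_real_, status = "unreachable"))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) <= t_p) hi <- mid else lo <- mid
  }
  list(d_star = hi, status = "ok")
}

#' Retention and apparent-coverage curve over a divergence grid
#'
#' @inheritParams divergence_to_absence
#' @param d_grid numeric vector of divergence values.
#' @return Data frame: `d`, `retention`, `normalized_coverage`
#'   (`copies * retention`), `called_absent`.
#' @export
retention_curve <- function(L, m, copies = 1, t_p = 0.25,
                            d_grid = seq(0, 0.2, by = 0.002)) {
  r <- vapply(d_grid, function(d) retention_analytic(L, d, m), numeric(1))
  data.frame(d = d_grid, retention = r,
             normalized_coverage = copies * r,
             called_absent = copies * r <= t_p)
}
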