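test_that("hypergeometric tails match exhaustive enumeration", {
  t1 <- hypergeom_tail(10, 4, 5, 4)
  expect_equal(t1$p_over, 6 / 252, tolerance = 1e-12)
  t0 <- hypergeom_tail(10, 4, 5, 0)
  expect_equal(t0$p_under, 6 / 252, tolerance = 1e-12)

  # every gene carries the term: x is forced to n, p_over = 1
  tall <- hypergeom_tail(20, 20, 7, 7)
  expect_equal(tall$p_over, 1)

  set.seed(99)
  for (i in 1:12) {
    N <- sample(5:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    xr <- max(0, n + K - N):min(K, n)
    x <- xr[sample.int(length(xr), 1)]
    got <- hypergeom_tail(N, K, n, x)
    oracle <- hyper_enum_oracle(N, K, n, x)
    expect_equal(got$p_over, oracle$p_over, tolerance = 1e-12)
    expect_equal(got$p_under, oracle$p_under, tolerance = 1e-12)
    # tails overlap exactly in the observed outcome
    expect_equal(got$p_over + got$p_under, 1 + dhyper(x, K, N - K, n),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_tail(10, 11, 5, 3), class = "pavpan_validation_error")
  expect_error(hypergeom_tail(10, 4, 5, 5), class = "pavpan_validation_error")
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))

  # hand step-up oracle with monotonicity enforcement
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n); out[o] <- pmin(q, 1); out
  }
  set.seed(12)
  for (i in 1:10) {
    p <- runif(sample(3:30, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm], tolerance = 1e-12)
    # q non-decreasing in sorted-p order
    expect_true(all(diff(bh_fdr(p)[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "pavpan_validation_error")
})

make_partition_ids <- function(core, dispensable) {
  copies <- rbind(
    matrix(2L, length(core), 2),
    cbind(rep(0L, length(dispensable)), rep(2L, length(dispensable)))
  )
  dimnames(copies) <- list(c(core, dispensable), c("i1", "i2"))
  partition_core_dispensable(zygosity_from_copies(copies))
}

test_that("term enrichment assigns directions consistently with fold", {
  core <- sprintf("c%03d", 1:60)
  disp <- sprintf("d%03d", 1:30)
  part <- make_partition_ids(core, disp)

  ann <- rbind(
    data.frame(gene_id = disp[1:15], term = "survival"),      # dispensable-only
    data.frame(gene_id = core[1:40], term = "housekeeping"),  # core-only
    # balanced term: x/n == K/N exactly -> fold 1, no direction
    data.frame(gene_id = c(core[1:20], disp[1:10]), term = "balanced")
  )
  res <- enrich_partition(part, ann, alpha = 0.05)
  res <- res[order(res$term), ]
  expect_equal(res$direction[res$term == "survival"], "over")
  expect_gt(res$fold[res$term == "survival"], 1)
  expect_equal(res$direction[res$term == "housekeeping"], "under")
  expect_equal(res$fold[res$term == "balanced"], 1)
  expect_equal(res$direction[res$term == "balanced"], "none")
  # direction and fold always agree
  expect_true(all(res$fold[res$direction == "over"] > 1))
  expect_true(all(res$fold[res$direction == "under"] < 1))

  empty <- make_partition_ids(core, character(0))
  expect_warning(res0 <- enrich_partition(empty, ann), "empty dispensable")
  expect_equal(nrow(res0), 0)
})

test_that("a planted enriched term is recovered in almost all replicates", {
  core <- sprintf("c%03d", 1:350)
  disp <- sprintf("d%03d", 1:150)
  part <- make_partition_ids(core, disp)
  genes <- c(core, disp)

  hits <- pavpan:::with_seed(2024, {
    vapply(1:100, function(rep) {
      # background terms: random 30-gene sets; planted term carried by
      # dispensable genes 21x more often than core genes (3x fold)
      ann <- do.call(rbind, lapply(1:8, function(t) {
        data.frame(gene_id = sample(genes, 30), term = sprintf("bg%02d", t))
      }))
      planted <- c(disp[runif(150) < 0.315], core[runif(350) < 0.015])
      ann <- rbind(ann, data.frame(gene_id = planted, term = "planted"))
      res <- enrich_partition(part, ann, alpha = 0.05)
      row <- res[res$term == "planted", ]
      nrow(row) == 1 && row$direction == "over" && row$q_over <= 0.05
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})
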