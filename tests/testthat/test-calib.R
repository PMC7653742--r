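test_that("stable-gene selection keeps constant genes and drops dropouts", {
  raw <- rbind(
    stable1 = c(80, 80, 80, 80),
    stable2 = c(78, 82, 79, 81),
    dropout = c(80, 0, 80, 80),
    wild    = c(10, 160, 40, 90)
  )
  raw <- raw[rep(1:4, each = 30), ]  # enough rows to clear the minimum
  rownames(raw) <- paste0(rep(c("stable1", "stable2", "dropout", "wild"), each = 30),
                          "_", seq_len(120))
  m <- pavpan:::new_coverage_matrix(raw)
  sel <- select_stable_genes(m, target_count = 120)
  expect_true(all(grepl("stable", sel)))
  expect_true(any(grepl("stable1", sel)))
  expect_false(any(grepl("dropout|wild", sel)))
  # target_count caps the selection at the lowest-CV genes
  sel2 <- select_stable_genes(m, target_count = 10)
  expect_length(sel2, 10)
  expect_true(all(grepl("stable1", sel2)))
})

test_that("stable-gene selection recovers the constructed core set", {
  fx <- called_fixture(400, 130, 6, lambda = 40, seed = 71)
  sel <- select_stable_genes(fx$matrix, target_count = 4000)
  core <- fx$model$genes$gene_id[fx$model$genes$category == "core"]
  expect_gte(mean(sel %in% core), 0.95)
  recall <- mean(core %in% sel)
  expect_gte(recall, 0.95)
})

test_that("depth peaks are recovered from a bimodal diploid distribution", {
  v <- simulate_depth_values(120000, lambda_hap = 41.5, hemi_frac = 0.3,
                             dispersion = 0.05, seed = 13)
  p <- estimate_depth_peaks(v)
  expect_lt(abs(p$lambda1 - 41.5), 1.0)
  expect_lt(abs(p$lambda2 - 83), 2.0)
  expect_gte(p$ratio, 1.8); expect_lte(p$ratio, 2.2)

  # a 5% spike at zero is excluded and does not move the peaks
  v0 <- simulate_depth_values(120000, lambda_hap = 41.5, hemi_frac = 0.3,
                              zero_frac = 0.05, dispersion = 0.05, seed = 13)
  p0 <- estimate_depth_peaks(v0)
  expect_lt(abs(p0$lambda1 - p$lambda1), 0.5)
})

test_that("peak recovery error stays within 3% of a known haploid depth", {
  v <- simulate_depth_values(100000, lambda_hap = 25, hemi_frac = 0.4,
                             dispersion = 0.05, seed = 29)
  p <- estimate_depth_peaks(v)
  expect_lt(abs(p$lambda1 - 25) / 25, 0.03)
})

test_that("peak estimation is scale-equivariant", {
  v <- simulate_depth_values(60000, lambda_hap = 30, hemi_frac = 0.35,
                             dispersion = 0.05, seed = 17)
  p1 <- estimate_depth_peaks(v)
  p3 <- estimate_depth_peaks(3 * v)
  expect_lt(abs(p3$lambda1 / p1$lambda1 - 3) / 3, 0.02)
  expect_lt(abs(p3$lambda2 / p1$lambda2 - 3) / 3, 0.02)
})

test_that("degenerate depth distributions follow the documented fallbacks", {
  # all values identical, constraint disabled: single mode read as homozygous
  p <- estimate_depth_peaks(rep(84, 2000), ratio_constraint = FALSE)
  expect_equal(p$lambda1, 42)
  expect_equal(p$lambda2, 84)

  # unimodal under the constraint without a prior: calibration error
  v <- simulate_depth_values(20000, lambda_hap = 40, hemi_frac = 0,
                             dispersion = 0.05, seed = 3)
  expect_error(estimate_depth_peaks(v), class = "pavpan_calibration_error")
  # ... but a stable-gene prior resolves it
  p2 <- estimate_depth_peaks(v, prior_stable_mean = 80)
  expect_lt(abs(p2$lambda2 - 80) / 80, 0.05)

  expect_error(estimate_depth_peaks(c(1, 2, 3)),
               class = "pavpan_validation_error")
})

test_that("normalization divides by the one-allele depth per individual", {
  raw <- cbind(i1 = c(41.5, 83, 0), i2 = c(20, 40, 10))
  rownames(raw) <- c("gA", "gB", "gC")
  m <- pavpan:::new_coverage_matrix(raw)
  cals <- list(
    structure(list(individual_id = "i1", lambda1 = 41.5, lambda2 = 83),
              class = "pav_calibration"),
    structure(list(individual_id = "i2", lambda1 = 20, lambda2 = 40),
              class = "pav_calibration")
  )
  n <- normalize_matrix(m, cals)
  expect_equal(n$normalized[, "i1"], c(gA = 1, gB = 2, gC = 0))
  expect_equal(n$normalized[, "i2"], c(gA = 1, gB = 2, gC = 0.5))
  expect_error(normalize_matrix(m, cals[1]), class = "pavpan_validation_error")
})

test_that("normalized stable genes sit at the two-allele expectation", {
  fx <- called_fixture(300, 100, 6, lambda = 35, seed = 81)
  cal <- calibrate_individuals(fx$matrix, target_count = 1000)
  n <- normalize_matrix(fx$matrix, cal)
  stable <- cal[[1]]$stable_gene_ids
  med <- median(n$normalized[stable, ])
  expect_gte(med, 1.9); expect_lte(med, 2.1)
  for (c in cal) {
    expect_gte(c$lambda2 / c$lambda1, 1.8)
    expect_lte(c$lambda2 / c$lambda1, 2.2)
  }
})
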