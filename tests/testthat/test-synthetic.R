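test_that("spec validation rejects bad shapes with the field named", {
  v <- data.frame(id = "rs1", chrom = "1", pos = 100L, maf = 0.3)
  p <- data.frame(id = c("P1", "P2"), chrom = "1", start = 1, end = 2)
  expect_error(synthetic_spec(0, 0, v, p, alpha = 0, beta = matrix(0, 2, 1)),
               "n_samples")
  expect_error(synthetic_spec(10, 5, v, p, alpha = 0, beta = matrix(0, 3, 1)),
               "beta")
  expect_error(synthetic_spec(10, 5, v, p, alpha = 0, beta = matrix(0, 2, 1),
                              gamma = matrix(0, 2, 2), n_factors = 1L),
               "gamma")
  expect_error(synthetic_spec(10, 5, transform(v, maf = 0.6), p, alpha = 0,
                              beta = matrix(0, 2, 1)), "maf")
  expect_error(synthetic_spec(10, 5, v, p, alpha = 0, beta = matrix(0, 2, 1),
                              epsilon_sd = 0), "epsilon_sd")
})

test_that("null model: means are alpha, sds are epsilon_sd, genotypes HWE-binomial", {
  spec <- scenario_preset("null", n_samples = 4000, n_discovery = 3000, seed = 2)
  ch <- generate_cohort(spec)
  n <- spec$n_samples
  for (j in 1:2) {
    expect_lt(abs(mean(ch$proteins[, j]) - spec$alpha[j]), 3 / sqrt(n))
    expect_lt(abs(sd(ch$proteins[, j]) - 1), 3 / sqrt(n))
  }
  expect_true(all(ch$genotypes %in% 0:2))
  af <- mean(ch$genotypes[, 1]) / 2
  expect_lt(abs(af - 0.3), 3 * sqrt(0.3 * 0.7 / (2 * n)))
  expect_false(anyNA(ch$proteins))
  expect_equal(as.integer(table(ch$cohort)), c(3000L, 1000L))
})

test_that("ratio regression recovers beta1 - beta2 within its 95% CI", {
  spec <- scenario_preset("opposite_beta", n_samples = 10000,
                          n_discovery = 10000, beta = 0.3, seed = 8)
  ch <- generate_cohort(spec)
  truth <- spec$beta[1, 1] - spec$beta[2, 1]   # 0.6
  d <- ch$proteins[, "P1"] - ch$proteins[, "P2"]
  fit <- summary(lm(d ~ ch$genotypes[, "rs1"]))$coefficients
  expect_lt(abs(fit[2, 1] - truth), 1.96 * fit[2, 2])
})

test_that("cohort generation is deterministic given the seed", {
  spec <- scenario_preset("single_beta_shared_W", n_samples = 300,
                          n_discovery = 200, seed = 77)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$covariates, b$covariates)
  spec2 <- scenario_preset("single_beta_shared_W", n_samples = 300,
                           n_discovery = 200, seed = 78)
  expect_false(identical(generate_cohort(spec2)$proteins, a$proteins))
})

test_that("missingness is applied at the requested MCAR rate", {
  spec <- scenario_preset("null", n_samples = 2000, n_discovery = 1500, seed = 3)
  spec$missing_rate <- 0.1
  ch <- generate_cohort(spec)
  rate <- mean(is.na(ch$proteins))
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / length(ch$proteins)))
})

test_that("covariate effects propagate into protein levels", {
  v <- data.frame(id = "rs1", chrom = "1", pos = 100L, maf = 0.3)
  p <- data.frame(id = c("P1", "P2"), chrom = "1", start = 1, end = 2)
  ce <- rbind(c(0.05, 0, 0, 0, 0),  # P1 loads on age
              c(0, 0, 0, 0, 0))
  spec <- synthetic_spec(5000, 4000, v, p, alpha = c(0, 0),
                         beta = matrix(0, 2, 1), covariate_effects = ce,
                         seed = 4)
  ch <- generate_cohort(spec)
  fit <- summary(lm(ch$proteins[, "P1"] ~ ch$covariates$age))$coefficients
  expect_lt(abs(fit[2, 1] - 0.05), 1.96 * fit[2, 2] + 1e-9)
})

test_that("scenario presets encode their defining structure", {
  expect_error(scenario_preset("bogus"), "opposite_beta")
  nul <- scenario_preset("null")
  expect_true(all(nul$beta == 0) && nul$n_factors == 0L)
  opp <- scenario_preset("opposite_beta")
  expect_true(opp$beta[1, 1] > 0 && opp$beta[2, 1] == -opp$beta[1, 1])
  expect_equal(opp$n_factors, 0L)
  sbw <- scenario_preset("single_beta_shared_W")
  expect_true(sbw$beta[1, 1] != 0 && sbw$beta[2, 1] == 0)
  expect_true(sbw$gamma[1, 1] == sbw$gamma[2, 1] && sbw$gamma[1, 1] != 0)
  shr <- scenario_preset("shared_beta_shared_W")
  expect_equal(shr$beta[1, 1], shr$beta[2, 1])
  expect_equal(shr$gamma[1, 1], shr$gamma[2, 1])
})

test_that("shared beta + shared W: ratio association is null distributed", {
  # genetic and shared-factor terms cancel in the ratio; its p-values must be
  # uniform: KS test over independent small cohorts
  n_rep <- 200
  pvals <- vapply(seq_len(n_rep), function(k) {
    spec <- scenario_preset("shared_beta_shared_W", n_samples = 500,
                            n_discovery = 500, seed = 1000 + k)
    ch <- generate_cohort(spec)
    ratio <- make_ratio_phenotype(ch$proteins, c("P1", "P2"))
    10^(-linear_assoc(ratio, ch$genotypes[, "rs1"])$neglog10p)
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / n_rep) + 1e-12)
})

test_that("opposite beta amplifies the ratio signal over both single proteins", {
  reps <- 60
  med <- matrix(NA_real_, reps, 3)
  for (k in seq_len(reps)) {
    spec <- scenario_preset("opposite_beta", n_samples = 1000,
                            n_discovery = 1000, seed = 2000 + k)
    ch <- generate_cohort(spec)
    g <- ch$genotypes[, "rs1"]
    med[k, 1] <- linear_assoc(inverse_normal_transform(ch$proteins[, "P1"]), g)$neglog10p
    med[k, 2] <- linear_assoc(inverse_normal_transform(ch$proteins[, "P2"]), g)$neglog10p
    med[k, 3] <- linear_assoc(make_ratio_phenotype(ch$proteins, c("P1", "P2")), g)$neglog10p
  }
  expect_gt(median(med[, 3]), median(med[, 1]))
  expect_gt(median(med[, 3]), median(med[, 2]))
})
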