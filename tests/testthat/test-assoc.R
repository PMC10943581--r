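test_that("HWE exact test matches the full-enumeration oracle on all tables n <= 60", {
  worst <- 0
  for (n in c(2:20, 30, 40, 50, 60)) {
    for (n_AA in 0:n) for (n_Aa in 0:(n - n_AA)) {
      n_aa <- n - n_AA - n_Aa
      got <- hwe_exact_pvalue(n_AA, n_Aa, n_aa)
      want <- hwe_oracle_direct(n_AA, n_Aa, n_aa)
      worst <- max(worst, abs(got - want))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("HWE worked cases: equilibrium, monomorphic, extreme deficit", {
  expect_gt(hwe_exact_pvalue(25, 50, 25), 0.5)
  expect_identical(hwe_exact_pvalue(100, 0, 0), 1)
  expect_identical(hwe_exact_pvalue(0, 0, 42), 1)
  expect_lt(hwe_exact_pvalue(50, 0, 50), 1e-15)
  # stays finite and sane for large cohorts (log-space path)
  expect_lt(hwe_exact_pvalue(5000, 100, 5000), 1e-300)
  expect_gt(hwe_exact_pvalue(4900, 4200, 900), 0)
  expect_error(hwe_exact_pvalue(0, 0, 0), "> 0")
})

make_geno <- function(n, mafs, seed = 1) {
  set.seed(seed)
  g <- vapply(mafs, function(f) rbinom(n, 2, f), numeric(n))
  dimnames(g) <- list(sprintf("s%04d", 1:n), sprintf("v%02d", seq_along(mafs)))
  g
}

test_that("variant QC: clean matrix passes, each filter catches its target", {
  g <- make_geno(1000, c(0.3, 0.4), seed = 51)
  out <- variant_qc(g)
  expect_equal(dim(out), dim(g))
  rep <- attr(out, "qc_report")
  expect_equal(rep$variants_removed_total, 0)
  expect_equal(rep$samples_removed_mind, 0)

  # MAF filter
  g2 <- cbind(g, rare = c(rep(1, 10), rep(0, 990)))  # maf 0.005
  rownames(g2) <- rownames(g)
  out2 <- variant_qc(g2)
  expect_false("rare" %in% colnames(out2))
  expect_equal(attr(out2, "qc_report")$variants_removed_maf, 1)

  # HWE filter: (50, 0, 50) has exact p << 1e-15 at n = 100
  g3 <- make_geno(100, 0.5, seed = 52)
  g3 <- cbind(g3, hwe_bad = rep(c(0, 2), each = 50))
  rownames(g3) <- sprintf("s%04d", 1:100)
  out3 <- variant_qc(g3, mac_min = 10)
  expect_false("hwe_bad" %in% colnames(out3))
  expect_equal(attr(out3, "qc_report")$variants_removed_hwe, 1)

  # missingness filters: one bad sample (mind), one bad variant (geno);
  # with 20 variants a single missing call (5%) stays under the 10% mind cut
  g4 <- make_geno(200, rep(0.3, 20), seed = 53)
  g4[1, ] <- NA                    # sample 100% missing
  g4[2:50, "v03"] <- NA            # variant ~25% missing after mind filter
  out4 <- variant_qc(g4, mac_min = 10)
  expect_false("v03" %in% colnames(out4))
  expect_equal(attr(out4, "qc_report")$samples_removed_mind, 1)
  expect_false("s0001" %in% rownames(out4))
})

test_that("QC report counts are consistent: removed + retained = input", {
  g <- make_geno(300, c(0.3, 0.02, 0.005, 0.45), seed = 54)
  g[1:40, 1] <- NA
  out <- variant_qc(g, mac_min = 20, geno_max_missing = 0.05)
  rep <- attr(out, "qc_report")
  expect_equal(rep$variants_retained + rep$variants_removed_total, ncol(g))
  expect_equal(rep$samples_retained + rep$samples_removed_mind, nrow(g))
  expect_error(variant_qc(g, maf_min = 0.5), "tally")
})

test_that("linear association matches lm() and records complete-case n", {
  cohort <- toy_cohort(n = 600, seed = 55)
  y <- inverse_normal_transform(cohort$proteins[, "P1"])
  g <- cohort$genotypes[, "rs1"]
  cov <- cohort$covariates
  got <- linear_assoc(y, g, cov, trait = "P1", variant = "rs1")
  ref <- summary(lm(y ~ g + age + sex + PC1 + PC2 + PC3, data = cov))
  expect_equal(got$beta, ref$coefficients["g", 1], tolerance = 1e-12)
  expect_equal(got$se, ref$coefficients["g", 2], tolerance = 1e-12)
  expect_equal(got$neglog10p,
               -log10(2 * pt(abs(ref$coefficients["g", 3]), got$n - 7,
                             lower.tail = FALSE)),
               tolerance = 1e-9)
  expect_equal(got$n, 600)
  # missing phenotype entries shrink n
  y2 <- y; y2[1:13] <- NA
  expect_equal(linear_assoc(y2, g, cov)$n, 587)
})

test_that("linear association guards: perfect fit, monomorphic, too few cases", {
  g <- setNames(rep(c(0, 1, 2), length.out = 99), sprintf("s%02d", 1:99))
  y <- g * 1.0
  got <- linear_assoc(y, g)
  expect_identical(got$neglog10p, Inf)
  expect_error(linear_assoc(rnorm(99) |> setNames(names(g)),
                            setNames(rep(1, 99), names(g))), "monomorphic")
  expect_error(linear_assoc(y[1:3], g[1:3],
                            covariates = matrix(rnorm(6), 3,
                                                dimnames = list(names(g)[1:3], c("a", "b")))),
               "complete cases")
})

test_that("negating the INT phenotype flips beta, preserves -log10 p", {
  cohort <- toy_cohort(n = 400, seed = 56)
  y <- cohort$proteins[, "P1"]
  g <- cohort$genotypes[, "rs1"]
  a <- linear_assoc(inverse_normal_transform(y), g, cohort$covariates)
  b <- linear_assoc(inverse_normal_transform(-y), g, cohort$covariates)
  expect_equal(a$beta, -b$beta)
  expect_equal(a$neglog10p, b$neglog10p)
})

test_that("null simulation: p-values uniform at nominal level", {
  set.seed(57)
  n <- 150; reps <- 2000
  hits <- 0L
  for (r in seq_len(reps)) {
    g <- rbinom(n, 2, 0.3)
    y <- rnorm(n)
    rr <- cor(y, g)
    nlp <- neglog10_p_from_t(rr * sqrt((n - 2) / (1 - rr^2)), n - 2)
    hits <- hits + (nlp > -log10(0.05))
  }
  frac <- hits / reps
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("samples align by id, not order", {
  cohort <- toy_cohort(n = 300, seed = 58)
  y <- inverse_normal_transform(cohort$proteins[, "P1"])
  g <- cohort$genotypes[, "rs1"]
  perm <- sample(length(g))
  a <- linear_assoc(y, g, cohort$covariates)
  b <- linear_assoc(y, g[perm], cohort$covariates)
  expect_equal(a$beta, b$beta)
  expect_equal(a$neglog10p, b$neglog10p)
})
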