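make_reference <- function(pairs_mat, score = 0.9) {
  data.frame(protein1 = pairs_mat[, 1], protein2 = pairs_mat[, 2],
             score = rep(score, nrow(pairs_mat)), stringsAsFactors = FALSE)
}

test_that("fold enrichment: saturated and empty references", {
  universe <- sprintf("U%02d", 1:8)
  all_pairs <- t(combn(universe, 2))
  query <- data.frame(proteinA = all_pairs[1:5, 1], proteinB = all_pairs[1:5, 2])
  # reference contains every possible pair -> observed = expected = |query|
  res <- fold_enrichment(query, make_reference(all_pairs), universe = universe,
                         seed = 3)
  expect_equal(res$observed, 5)
  expect_equal(res$resampled_mean, 5)
  expect_equal(res$fold, 1)
  # empty reference -> observed 0, fold undefined
  res0 <- fold_enrichment(query, make_reference(all_pairs[0, , drop = FALSE]),
                          universe = universe, seed = 3)
  expect_equal(res0$observed, 0)
  expect_equal(res0$resampled_mean, 0)
  expect_true(is.na(res0$fold))
})

test_that("planted fixture matches the closed-form expected overlap", {
  # 20-protein universe, 30 reference pairs, query of 10 pairs with 8 links:
  # a random pair is a link with prob 30 / C(20,2), so the resampled mean
  # converges to 10 * 30/190 = 1.579 and fold to 8 / 1.579 = 5.07
  set.seed(81)
  universe <- sprintf("U%02d", 1:20)
  all_pairs <- t(combn(universe, 2))
  ref_rows <- sample(nrow(all_pairs), 30)
  reference <- make_reference(all_pairs[ref_rows, ])
  in_ref <- all_pairs[ref_rows[1:8], ]
  out_ref <- all_pairs[setdiff(seq_len(nrow(all_pairs)), ref_rows)[1:2], ]
  query <- data.frame(proteinA = c(in_ref[, 1], out_ref[, 1]),
                      proteinB = c(in_ref[, 2], out_ref[, 2]))
  res <- fold_enrichment(query, reference, universe = universe,
                         n_resamples = 400, seed = 82)
  expect_equal(res$observed, 8)
  expected_mean <- 10 * 30 / choose(20, 2)
  expect_lt(abs(res$resampled_mean - expected_mean),
            3 * res$resampled_sd / sqrt(res$n_resamples))
  expect_equal(res$fold, 8 / res$resampled_mean)
})

test_that("a random query converges to fold ~ 1", {
  set.seed(83)
  universe <- sprintf("U%02d", 1:25)
  all_pairs <- t(combn(universe, 2))
  reference <- make_reference(all_pairs[sample(nrow(all_pairs), 60), ])
  qi <- sample(nrow(all_pairs), 40)
  query <- data.frame(proteinA = all_pairs[qi, 1], proteinB = all_pairs[qi, 2])
  res <- fold_enrichment(query, reference, universe = universe,
                         n_resamples = 500, seed = 84)
  expect_lt(abs(res$observed - res$resampled_mean), 3 * res$resampled_sd)
})

test_that("resampling is deterministic given the seed; guards fire", {
  universe <- sprintf("U%02d", 1:10)
  all_pairs <- t(combn(universe, 2))
  reference <- make_reference(all_pairs[1:10, ])
  query <- data.frame(proteinA = all_pairs[1:6, 1], proteinB = all_pairs[1:6, 2])
  a <- fold_enrichment(query, reference, universe = universe, seed = 5)
  b <- fold_enrichment(query, reference, universe = universe, seed = 5)
  expect_identical(a[c("resampled_mean", "resampled_sd")],
                   b[c("resampled_mean", "resampled_sd")])
  expect_error(fold_enrichment(query, reference, universe = c("U01", "U02")),
               "distinct pairs")
  expect_error(fold_enrichment(query[0, ], reference, universe = universe),
               "non-empty")
  bad <- reference; bad$score <- 900
  expect_error(fold_enrichment(query, bad, universe = universe), "\\[0, 1\\]")
})

test_that("score threshold is strict and pair orientation ignored", {
  reference <- data.frame(protein1 = c("B", "C"), protein2 = c("A", "D"),
                          score = c(0.7, 0.71))
  query <- data.frame(proteinA = c("A", "C"), proteinB = c("B", "D"))
  res <- fold_enrichment(query, reference, universe = c("A", "B", "C", "D"),
                         seed = 1)
  expect_equal(res$observed, 1)  # 0.70 fails the strict > 0.7 cut; 0.71 passes
})

test_that("Fisher exact matches full enumeration and fisher.test on small tables", {
  # direct brute force over all tables with the observed margins
  brute <- function(a, b, c, d) {
    m1 <- a + b; m2 <- c + d; k1 <- a + c
    xs <- max(0, k1 - m2):min(m1, k1)
    prob <- vapply(xs, function(x) {
      choose(m1, x) * choose(m2, k1 - x) / choose(m1 + m2, k1)
    }, numeric(1))
    p_obs <- prob[xs == a]
    list(greater = sum(prob[xs >= a]),
         two = sum(prob[prob <= p_obs * (1 + 1e-7)]))
  }
  set.seed(85)
  worst <- 0
  for (n in c(4:20, 30, 45, 60)) {
    for (rep in 1:8) {
      cnt <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
      a <- cnt[1]; b <- cnt[2]; c <- cnt[3]; d <- cnt[4]
      if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
      got <- fisher_exact_2x2(a, b, c, d)
      want <- brute(a, b, c, d)
      ft <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
      worst <- max(worst, abs(got$p_greater - want$greater),
                   abs(got$p_two_sided - want$two),
                   abs(got$p_two_sided - ft$p.value))
      # in the enrichment direction (a at or above the hypergeometric mode)
      # the upper tail is a subset of the two-sided rejection set
      mode_a <- floor((a + c + 1) * (a + b + 1) / (a + b + c + d + 2))
      if (a >= mode_a) expect_lte(got$p_greater, got$p_two_sided + 1e-12)
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("Fisher exact: worked enrichment table and degenerate cases", {
  # cytokine-pair enrichment table: 30/39 with rQTL vs 1512/2887 without
  got <- fisher_exact_2x2(30, 9, 1512, 1375)
  expect_gt(got$odds_ratio, 1)
  # the printed "p < 0.002" matches the one-sided (enrichment) test; the
  # two-sided p is 0.00204, so both are reported
  expect_lt(got$p_greater, 0.002)
  expect_lt(got$p_two_sided, 0.0021)
  expect_equal(got$p_two_sided,
               fisher.test(matrix(c(30, 9, 1512, 1375), 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)
  # no association
  flat <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_two_sided, 1)
  # infinity sentinel when b*c = 0
  expect_identical(fisher_exact_2x2(5, 0, 3, 4)$odds_ratio, Inf)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_2x2(1, 2, -1, 3), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "margins")
})
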