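#' Fold enrichment of protein pairs in an interaction reference
#'
#' Counts how many query pairs have a high-confidence link in the reference,
#' then estimates the chance expectation by drawing `n_resamples` random sets
#' of the same number of distinct unordered pairs from the same protein
#' universe and counting their links. Fold enrichment is observed / mean.
#'
#' @param pairs data.frame (`proteinA`, `proteinB`) or 2-column matrix of
#'   unordered query pairs.
#' @param reference data.frame `protein1`, `protein2`, `score` with scores in
#'   [0, 1] (see [read_interaction_reference()] for the 0-1000 dialect).
#' @param universe Character vector of proteins to resample from; defaults to
#'   the proteins appearing in `pairs`.
#' @param score_min Confidence threshold, strict (default 0.7).
#' @param n_resamples Number of resampling draws (default 100).
#' @param seed Integer seed for the resampling.
#' @return List: `observed`, `resampled_mean`, `resampled_sd` (sample sd),
#'   `fold` (NA when the mean is 0), `n_pairs`, `n_resamples`, `seed`.
#' @export
fold_enrichment <- function(pairs, reference, universe = NULL,
                            score_min = 0.7, n_resamples = 100L, seed = 1L) {
  pairs <- as.data.frame(pairs)
  if (!nrow(pairs)) stop("'pairs' must be non-empty")
  names(pairs)[1:2] <- c("proteinA", "proteinB")
  reference <- as.data.frame(reference)
  if (any(reference$score < 0 | reference$score > 1)) {
    stop("reference scores must lie in [0, 1]")
  }
  if (is.null(universe)) universe <- unique(c(pairs$proteinA, pairs$proteinB))
  universe <- sort(unique(as.character(universe)))
  n_univ_pairs <- choose(length(universe), 2)
  k <- nrow(pairs)
  if (n_univ_pairs < k) {
    stop("universe of ", length(universe), " proteins holds only ",
         n_univ_pairs, " distinct pairs; cannot draw ", k)
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ref_keys <- key(as.character(reference$protein1),
                  as.character(reference$protein2))
  ref_keys <- unique(ref_keys[reference$score > score_min])
  observed <- sum(key(pairs$proteinA, pairs$proteinB) %in% ref_keys)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  nu <- length(universe)
  # pairs (i < j) indexed lexicographically; f(m) = pairs with first index <= m
  f <- function(m) m * nu - m * (m + 1) / 2
  counts <- vapply(seq_len(n_resamples), function(r) {
    # draw k distinct unordered pairs by index into the C(nu, 2) pair space
    idx <- sample.int(n_univ_pairs, k)
    i <- ceiling((2 * nu - 1 - sqrt((2 * nu - 1)^2 - 8 * idx)) / 2)
    i <- pmax(1L, pmin(nu - 1L, i))
    # guard the float root against off-by-one
    i <- i - (f(i - 1) >= idx) + (f(i) < idx)
    j <- idx - f(i - 1) + i
    sum(key(universe[i], universe[j]) %in% ref_keys)
  }, numeric(1))
  m <- mean(counts)
  list(observed = observed, resampled_mean = m,
       resampled_sd = stats::sd(counts),
       fold = if (m > 0) observed / m else NA_real_,
       n_pairs = k, n_resamples = n_resamples, seed = seed)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test of association in the table
#' \preformatted{  a  b
#'   c  d}
#' conditioning on both margins. The one-sided p is the upper tail
#' (enrichment of cell `a`); the two-sided p sums the probabilities of all
#' tables (with the same margins) no more probable than the observed one.
#'
#' @param a,b,c,d Non-negative integer counts; both margins must be positive.
#' @return List: `odds_ratio` (= ad/bc, `Inf` when bc = 0),
#'   `p_greater` (one-sided upper tail), `p_two_sided`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all-zero table")
  m1 <- a + b; m2 <- c + d; k1 <- a + c
  if (m1 == 0 || m2 == 0 || k1 == 0 || (b + d) == 0) {
    stop("both margins of the table must be positive")
  }
  # support of cell a given margins
  lo <- max(0, k1 - m2); hi <- min(m1, k1)
  xs <- lo:hi
  dp <- stats::dhyper(xs, m1, m2, k1)
  p_obs <- stats::dhyper(a, m1, m2, k1)
  p_greater <- sum(dp[xs >= a])
  p_two <- sum(dp[dp <= p_obs * (1 + 1e-7)])
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p_greater = min(1, p_greater),
       p_two_sided = min(1, p_two))
}
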