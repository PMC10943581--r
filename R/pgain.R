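#' The p-gain of a ratio association, on the log10 scale
#'
#' The p-gain is the smaller of the two single-protein association p-values
#' divided by the ratio association p-value: the factor by which testing the
#' ratio improves on the better of the two component tests. All arithmetic is
#' done on the -log10 scale — log10(p-gain) = (-log10 p_ratio) -
#' max(-log10 p_1, -log10 p_2) — so no raw p-value is ever materialized and
#' no overflow can occur.
#'
#' @param neglogp1,neglogp2 -log10 p of the two single-protein associations.
#' @param neglogp3 -log10 p of the ratio association.
#' @return log10(p-gain); vectorized over the inputs.
#' @examples
#' log10_pgain(2878.1, 0.6, 3235.0) # 356.9
#' log10_pgain(5.7, 0.3, 16.9)      # 11.2
#' @export
log10_pgain <- function(neglogp1, neglogp2, neglogp3) {
  if (any(!is.finite(c(neglogp1, neglogp2, neglogp3)))) {
    stop("p-gain inputs must be finite -log10 p values")
  }
  if (any(c(neglogp1, neglogp2, neglogp3) < 0)) {
    stop("-log10 p inputs must be >= 0")
  }
  neglogp3 - pmax(neglogp1, neglogp2)
}

#' Critical p-gain for a family of tests
#'
#' A p-gain of 1/(2 alpha) corresponds to a nominal level-alpha test of a
#' single ratio (10 at alpha = 0.05); Bonferroni control over `n_tests`
#' ratios multiplies the critical value by the number of tests.
#'
#' @param n_tests Number of ratio tests in the family (>= 1).
#' @param alpha Nominal level (default 0.05).
#' @return The critical value on the log10 scale:
#'   log10(n_tests / (2 * alpha)).
#' @examples
#' pgain_threshold(1)       # log10(10) = 1
#' pgain_threshold(179923)  # log10(1,799,230) ~ 6.255
#' @export
pgain_threshold <- function(n_tests, alpha = 0.05) {
  if (any(n_tests < 1)) stop("'n_tests' must be >= 1")
  stopifnot(alpha > 0, alpha < 1)
  log10(n_tests) + log10(1 / (2 * alpha))
}

#' Null calibration of the p-gain by simulation
#'
#' Simulates ratio tests between two random proteins with no genetic effect:
#' per replicate a biallelic SNP is drawn at the given MAF and a bivariate
#' normal protein pair with correlation `rho`; the two proteins and the
#' inverse-normal-transformed difference are each regressed on the dosage
#' and the p-gain computed. Under this null a p-gain above 10 is expected in
#' about 5% of replicates.
#'
#' @param n_samples Samples per replicate.
#' @param n_reps Number of replicates (>= 1000 for a meaningful estimate).
#' @param maf Minor allele frequency of the simulated SNP (default 0.3).
#' @param rho Correlation between the two protein traits, |rho| < 1.
#' @param seed Integer seed.
#' @param log10_pgain_min Exceedance threshold on the log10 scale (default 1,
#'   i.e. p-gain 10).
#' @return List: `exceedance` (fraction of replicates with log10 p-gain >
#'   threshold), `ci` (95% binomial normal-approximation interval), `n_reps`,
#'   `n_exceed`.
#' @export
simulate_null_pgain <- function(n_samples, n_reps, maf = 0.3, rho = 0,
                                seed = 1L, log10_pgain_min = 1) {
  if (n_reps < 1000) stop("'n_reps' must be >= 1000 for a meaningful estimate")
  if (abs(rho) >= 1) stop("'rho' must satisfy |rho| < 1")
  stopifnot(maf > 0, maf <= 0.5, n_samples >= 10)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  exceed <- logical(n_reps)
  thr <- log10_pgain_min
  for (r in seq_len(n_reps)) {
    g <- stats::rbinom(n_samples, 2L, maf)
    if (stats::var(g) == 0) { exceed[r] <- FALSE; next }  # ~impossible at n>=10
    p1 <- stats::rnorm(n_samples)
    p2 <- rho * p1 + sqrt(1 - rho^2) * stats::rnorm(n_samples)
    ratio <- inverse_normal_transform(p1 - p2)
    nlp <- vapply(list(p1, p2, ratio), function(y) {
      fast_simple_assoc(y, g)
    }, numeric(1))
    exceed[r] <- log10_pgain(nlp[1L], nlp[2L], nlp[3L]) > thr
  }
  k <- sum(exceed)
  phat <- k / n_reps
  se <- sqrt(phat * (1 - phat) / n_reps)
  list(exceedance = phat, ci = c(max(0, phat - 1.96 * se), phat + 1.96 * se),
       n_reps = n_reps, n_exceed = k)
}

# -log10 p of simple (no-covariate) OLS of y on g via the correlation
# identity t = r * sqrt((n - 2) / (1 - r^2)); exact for simple regression.
fast_simple_assoc <- function(y, g) {
  n <- length(y)
  r <- stats::cor(y, g)
  if (abs(r) >= 1) return(Inf)
  neglog10_p_from_t(r * sqrt((n - 2) / (1 - r^2)), n - 2)
}
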