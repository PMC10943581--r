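#' Specify a synthetic proteomics-GWAS cohort
#'
#' The generative model for each protein i on the log scale is
#'
#'   log(P_i) = alpha_i + sum_v beta_iv * SNP_v + sum_f gamma_if * W_f
#'              + covariate terms + eps_i,
#'
#' with SNP_v ~ Binomial(2, maf_v) genotypes under Hardy-Weinberg, W_f iid
#' standard-normal latent factors shared across proteins (unidentified
#' non-genetic variance), and eps_i ~ Normal(0, epsilon_sd_i^2). A ratio
#' phenotype log(P1/P2) therefore carries slope beta_1v - beta_2v on
#' variant v, and factor loading gamma_1f - gamma_2f.
#'
#' @param n_samples Total number of samples (> 0).
#' @param n_discovery Number assigned to the discovery cohort (the first
#'   `n_discovery` samples); the remainder form the replication cohort.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `maf`
#'   (maf in (0, 0.5]).
#' @param proteins data.frame with columns `id`, `chrom`, `start`, `end`
#'   (coding-gene coordinates, used for cis/trans annotation downstream).
#' @param alpha Per-protein intercept (length = n proteins).
#' @param beta Proteins x variants matrix of allelic effects (log-abundance
#'   per effect allele).
#' @param gamma Proteins x factors matrix of latent-factor loadings.
#' @param n_factors Number of shared latent factors (columns of `gamma`).
#' @param epsilon_sd Per-protein residual standard deviation (> 0); scalar
#'   recycled.
#' @param missing_rate Fraction of protein measurements set missing
#'   completely at random, in [0, 1).
#' @param covariate_effects Optional proteins x 5 matrix of loadings on
#'   (age, sex, PC1, PC2, PC3); defaults to all zero.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec including this seed.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_cohort()], [scenario_preset()]
#' @export
synthetic_spec <- function(n_samples, n_discovery, variants, proteins,
                           alpha, beta, gamma = NULL, n_factors = 0L,
                           epsilon_sd = 1, missing_rate = 0,
                           covariate_effects = NULL, seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1) {
    stop("'n_samples' must be a positive count")
  }
  n_samples <- as.integer(n_samples)
  n_discovery <- as.integer(n_discovery)
  if (n_discovery < 1L || n_discovery > n_samples) {
    stop("'n_discovery' must be in [1, n_samples]")
  }
  variants <- as.data.frame(variants)
  need_v <- c("id", "chrom", "pos", "maf")
  if (!all(need_v %in% names(variants))) {
    stop("'variants' needs columns: ", paste(need_v, collapse = ", "))
  }
  if (any(variants$maf <= 0 | variants$maf > 0.5)) {
    stop("'variants$maf' must lie in (0, 0.5]")
  }
  proteins <- as.data.frame(proteins)
  need_p <- c("id", "chrom", "start", "end")
  if (!all(need_p %in% names(proteins))) {
    stop("'proteins' needs columns: ", paste(need_p, collapse = ", "))
  }
  np <- nrow(proteins); nv <- nrow(variants)
  n_factors <- as.integer(n_factors)
  alpha <- rep_len(as.numeric(alpha), np)
  epsilon_sd <- rep_len(as.numeric(epsilon_sd), np)
  if (any(epsilon_sd <= 0)) stop("'epsilon_sd' must be > 0")
  beta <- as.matrix(beta)
  if (!identical(dim(beta), c(np, nv))) {
    stop("'beta' must have shape (n_proteins = ", np, ") x (n_variants = ",
         nv, "), got ", nrow(beta), " x ", ncol(beta))
  }
  if (n_factors > 0L) {
    if (is.null(gamma)) stop("'gamma' required when n_factors > 0")
    gamma <- as.matrix(gamma)
    if (!identical(dim(gamma), c(np, n_factors))) {
      stop("'gamma' must have shape (n_proteins = ", np, ") x (n_factors = ",
           n_factors, "), got ", nrow(gamma), " x ", ncol(gamma))
    }
  } else {
    gamma <- matrix(0, np, 0L)
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("'missing_rate' must be in [0, 1)")
  if (is.null(covariate_effects)) {
    covariate_effects <- matrix(0, np, 5L)
  } else {
    covariate_effects <- as.matrix(covariate_effects)
    if (!identical(dim(covariate_effects), c(np, 5L))) {
      stop("'covariate_effects' must have shape (n_proteins = ", np,
           ") x 5 (age, sex, PC1-3)")
    }
  }
  colnames(covariate_effects) <- c("age", "sex", "PC1", "PC2", "PC3")
  structure(list(
    n_samples = n_samples, n_discovery = n_discovery,
    variants = variants, proteins = proteins,
    alpha = alpha, beta = beta, gamma = gamma, n_factors = n_factors,
    epsilon_sd = epsilon_sd, missing_rate = missing_rate,
    covariate_effects = covariate_effects, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a synthetic cohort from a model specification
#'
#' Draws genotypes, latent factors, covariates, and residuals, and assembles
#' the protein matrix according to the linear generative model of
#' [synthetic_spec()]. Missingness is applied completely at random. The
#' result is a deterministic function of the spec (including its seed).
#'
#' @param spec A `synthetic_spec`.
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `genotypes` (samples x variants, values 0/1/2), `proteins` (samples x
#'   proteins, log scale, `NA` where missing), `covariates` (data.frame with
#'   age, sex, PC1-3), `cohort` (factor "discovery"/"replication"),
#'   `variants`, `gene_table`, and `truth` (the spec).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("'spec' must be a synthetic_spec")
  n <- spec$n_samples
  nv <- nrow(spec$variants)
  np <- nrow(spec$proteins)
  sample_ids <- sprintf("S%05d", seq_len(n))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  geno <- matrix(stats::rbinom(n * nv, 2L, rep(spec$variants$maf, each = n)),
                 nrow = n, ncol = nv,
                 dimnames = list(sample_ids, spec$variants$id))
  W <- matrix(stats::rnorm(n * spec$n_factors), n, spec$n_factors)
  covariates <- data.frame(
    age = stats::runif(n, 40, 70),
    sex = stats::rbinom(n, 1L, 0.5),
    PC1 = stats::rnorm(n), PC2 = stats::rnorm(n), PC3 = stats::rnorm(n),
    row.names = sample_ids
  )
  eps <- matrix(stats::rnorm(n * np, sd = rep(spec$epsilon_sd, each = n)), n, np)
  prot <- matrix(rep(spec$alpha, each = n), n, np) +
    geno %*% t(spec$beta) +
    (if (spec$n_factors > 0L) W %*% t(spec$gamma) else 0) +
    as.matrix(covariates) %*% t(spec$covariate_effects) +
    eps
  dimnames(prot) <- list(sample_ids, spec$proteins$id)
  if (spec$missing_rate > 0) {
    drop <- stats::runif(n * np) < spec$missing_rate
    prot[drop] <- NA_real_
  }
  cohort <- factor(ifelse(seq_len(n) <= spec$n_discovery,
                          "discovery", "replication"),
                   levels = c("discovery", "replication"))
  structure(list(
    genotypes = geno, proteins = prot, covariates = covariates,
    cohort = cohort, variants = spec$variants,
    gene_table = spec$proteins, truth = spec
  ), class = "synthetic_cohort")
}

#' Canonical two-protein, one-variant simulation scenarios
#'
#' Presets for the mechanisms by which a ratio between two protein levels
#' can associate more strongly with a variant than either protein alone:
#'
#' * `opposite_beta` — the variant raises one protein and lowers the other
#'   (beta1 = -beta2, no shared factor); the ratio doubles the genetic signal.
#' * `single_beta_shared_W` — only protein 1 carries a genetic effect, but
#'   both load equally on a shared non-genetic factor W; the ratio cancels W
#'   and unmasks the genetic signal.
#' * `shared_beta_shared_W` — identical genetic effects and identical W
#'   loadings; the ratio cancels both and is null-distributed.
#' * `null` — no genetic effects, no shared factor.
#'
#' @param name One of `"opposite_beta"`, `"single_beta_shared_W"`,
#'   `"shared_beta_shared_W"`, `"null"`.
#' @param n_samples,n_discovery Cohort sizes (defaults 6000 / 5000).
#' @param maf Minor allele frequency of the single variant (default 0.3).
#' @param beta Genetic effect magnitude in log-abundance units per allele
#'   (default 0.2; `single_beta_shared_W` uses 1.5 * beta on protein 1).
#' @param gamma Shared-factor loading used by the shared-W scenarios
#'   (default 2 for `single_beta_shared_W`, 1 for `shared_beta_shared_W`).
#' @param seed Integer seed.
#' @return A `synthetic_spec` with two proteins `P1`, `P2` and one variant
#'   `rs1`.
#' @export
scenario_preset <- function(name, n_samples = 6000L, n_discovery = 5000L,
                            maf = 0.3, beta = 0.2, gamma = NULL, seed = 1L) {
  valid <- c("opposite_beta", "single_beta_shared_W",
             "shared_beta_shared_W", "null")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  }
  variants <- data.frame(id = "rs1", chrom = "1", pos = 50e6L, maf = maf)
  proteins <- data.frame(id = c("P1", "P2"), chrom = c("1", "2"),
                         start = c(49.9e6, 10e6), end = c(50.1e6, 10.2e6))
  par <- switch(name,
    opposite_beta = list(beta = c(beta, -beta), gam = NULL),
    single_beta_shared_W = list(beta = c(1.5 * beta, 0),
                                gam = rep(if (is.null(gamma)) 2 else gamma, 2)),
    shared_beta_shared_W = list(beta = c(beta, beta),
                                gam = rep(if (is.null(gamma)) 1 else gamma, 2)),
    null = list(beta = c(0, 0), gam = NULL)
  )
  synthetic_spec(
    n_samples = n_samples, n_discovery = n_discovery,
    variants = variants, proteins = proteins,
    alpha = c(5, 5),
    beta = matrix(par$beta, 2, 1),
    gamma = if (is.null(par$gam)) NULL else matrix(par$gam, 2, 1),
    n_factors = if (is.null(par$gam)) 0L else 1L,
    epsilon_sd = 1, missing_rate = 0, seed = seed
  )
}
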