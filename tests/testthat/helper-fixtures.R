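# Shared fixture builders; all randomness is seeded locally.

toy_protein_matrix <- function() {
  # 10 samples x 5 proteins; sample s10 is 4/5 missing; after its removal
  # protein p3 is missing in 3 of the 9 remaining samples (fraction 1/3);
  # samples s1-s3 are exactly 1/5 = 0.2 missing, at (not over) the cut
  m <- matrix(rnorm(50), 10, 5,
              dimnames = list(paste0("s", 1:10), paste0("p", 1:5)))
  m <- round(m, 3)
  m["s10", c("p1", "p2", "p3", "p4")] <- NA
  m[c("s1", "s2", "s3"), "p3"] <- NA
  m
}

random_protein_matrix <- function(n, p, missing_rate = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%04d", 1:n), sprintf("p%03d", 1:p)))
  if (missing_rate > 0) m[runif(n * p) < missing_rate] <- NA
  m
}

# Small complete cohort list for direct pipeline calls.
toy_cohort <- function(n = 400, seed = 7) {
  spec <- scenario_preset("opposite_beta", n_samples = n,
                          n_discovery = n, seed = seed)
  ch <- generate_cohort(spec)
  list(proteins = ch$proteins, genotypes = ch$genotypes,
       covariates = ch$covariates)
}

# Sparse-precision multivariate normal sample with known conditional
# independence graph; returns the data and the true edge set.
simulate_sparse_ggm <- function(n = 5000, p = 20, n_edges = 15,
                                weight = -0.15, seed = 99) {
  set.seed(seed)
  all_pairs <- t(combn(p, 2))
  edge_idx <- sample(nrow(all_pairs), n_edges)
  omega <- diag(p)
  for (e in edge_idx) {
    i <- all_pairs[e, 1]; j <- all_pairs[e, 2]
    omega[i, j] <- omega[j, i] <- weight
  }
  # diagonal dominance keeps omega positive definite
  sigma <- solve(omega)
  L <- chol(sigma)
  x <- matrix(rnorm(n * p), n, p) %*% L
  dimnames(x) <- list(sprintf("s%05d", 1:n), sprintf("p%02d", 1:p))
  true_edges <- apply(all_pairs[edge_idx, , drop = FALSE], 1, function(ij) {
    paste(sprintf("p%02d", sort(ij)), collapse = "|")
  })
  list(x = x, true_edges = sort(true_edges))
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# Multi-protein cohort with two planted signals: pair (Q01, Q02) has opposite
# betas on rs01; pair (Q03, Q04) has a single beta on rs02 plus a strong
# shared latent factor. All other proteins and variants are null.
planted_cohort_spec <- function(n_samples = 5000, n_discovery = 4000,
                                n_null_prot = 8, n_variants = 5, seed = 1) {
  np <- 4 + n_null_prot
  ids <- sprintf("Q%02d", seq_len(np))
  variants <- data.frame(id = sprintf("rs%02d", seq_len(n_variants)),
                         chrom = as.character(rep(1:5, length.out = n_variants)),
                         pos = 2e7 + 5e6 * seq_len(n_variants), maf = 0.3)
  proteins <- data.frame(id = ids,
                         chrom = as.character(rep(1:10, length.out = np)),
                         start = 1e6 + 3e6 * seq_len(np),
                         end = 1e6 + 3e6 * seq_len(np) + 2e5)
  beta <- matrix(0, np, n_variants)
  beta[1, 1] <- 0.2; beta[2, 1] <- -0.2
  beta[3, 2] <- 0.3
  gamma <- matrix(0, np, 1)
  gamma[3, 1] <- 2; gamma[4, 1] <- 2
  synthetic_spec(n_samples, n_discovery, variants, proteins,
                 alpha = rep(3, np), beta = beta, gamma = gamma,
                 n_factors = 1L, epsilon_sd = 1, seed = seed)
}
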