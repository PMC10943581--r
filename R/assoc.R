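#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, sums the probabilities of all
#' heterozygote counts whose probability does not exceed that of the observed
#' count (the standard exact HWE test, as used by plink's `--hwe`). All
#' probabilities are computed in log space so the test is stable for large
#' cohorts.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @return Exact two-sided p-value in (0, 1]; monomorphic input gives 1.
#' @examples
#' hwe_exact_pvalue(25, 50, 25)  # perfect HWE, p near 1
#' hwe_exact_pvalue(50, 0, 50)   # extreme heterozygote deficit, p << 1e-15
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("total genotype count must be > 0")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  n_minor <- min(nA, na)
  # heterozygote counts share the parity of the minor allele count
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(het = h | allele counts): multinomial over genotypes / binomial
  # over alleles, with 2^h orderings of the heterozygote alleles
  log_p <- hets * log(2) +
    lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((na - hets) / 2 + 1) -
    (lgamma(2 * n + 1) - lgamma(nA + 1) - lgamma(na + 1))
  # normalize in log space to absorb rounding in the closed form
  m <- max(log_p)
  log_p <- log_p - (m + log(sum(exp(log_p - m))))
  obs <- log_p[hets == n_Aa]
  if (length(obs) != 1L) return(0)  # impossible configuration given alleles
  keep <- log_p <= obs + 1e-10      # plink-style tolerance for ties
  min(1, sum(exp(log_p[keep])))
}

#' Variant and sample quality control for a dosage matrix
#'
#' Applies the standard pre-GWAS filters in plink's documented order: samples
#' with missing fraction above `mind_max_missing` are removed first, then
#' variants are removed when (on the retained samples) the missing fraction
#' exceeds `geno_max_missing`, the minor allele frequency falls below
#' `maf_min`, the minor allele count falls below `mac_min`, or the exact HWE
#' p-value falls below `hwe_p_min`.
#'
#' @param geno Samples x variants matrix of dosages in \{0, 1, 2, NA\} with
#'   dimnames.
#' @param geno_max_missing Per-variant missing fraction cut (default 0.1).
#' @param mind_max_missing Per-sample missing fraction cut (default 0.1).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param mac_min Minimum minor allele count (default 100).
#' @param hwe_p_min Minimum exact HWE p-value (default 1e-15).
#' @return Filtered matrix with attribute `qc_report`: a list of per-filter
#'   removal counts (a variant failing several filters is counted once per
#'   filter; removal is the union).
#' @export
variant_qc <- function(geno, geno_max_missing = 0.1, mind_max_missing = 0.1,
                       maf_min = 0.01, mac_min = 100, hwe_p_min = 1e-15) {
  geno <- as_genotype_matrix(geno)
  stopifnot(geno_max_missing >= 0, geno_max_missing <= 1,
            mind_max_missing >= 0, mind_max_missing <= 1,
            maf_min >= 0, maf_min <= 0.5, mac_min >= 0, hwe_p_min >= 0)
  mind <- rowMeans(is.na(geno))
  keep_s <- mind <= mind_max_missing
  g <- geno[keep_s, , drop = FALSE]
  n_obs <- colSums(!is.na(g))
  miss_frac <- 1 - n_obs / nrow(g)
  ac <- colSums(g, na.rm = TRUE)
  af <- ifelse(n_obs > 0, ac / (2 * n_obs), NA_real_)
  mac <- pmin(ac, 2 * n_obs - ac)
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]; x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_pvalue(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  fail_geno <- miss_frac > geno_max_missing
  fail_maf <- is.na(maf) | maf < maf_min
  fail_mac <- mac < mac_min
  fail_hwe <- hwe_p < hwe_p_min
  keep_v <- !(fail_geno | fail_maf | fail_mac | fail_hwe)
  report <- list(
    samples_removed_mind = sum(!keep_s),
    variants_removed_geno = sum(fail_geno),
    variants_removed_maf = sum(fail_maf),
    variants_removed_mac = sum(fail_mac),
    variants_removed_hwe = sum(fail_hwe),
    variants_removed_total = sum(!keep_v),
    samples_retained = sum(keep_s),
    variants_retained = sum(keep_v)
  )
  if (!any(keep_v) || !any(keep_s)) {
    stop("QC removed everything; per-filter tally: ",
         paste(names(report), unlist(report), sep = "=", collapse = ", "))
  }
  out <- g[, keep_v, drop = FALSE]
  attr(out, "qc_report") <- report
  out
}

#' Covariate-adjusted linear-model association test
#'
#' Ordinary least squares of a phenotype on [intercept, dosage, covariates],
#' on complete cases of all three. The dosage coefficient's t statistic is
#' converted to a two-sided -log10 p-value in log space, so genome-scale
#' signals with p far below double precision are reported exactly.
#'
#' @param y Named phenotype vector (names = sample ids), NA allowed.
#' @param g Named dosage vector; samples aligned with `y` by name.
#' @param covariates Optional data.frame / matrix of numeric covariates with
#'   sample-id rownames; must be complete for analysed samples.
#' @param trait,variant Optional labels carried into the result.
#' @return One-row data.frame: `trait`, `variant`, `n`, `beta`, `se`, `t`,
#'   `neglog10p`. A perfect fit (zero residual variance) yields
#'   `neglog10p = Inf`.
#' @export
linear_assoc <- function(y, g, covariates = NULL, trait = NA_character_,
                         variant = NA_character_) {
  if (is.null(names(y)) || is.null(names(g))) {
    stop("'y' and 'g' must carry sample ids as names")
  }
  ids <- intersect(names(y), names(g))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(rownames(covariates))) stop("covariates need sample-id rownames")
    ids <- intersect(ids, rownames(covariates))
  }
  yv <- y[ids]; gv <- g[ids]
  cv <- if (is.null(covariates)) NULL else covariates[ids, , drop = FALSE]
  cc <- !is.na(yv) & !is.na(gv)
  if (!is.null(cv)) cc <- cc & stats::complete.cases(cv)
  k_cov <- if (is.null(cv)) 0L else ncol(cv)
  if (sum(cc) < k_cov + 3L) {
    stop("too few complete cases (", sum(cc), ") for ", k_cov, " covariates")
  }
  yv <- yv[cc]; gv <- gv[cc]
  if (stats::var(gv) == 0) stop("variant is monomorphic in analysis set")
  X <- cbind(`(Intercept)` = 1, dosage = gv,
             if (!is.null(cv)) cv[cc, , drop = FALSE])
  fit <- stats::lm.fit(X, yv)
  df <- length(yv) - fit$rank
  rss <- sum(fit$residuals^2)
  piv <- fit$qr$pivot[seq_len(fit$rank)]
  pos <- match(2L, piv)  # dosage is column 2 of X; follow QR pivoting
  if (is.na(pos)) stop("dosage column dropped as collinear in analysis set")
  XtXinv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                               drop = FALSE])
  XtXinv_22 <- XtXinv[pos, pos]
  beta <- unname(fit$coefficients["dosage"])
  if (rss <= 1e-12 * sum(yv^2)) {
    se <- 0; tstat <- Inf; nlp <- Inf
  } else {
    se <- sqrt(rss / df * XtXinv_22)
    tstat <- beta / se
    nlp <- neglog10_p_from_t(tstat, df)
  }
  data.frame(trait = trait, variant = variant, n = length(yv),
             beta = beta, se = se, t = tstat, neglog10p = nlp,
             stringsAsFactors = FALSE)
}

# Coerce/validate a dosage matrix: values in {0,1,2,NA}, dimnames present.
as_genotype_matrix <- function(geno) {
  if (is.data.frame(geno)) geno <- as.matrix(geno)
  if (!is.matrix(geno) || !is.numeric(geno)) {
    stop("genotype matrix must be numeric samples x variants")
  }
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    stop("genotype matrix needs sample ids (rownames) and variant ids (colnames)")
  }
  bad <- !is.na(geno) & !(geno %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("dosage outside {0,1,2,NA} at sample '", rownames(geno)[idx[1L]],
         "', variant '", colnames(geno)[idx[2L]], "'")
  }
  geno
}
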