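#' Split a cohort into discovery and replication subsets
#'
#' @param cohort A `synthetic_cohort` (or any list with `proteins`,
#'   `genotypes`, `covariates`, and a `cohort` factor).
#' @return List with elements `discovery` and `replication`, each a list of
#'   aligned `proteins`, `genotypes`, `covariates`.
#' @export
split_cohort <- function(cohort) {
  stopifnot(!is.null(cohort$cohort))
  lapply(stats::setNames(nm = c("discovery", "replication")), function(w) {
    keep <- cohort$cohort == w
    list(proteins = cohort$proteins[keep, , drop = FALSE],
         genotypes = cohort$genotypes[keep, , drop = FALSE],
         covariates = cohort$covariates[keep, , drop = FALSE])
  })
}

#' Candidate ratio-variant tests from network edges and known pQTLs
#'
#' For every partially correlated protein pair (A, B) and every known pQTL
#' variant of A or of B, emits one candidate test (A/B, variant),
#' de-duplicated on the unordered pair and variant. This is the overlap of
#' the significant network edges with the established pQTL table.
#'
#' @param edges data.frame with `proteinA`, `proteinB` (and optionally a
#'   `significant` flag, in which case only significant edges are used).
#' @param pqtls data.frame with `variant`, `protein` columns.
#' @return data.frame `proteinA`, `proteinB`, `variant` with A < B.
#' @export
select_candidate_tests <- function(edges, pqtls) {
  edges <- as.data.frame(edges)
  pqtls <- as.data.frame(pqtls)
  if (!nrow(edges) || !nrow(pqtls)) {
    return(data.frame(proteinA = character(), proteinB = character(),
                      variant = character(), stringsAsFactors = FALSE))
  }
  if ("significant" %in% names(edges)) {
    edges <- edges[edges$significant, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(seq_len(nrow(edges)), function(i) {
    a <- edges$proteinA[i]; b <- edges$proteinB[i]
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    v <- unique(pqtls$variant[pqtls$protein %in% c(a, b)])
    if (!length(v)) return(NULL)
    data.frame(proteinA = a, proteinB = b, variant = v,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(proteinA = character(), proteinB = character(),
                      variant = character(), stringsAsFactors = FALSE))
  }
  out <- unique(out)
  rownames(out) <- NULL
  out
}

# Inverse-normal transform every column of a protein matrix once, cached.
int_protein_matrix <- function(proteins, ids) {
  vapply(ids, function(p) inverse_normal_transform(proteins[, p]),
         numeric(nrow(proteins)))
}

# Run the protein1 / protein2 / ratio associations for one candidate in one
# cohort; returns the three -log10 p values and the ratio effect.
candidate_assoc <- function(int_prot, proteins, geno, covariates,
                            a, b, variant) {
  if (!(variant %in% colnames(geno))) stop("unknown variant: ", variant)
  g <- geno[, variant]
  ratio <- make_ratio_phenotype(proteins, c(a, b))
  r1 <- linear_assoc(int_prot[, a], g, covariates)
  r2 <- linear_assoc(int_prot[, b], g, covariates)
  r3 <- linear_assoc(ratio, g, covariates)
  list(nlp1 = r1$neglog10p, nlp2 = r2$neglog10p, nlp3 = r3$neglog10p,
       beta = r3$beta, se = r3$se, n = r3$n)
}

#' Targeted discovery/replication scan of candidate ratio tests
#'
#' For each candidate (protein pair, variant), computes the two
#' single-protein associations and the ratio association in the discovery
#' cohort (each phenotype inverse-normal transformed within the cohort),
#' derives the p-gain, and flags significance against the Bonferroni-scaled
#' critical p-gain `1/(2 alpha) * n_candidates`. Significant candidates are
#' re-tested in the replication cohort and flagged replicated when the
#' replication p-gain exceeds `1/(2 alpha) * n_significant`.
#'
#' @param candidates data.frame `proteinA`, `proteinB`, `variant`.
#' @param discovery,replication Cohort lists (`proteins`, `genotypes`,
#'   `covariates`), e.g. from [split_cohort()]. `replication = NULL` skips
#'   the replication stage.
#' @param alpha Nominal level for both critical p-gains (default 0.05).
#' @return List: `records` (one row per candidate with `-log10 p` columns
#'   `neglogP1`, `neglogP2`, `neglogP3`, `logPgain`, significance and
#'   replication fields) and `counts` (candidates, significant, replicated).
#' @export
targeted_scan <- function(candidates, discovery, replication = NULL,
                          alpha = 0.05) {
  candidates <- as.data.frame(candidates)
  counts <- list(n_candidates = nrow(candidates), n_significant = 0L,
                 n_replicated = 0L)
  if (!nrow(candidates)) {
    rec <- data.frame(proteinA = character(), proteinB = character(),
                      variant = character(), ratio = character(),
                      neglogP1 = numeric(), neglogP2 = numeric(),
                      neglogP3 = numeric(), logPgain = numeric(),
                      significant = logical(), repl_neglogP3 = numeric(),
                      repl_logPgain = numeric(), replicated = logical(),
                      stringsAsFactors = FALSE)
    return(list(records = rec, counts = counts))
  }
  prot_ids <- unique(c(candidates$proteinA, candidates$proteinB))
  missing_p <- setdiff(prot_ids, colnames(discovery$proteins))
  if (length(missing_p)) stop("unknown protein(s): ",
                              paste(missing_p, collapse = ", "))
  missing_v <- setdiff(unique(candidates$variant),
                       colnames(discovery$genotypes))
  if (length(missing_v)) stop("unknown variant(s): ",
                              paste(missing_v, collapse = ", "))
  int_disc <- int_protein_matrix(discovery$proteins, prot_ids)
  rownames(int_disc) <- rownames(discovery$proteins)
  res <- lapply(seq_len(nrow(candidates)), function(i) {
    candidate_assoc(int_disc, discovery$proteins, discovery$genotypes,
                    discovery$covariates,
                    candidates$proteinA[i], candidates$proteinB[i],
                    candidates$variant[i])
  })
  rec <- data.frame(
    proteinA = candidates$proteinA, proteinB = candidates$proteinB,
    variant = candidates$variant,
    ratio = paste0(candidates$proteinA, "/", candidates$proteinB),
    neglogP1 = vapply(res, `[[`, numeric(1), "nlp1"),
    neglogP2 = vapply(res, `[[`, numeric(1), "nlp2"),
    neglogP3 = vapply(res, `[[`, numeric(1), "nlp3"),
    stringsAsFactors = FALSE
  )
  rec$logPgain <- rec$neglogP3 - pmax(rec$neglogP1, rec$neglogP2)
  crit <- pgain_threshold(nrow(rec), alpha)
  rec$significant <- rec$logPgain > crit
  counts$n_significant <- sum(rec$significant)
  rec$repl_neglogP3 <- NA_real_
  rec$repl_logPgain <- NA_real_
  rec$replicated <- NA
  if (!is.null(replication) && counts$n_significant > 0L) {
    int_repl <- int_protein_matrix(replication$proteins, prot_ids)
    rownames(int_repl) <- rownames(replication$proteins)
    crit_repl <- pgain_threshold(counts$n_significant, alpha)
    for (i in which(rec$significant)) {
      rr <- candidate_assoc(int_repl, replication$proteins,
                            replication$genotypes, replication$covariates,
                            rec$proteinA[i], rec$proteinB[i], rec$variant[i])
      rec$repl_neglogP3[i] <- rr$nlp3
      rec$repl_logPgain[i] <- rr$nlp3 - pmax(rr$nlp1, rr$nlp2)
      rec$replicated[i] <- rec$repl_logPgain[i] > crit_repl
    }
    counts$n_replicated <- sum(rec$replicated, na.rm = TRUE)
  }
  attr(rec, "pgain_threshold") <- crit
  list(records = rec, counts = counts)
}

#' Genome-wide association scan over ratio phenotypes
#'
#' Scans every ratio against every variant, computing the ratio association,
#' both single-protein associations, and the p-gain. Associations are
#' retained when the ratio p-value beats `genomewide_alpha / n_ratios` AND
#' the p-gain exceeds `pgain_base * n_ratios` (both Bonferroni-scaled over
#' the number of ratios tested).
#'
#' @param pairs data.frame `proteinA`, `proteinB` — the ratios to scan.
#' @param cohort Cohort list (`proteins`, `genotypes`, `covariates`).
#' @param variants data.frame `id`, `chrom`, `pos` for the scanned variants.
#' @param genomewide_alpha Genome-wide single-test level (default 5e-8).
#' @param pgain_base Single-ratio critical p-gain for a genome-wide scan
#'   (default 1e7).
#' @return List: `full` (all ratio-variant results), `retained` (passing both
#'   thresholds), `thresholds`.
#' @export
ratio_gwas <- function(pairs, cohort, variants, genomewide_alpha = 5e-8,
                       pgain_base = 1e7) {
  pairs <- as.data.frame(pairs)
  if (!nrow(pairs)) stop("'pairs' must contain at least one ratio")
  variants <- as.data.frame(variants)
  n_ratios <- nrow(pairs)
  p_cut_neglog <- -log10(genomewide_alpha / n_ratios)
  pgain_cut <- log10(pgain_base) + log10(n_ratios)
  prot_ids <- unique(c(pairs$proteinA, pairs$proteinB))
  int_prot <- int_protein_matrix(cohort$proteins, prot_ids)
  rownames(int_prot) <- rownames(cohort$proteins)
  vids <- intersect(variants$id, colnames(cohort$genotypes))
  if (!length(vids)) stop("no variants shared between 'variants' and the cohort")
  vinfo <- variants[match(vids, variants$id), ]
  # cache single-protein scans: protein x variant -> -log10 p
  single <- matrix(NA_real_, length(prot_ids), length(vids),
                   dimnames = list(prot_ids, vids))
  for (p in prot_ids) for (v in vids) {
    single[p, v] <- linear_assoc(int_prot[, p], cohort$genotypes[, v],
                                 cohort$covariates)$neglog10p
  }
  rows <- vector("list", n_ratios * length(vids))
  k <- 0L
  for (i in seq_len(n_ratios)) {
    a <- pairs$proteinA[i]; b <- pairs$proteinB[i]
    ratio <- make_ratio_phenotype(cohort$proteins, c(a, b))
    for (j in seq_along(vids)) {
      v <- vids[j]
      r3 <- linear_assoc(ratio, cohort$genotypes[, v], cohort$covariates)
      k <- k + 1L
      rows[[k]] <- data.frame(
        ratio = paste0(a, "/", b), proteinA = a, proteinB = b,
        variant = v, chrom = as.character(vinfo$chrom[j]), pos = vinfo$pos[j],
        n = r3$n, beta = r3$beta, se = r3$se, t = r3$t,
        neglogP1 = single[a, v], neglogP2 = single[b, v],
        neglogP3 = r3$neglog10p,
        stringsAsFactors = FALSE
      )
    }
  }
  full <- do.call(rbind, rows)
  full$logPgain <- full$neglogP3 - pmax(full$neglogP1, full$neglogP2)
  retained <- full[full$neglogP3 > p_cut_neglog & full$logPgain > pgain_cut, ]
  rownames(retained) <- NULL
  list(full = full, retained = retained,
       thresholds = list(neglogp_min = p_cut_neglog,
                         log10_pgain_min = pgain_cut,
                         n_ratios = n_ratios))
}

#' Distance-based pruning to independent lead associations
#'
#' Greedy pruning of the significant associations of one ratio: repeatedly
#' keep the strongest remaining association and discard all others on the
#' same chromosome within `min_distance` base pairs of it. Ties in strength
#' are broken by position, then variant id, so the result is independent of
#' input order.
#'
#' @param assoc data.frame with `variant`, `chrom`, `pos`, `neglog10p`
#'   columns (a `neglogP3` column is accepted as the strength if
#'   `neglog10p` is absent).
#' @param min_distance Exclusion radius in bp (default 1e6).
#' @return The lead rows of `assoc`, strongest first.
#' @export
prune_independent <- function(assoc, min_distance = 1e6) {
  assoc <- as.data.frame(assoc)
  if (!nrow(assoc)) return(assoc)
  strength <- if ("neglog10p" %in% names(assoc)) assoc$neglog10p else assoc$neglogP3
  if (is.null(strength)) stop("'assoc' needs a 'neglog10p' or 'neglogP3' column")
  ord <- order(-strength, assoc$pos, as.character(assoc$variant))
  assoc <- assoc[ord, , drop = FALSE]
  keep <- logical(nrow(assoc))
  alive <- rep(TRUE, nrow(assoc))
  for (i in seq_len(nrow(assoc))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    near <- alive & assoc$chrom == assoc$chrom[i] &
      abs(assoc$pos - assoc$pos[i]) <= min_distance
    alive[near] <- FALSE
  }
  out <- assoc[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Distance from a position to a gene body: 0 inside, else bp to nearest edge.
gene_distance <- function(pos, start, end) {
  ifelse(pos >= start & pos <= end, 0, pmin(abs(pos - start), abs(pos - end)))
}

#' Annotate cis/trans status of the proteins in each record
#'
#' A protein is in cis with the variant when the variant lies on the
#' chromosome of the protein's coding gene and strictly less than `window`
#' bp from the nearest gene edge (distance 0 inside the gene body).
#'
#' @param records data.frame with `proteinA`, `proteinB`, `chrom`, `pos`.
#' @param gene_table data.frame `id` (or `protein`), `chrom`, `start`, `end`.
#' @param window Distance cut in bp, strict (default 1e6).
#' @return `records` with logical columns `cisA`, `cisB` and a `cis_protein`
#'   label (the cis protein's id when exactly one of the two is cis, else NA).
#' @export
annotate_cis_trans <- function(records, gene_table, window = 1e6) {
  records <- as.data.frame(records)
  gene_table <- as.data.frame(gene_table)
  idcol <- if ("protein" %in% names(gene_table)) "protein" else "id"
  cis_of <- function(protein, chrom, pos) {
    j <- match(protein, gene_table[[idcol]])
    if (anyNA(j)) {
      stop("no gene coordinates for protein(s): ",
           paste(unique(protein[is.na(j)]), collapse = ", "))
    }
    same <- as.character(gene_table$chrom[j]) == as.character(chrom)
    d <- gene_distance(pos, gene_table$start[j], gene_table$end[j])
    same & d < window
  }
  records$cisA <- cis_of(records$proteinA, records$chrom, records$pos)
  records$cisB <- cis_of(records$proteinB, records$chrom, records$pos)
  records$cis_protein <- ifelse(records$cisA & !records$cisB, records$proteinA,
                          ifelse(records$cisB & !records$cisA, records$proteinB,
                                 NA_character_))
  records
}

#' Flag ratio associations that are novel relative to known pQTLs
#'
#' A record is novel when no known pQTL of either protein in the ratio lies
#' on the same chromosome strictly within `window` bp of the record's
#' variant.
#'
#' @param records data.frame with `proteinA`, `proteinB`, `chrom`, `pos`.
#' @param known_pqtls data.frame `variant`, `protein`.
#' @param variant_map data.frame `id`, `chrom`, `pos` locating every known
#'   pQTL variant.
#' @param window Distance cut in bp (default 1e6; novel means more distant
#'   than this).
#' @return `records` with a logical `novel` column.
#' @export
flag_novel <- function(records, known_pqtls, variant_map, window = 1e6) {
  records <- as.data.frame(records)
  known_pqtls <- as.data.frame(known_pqtls)
  variant_map <- as.data.frame(variant_map)
  j <- match(known_pqtls$variant, variant_map$id)
  if (anyNA(j)) {
    stop("known pQTL variant(s) absent from variant map: ",
         paste(unique(known_pqtls$variant[is.na(j)]), collapse = ", "))
  }
  known_pqtls$chrom <- as.character(variant_map$chrom[j])
  known_pqtls$pos <- variant_map$pos[j]
  records$novel <- vapply(seq_len(nrow(records)), function(i) {
    rel <- known_pqtls$protein %in% c(records$proteinA[i], records$proteinB[i]) &
      known_pqtls$chrom == as.character(records$chrom[i]) &
      abs(known_pqtls$pos - records$pos[i]) <= window
    !any(rel)
  }, logical(1))
  records
}

#' Test one variant against all ratios within a protein subset
#'
#' Exhaustively tests the k(k-1)/2 unordered ratios between the given
#' proteins against a single variant and returns those whose p-gain exceeds
#' `pgain_min` — the all-against-all mode used at pleiotropic loci where many
#' functionally related proteins associate with one variant.
#'
#' @param variant Variant id present in the cohort genotypes.
#' @param protein_subset Character vector of >= 2 protein ids.
#' @param cohort Cohort list (`proteins`, `genotypes`, `covariates`).
#' @param pgain_min Critical p-gain on the natural scale (default 1e10).
#' @return data.frame of passing ratios (columns as in [targeted_scan()]
#'   records); attribute `n_tested` holds the number of ratios tested.
#' @export
variant_all_ratios <- function(variant, protein_subset, cohort,
                               pgain_min = 1e10) {
  protein_subset <- unique(as.character(protein_subset))
  if (length(protein_subset) < 2L) stop("need >= 2 proteins in the subset")
  if (!(variant %in% colnames(cohort$genotypes))) {
    stop("unknown variant: ", variant)
  }
  pairs <- t(utils::combn(sort(protein_subset), 2L))
  candidates <- data.frame(proteinA = pairs[, 1L], proteinB = pairs[, 2L],
                           variant = variant, stringsAsFactors = FALSE)
  scan <- targeted_scan(candidates, cohort, replication = NULL)
  rec <- scan$records
  out <- rec[rec$logPgain > log10(pgain_min), , drop = FALSE]
  out$significant <- NULL
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(rec)
  out
}

#' Moving-average significance rate along the partial-correlation axis
#'
#' Sorts test results by |pcor| and reports the fraction of significant
#' p-gains within a sliding window, summarizing how the chance of a
#' significant ratio association grows with the strength of the partial
#' correlation between the pair.
#'
#' @param results data.frame with `abs_pcor` (or `pcor`, of which the
#'   absolute value is taken) and a logical `significant` column.
#' @param window Window size in data points (default 10000).
#' @return data.frame `abs_pcor` (window-center value), `rate`. With fewer
#'   results than `window`, a single global fraction is returned with a
#'   warning.
#' @export
summarize_pgain_rate_by_pcor <- function(results, window = 10000L) {
  results <- as.data.frame(results)
  ap <- if ("abs_pcor" %in% names(results)) results$abs_pcor else abs(results$pcor)
  if (is.null(ap)) stop("'results' needs an 'abs_pcor' or 'pcor' column")
  sig <- as.logical(results$significant)
  ord <- order(ap)
  ap <- ap[ord]; sig <- sig[ord]
  n <- length(ap)
  if (n < window) {
    warning("fewer results (", n, ") than window (", window,
            "); returning the global fraction")
    return(data.frame(abs_pcor = stats::median(ap), rate = mean(sig)))
  }
  cs <- cumsum(sig)
  starts <- seq_len(n - window + 1L)
  ends <- starts + window - 1L
  rate <- (cs[ends] - c(0, cs[starts[-1L] - 1L])) / window
  centers <- (ap[starts] + ap[ends]) / 2
  data.frame(abs_pcor = centers, rate = rate)
}
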