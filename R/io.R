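#' Read a protein abundance matrix from TSV
#'
#' Expects a tab-separated file with a header row; the first column holds
#' sample ids, remaining columns one protein each. `NA` is the missing token.
#'
#' @param path File path.
#' @return Numeric samples x proteins matrix with dimnames.
#' @export
read_protein_matrix <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L) stop("protein matrix file needs sample id + >= 1 protein column")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    line <- which(duplicated(ids))[1L] + 1L  # +1 for the header
    stop("duplicate sample id '", dup[1L], "' at line ", line, " of ", path)
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(!is.na(vals[[j]]) & is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop("non-numeric value in column '", names(vals)[j], "' at line ",
           bad + 1L, " of ", path)
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  as_protein_matrix(mat)
}

#' Write a protein matrix to TSV
#' @param mat Samples x proteins matrix with dimnames.
#' @param path Output path.
#' @export
write_protein_matrix <- function(mat, path) {
  mat <- as_protein_matrix(mat)
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read genotype dosages in PLINK .raw text dialect
#'
#' Expects the header `FID IID PAT MAT SEX PHENOTYPE` followed by one column
#' per variant named `<id>_<effect allele>`, with dosage values 0/1/2/NA.
#' Sample ids are taken from IID.
#'
#' @param path File path.
#' @return List: `genotypes` (samples x variants matrix, variant ids as
#'   colnames), `effect_allele` (named character vector).
#' @export
read_genotypes_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "", as.is = TRUE,
                          check.names = FALSE, na.strings = "NA")
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% names(df)[1:6])) {
    stop("not a PLINK .raw file: expected header columns ",
         paste(fixed, collapse = " "))
  }
  vcols <- setdiff(names(df), fixed)
  if (!length(vcols)) stop("no variant columns in ", path)
  ok <- grepl("_[A-Za-z]+$", vcols)
  if (any(!ok)) {
    stop("variant column(s) without an _allele suffix: ",
         paste(vcols[!ok], collapse = ", "))
  }
  vid <- sub("_[A-Za-z]+$", "", vcols)
  allele <- sub("^.*_", "", vcols)
  geno <- as.matrix(df[, vcols, drop = FALSE])
  rownames(geno) <- as.character(df$IID)
  colnames(geno) <- vid
  bad <- !is.na(geno) & !(geno %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("dosage outside {0,1,2,NA} at sample '", rownames(geno)[idx[1L]],
         "', variant '", colnames(geno)[idx[2L]], "' in ", path)
  }
  list(genotypes = as_genotype_matrix(geno),
       effect_allele = stats::setNames(allele, vid))
}

#' Write genotype dosages in PLINK .raw text dialect
#' @param geno Samples x variants dosage matrix with dimnames.
#' @param effect_allele Named character vector (variant id -> allele); a
#'   default of "A" is used for variants without an entry.
#' @param path Output path.
#' @export
write_genotypes_raw <- function(geno, path, effect_allele = NULL) {
  geno <- as_genotype_matrix(geno)
  vid <- colnames(geno)
  al <- rep("A", length(vid))
  if (!is.null(effect_allele)) {
    hit <- match(vid, names(effect_allele))
    al[!is.na(hit)] <- effect_allele[hit[!is.na(hit)]]
  }
  df <- data.frame(FID = rownames(geno), IID = rownames(geno), PAT = 0L,
                   MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
                   stringsAsFactors = FALSE)
  g <- as.data.frame(geno)
  names(g) <- paste0(vid, "_", al)
  utils::write.table(cbind(df, g), path, sep = " ", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a variant map (id, chrom, pos, a1, a2)
#' @param path TSV path with header.
#' @return data.frame with at least `id`, `chrom`, `pos` columns.
#' @export
read_variant_map <- function(path) {
  df <- read_tsv_checked(path, required = c("id", "chrom", "pos"))
  if (anyDuplicated(df$id)) stop("duplicate variant id in ", path)
  if (any(df$pos < 1)) stop("variant position must be >= 1 in ", path)
  df
}

#' Read a gene coordinate table (protein, chrom, start, end)
#' @param path TSV path with header.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  read_tsv_checked(path, required = c("protein", "chrom", "start", "end"))
}

#' Read a known pQTL table (variant, protein, neglog10p)
#' @param path TSV path with header.
#' @return data.frame.
#' @export
read_known_pqtls <- function(path) {
  df <- read_tsv_checked(path, required = c("variant", "protein"))
  if (anyDuplicated(df[c("variant", "protein")])) {
    stop("duplicate (variant, protein) rows in ", path)
  }
  df
}

#' Read a STRING-dialect protein interaction reference
#'
#' Expects columns `protein1`, `protein2`, `combined_score`, with scores as
#' 0-1000 integers (normalized to [0, 1] on read). An optional alias table
#' maps reference identifiers to the protein ids used in the analysis.
#'
#' @param path TSV path.
#' @param alias Optional data.frame `alias`, `protein` for identifier mapping.
#' @return data.frame `protein1`, `protein2`, `score` in [0, 1].
#' @export
read_interaction_reference <- function(path, alias = NULL) {
  df <- read_tsv_checked(path,
                         required = c("protein1", "protein2", "combined_score"))
  if (any(df$combined_score < 0 | df$combined_score > 1000)) {
    stop("combined_score must lie in [0, 1000] in ", path)
  }
  out <- data.frame(protein1 = as.character(df$protein1),
                    protein2 = as.character(df$protein2),
                    score = df$combined_score / 1000,
                    stringsAsFactors = FALSE)
  if (!is.null(alias)) {
    alias <- as.data.frame(alias)
    map <- stats::setNames(as.character(alias$protein), as.character(alias$alias))
    hit1 <- out$protein1 %in% names(map)
    hit2 <- out$protein2 %in% names(map)
    out$protein1[hit1] <- map[out$protein1[hit1]]
    out$protein2[hit2] <- map[out$protein2[hit2]]
  }
  out
}

#' Read / write partial-correlation edge tables
#' @param path TSV path.
#' @return data.frame `proteinA`, `proteinB`, `pcor`, `neglog10p`,
#'   `significant`.
#' @export
read_edges <- function(path) {
  df <- read_tsv_checked(path, required = c("proteinA", "proteinB", "pcor",
                                            "neglog10p", "significant"))
  df$significant <- as.logical(df$significant)
  df
}

#' @rdname read_edges
#' @param edges Edge data.frame (from [significant_edges()]).
#' @export
write_edges <- function(edges, path) {
  write_tsv_full(edges[c("proteinA", "proteinB", "pcor", "neglog10p",
                         "significant")], path)
}

#' Write / read an rQTL record table
#'
#' All p-values and p-gains are serialized on the -log10 scale with full
#' precision; raw p-values are never written.
#'
#' @param records rQTL record data.frame (from [targeted_scan()] /
#'   [ratio_gwas()]).
#' @param path TSV path.
#' @export
write_rqtl_table <- function(records, path) {
  write_tsv_full(as.data.frame(records), path)
}

#' @rdname write_rqtl_table
#' @export
read_rqtl_table <- function(path) {
  df <- read_tsv_checked(path, required = c("ratio", "variant", "neglogP1",
                                            "neglogP2", "neglogP3", "logPgain"))
  for (col in c("significant", "replicated", "novel", "cisA", "cisB")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Read a flat key: value run configuration
#'
#' A minimal YAML-subset config: one `key: value` pair per line, `#` comments
#' and blank lines ignored. Values are parsed as numbers where possible.
#' Every threshold of the pipeline has a default (see [default_config()]);
#' the file only overrides.
#'
#' @param path Config file path; `NULL` returns the defaults.
#' @return Named list of settings.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^:]+):[[:space:]]*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[2L]); val <- trimws(kv[3L])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' Default thresholds of the ratio-QTL pipeline
#' @return Named list of all tunable thresholds with their defaults.
#' @export
default_config <- function() {
  list(
    sample_max_missing = 0.2, protein_max_missing = 0.2,
    ggm_alpha = 0.05,
    geno_max_missing = 0.1, mind_max_missing = 0.1,
    maf_min = 0.01, mac_min = 100, hwe_p_min = 1e-15,
    pgain_alpha = 0.05,
    genomewide_alpha = 5e-8, pgain_base = 1e7,
    prune_distance = 1e6, cis_window = 1e6, novel_window = 1e6,
    string_score_min = 0.7, n_resamples = 100,
    seed = 1
  )
}

#' Write a flat key: value configuration
#' @param cfg Named list.
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  writeLines(paste0(names(cfg), ": ",
                    vapply(cfg, function(v) format(v, digits = 17),
                           character(1))),
             path)
  invisible(path)
}

#' Write a machine-readable run log
#' @param path JSON output path.
#' @param ... Named entries (thresholds, stage counts, seed).
#' @keywords internal
write_run_log <- function(path, ...) {
  entries <- list(...)
  entries$package_version <- as.character(utils::packageVersion("ratioqtl"))
  entries$r_version <- as.character(getRversion())
  entries$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Strict TSV reader: header required, ragged rows rejected with line numbers,
# required columns checked.
read_tsv_checked <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  n_fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(n_fields)) > 1L) {
    bad <- which(n_fields != n_fields[1L])[1L]
    stop("ragged row at line ", bad, " of ", path, " (", n_fields[bad],
         " fields, expected ", n_fields[1L], ")")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          as.is = TRUE, check.names = FALSE,
                          na.strings = "NA")
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop("missing required column(s) in ", path, ": ",
           paste(missing, collapse = ", "))
    }
  }
  df
}

# Full-precision TSV writer.
write_tsv_full <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- format(df[[j]], digits = 17, trim = TRUE,
                                          scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a synthetic cohort to disk in the pipeline's file formats
#'
#' Emits the protein matrix TSV, PLINK-.raw genotypes, variant map TSV, gene
#' table TSV, covariate TSV, cohort assignment TSV, and a flat key: value
#' truth file recording the generating parameters.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteins = file.path(dir, "proteins.tsv"),
    genotypes = file.path(dir, "genotypes.raw"),
    variants = file.path(dir, "variants.tsv"),
    genes = file.path(dir, "genes.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    cohort = file.path(dir, "cohort.tsv"),
    truth = file.path(dir, "truth.txt")
  )
  write_protein_matrix(cohort$proteins, paths["proteins"])
  write_genotypes_raw(cohort$genotypes, paths["genotypes"])
  vm <- cohort$variants
  vm$a1 <- "A"; vm$a2 <- "B"
  write_tsv_full(vm[c("id", "chrom", "pos", "a1", "a2")], paths["variants"])
  gt <- cohort$gene_table
  names(gt)[names(gt) == "id"] <- "protein"
  write_tsv_full(gt[c("protein", "chrom", "start", "end")], paths["genes"])
  cov <- data.frame(sample_id = rownames(cohort$covariates),
                    cohort$covariates, stringsAsFactors = FALSE)
  write_tsv_full(cov, paths["covariates"])
  write_tsv_full(data.frame(sample_id = rownames(cohort$proteins),
                            cohort = as.character(cohort$cohort),
                            stringsAsFactors = FALSE), paths["cohort"])
  tr <- cohort$truth
  write_run_config(list(
    n_samples = tr$n_samples, n_discovery = tr$n_discovery,
    n_variants = nrow(tr$variants), n_proteins = nrow(tr$proteins),
    n_factors = tr$n_factors, missing_rate = tr$missing_rate,
    seed = tr$seed,
    alpha = paste(format(tr$alpha, digits = 17), collapse = ","),
    epsilon_sd = paste(format(tr$epsilon_sd, digits = 17), collapse = ","),
    beta = paste(format(as.vector(tr$beta), digits = 17), collapse = ","),
    gamma = paste(format(as.vector(tr$gamma), digits = 17), collapse = ",")
  ), paths["truth"])
  paths
}
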