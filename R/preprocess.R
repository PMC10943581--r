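#' Missingness filtering of a protein abundance matrix
#'
#' Applies the two-stage completeness filter used before network estimation:
#' samples with a missing fraction above `sample_max_missing` are removed
#' first, then proteins missing in more than `protein_max_missing` of the
#' *retained* samples are removed. The order is normative: filtering proteins
#' first can give a different result.
#'
#' @param mat Numeric matrix, samples in rows, proteins in columns, with
#'   rownames (sample ids) and colnames (protein ids). `NA` marks missing.
#' @param sample_max_missing Maximum tolerated per-sample missing fraction
#'   (strict inequality; default 0.2).
#' @param protein_max_missing Maximum tolerated per-protein missing fraction,
#'   computed on retained samples (strict inequality; default 0.2).
#' @return The filtered matrix, with attributes `samples_removed` and
#'   `proteins_removed` holding the dropped ids.
#' @export
filter_missingness <- function(mat, sample_max_missing = 0.2,
                               protein_max_missing = 0.2) {
  mat <- as_protein_matrix(mat)
  stopifnot(sample_max_missing >= 0, sample_max_missing <= 1,
            protein_max_missing >= 0, protein_max_missing <= 1)
  samp_frac <- rowMeans(is.na(mat))
  keep_s <- samp_frac <= sample_max_missing
  if (!any(keep_s)) {
    stop("sample missingness filter removed every sample (threshold ",
         sample_max_missing, ")")
  }
  out <- mat[keep_s, , drop = FALSE]
  prot_frac <- colMeans(is.na(out))
  keep_p <- prot_frac <= protein_max_missing
  if (!any(keep_p)) {
    stop("protein missingness filter removed every protein (threshold ",
         protein_max_missing, ")")
  }
  res <- out[, keep_p, drop = FALSE]
  attr(res, "samples_removed") <- rownames(mat)[!keep_s]
  attr(res, "proteins_removed") <- colnames(mat)[!keep_p]
  res
}

#' Impute remaining missing values to the per-protein observed minimum
#'
#' Olink-style abundances missing after the completeness filters are treated
#' as below-detection and set to the lowest observed value of that protein.
#'
#' @param mat Numeric samples x proteins matrix with dimnames.
#' @return Matrix of the same shape with no missing values.
#' @export
impute_minimum <- function(mat) {
  mat <- as_protein_matrix(mat)
  all_missing <- colSums(!is.na(mat)) == 0L
  if (any(all_missing)) {
    stop("protein(s) with no observed values cannot be imputed: ",
         paste(colnames(mat)[all_missing], collapse = ", "))
  }
  for (j in seq_len(ncol(mat))) {
    miss <- is.na(mat[, j])
    if (any(miss)) mat[miss, j] <- min(mat[, j], na.rm = TRUE)
  }
  mat
}

#' Rank-based inverse-normal transform (Blom offset)
#'
#' Maps the non-missing entries of a phenotype vector to standard-normal
#' quantiles via qnorm((rank - 3/8) / (m + 1/4)), where m is the number of
#' non-missing values and ties receive average ranks. Missing entries stay
#' missing.
#'
#' @param x Numeric vector, `NA` allowed.
#' @return Numeric vector of the same length; non-missing entries replaced by
#'   normal quantiles, mean approximately 0.
#' @examples
#' inverse_normal_transform(c(1, 2, 3)) # -0.8416, 0, 0.8416
#' @export
inverse_normal_transform <- function(x) {
  obs <- !is.na(x)
  m <- sum(obs)
  if (m < 3L) stop("inverse-normal transform needs >= 3 non-missing values, got ", m)
  r <- rank(x[obs], ties.method = "average")
  out <- x
  out[obs] <- stats::qnorm((r - 3 / 8) / (m + 1 / 4))
  out
}

#' Construct an inverse-normal-scaled log-ratio phenotype
#'
#' Because NPX abundances are on a log scale, the log of the ratio A/B is the
#' difference of the two columns: log(A/B) = log(A) - log(B). The difference
#' is inverse-normal transformed (within whatever sample set `mat` holds, so
#' callers analysing cohorts separately transform separately). Entries where
#' either protein is missing stay missing.
#'
#' @param mat Numeric samples x proteins matrix with dimnames.
#' @param pair Character vector of two protein ids `(numerator, denominator)`.
#' @param transform Apply the inverse-normal transform (default TRUE). With
#'   `FALSE` the raw difference is returned (useful for effect-size recovery
#'   on the original log-abundance scale).
#' @return Named numeric phenotype vector aligned with `rownames(mat)`.
#' @export
make_ratio_phenotype <- function(mat, pair, transform = TRUE) {
  mat <- as_protein_matrix(mat)
  pair <- as.character(pair)
  if (length(pair) != 2L || pair[1] == pair[2]) {
    stop("'pair' must name two distinct proteins")
  }
  missing_ids <- setdiff(pair, colnames(mat))
  if (length(missing_ids)) {
    stop("unknown protein id(s): ", paste(missing_ids, collapse = ", "))
  }
  d <- mat[, pair[1]] - mat[, pair[2]]
  obs <- d[!is.na(d)]
  if (length(obs) >= 1L && length(unique(obs)) == 1L) {
    stop("degenerate ratio phenotype: ", pair[1], " - ", pair[2],
         " is constant across samples")
  }
  if (transform) d <- inverse_normal_transform(d)
  stats::setNames(d, rownames(mat))
}

# Coerce to a numeric matrix with unique sample/protein ids.
as_protein_matrix <- function(mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("protein matrix must be a numeric samples x proteins matrix")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("protein matrix needs sample ids (rownames) and protein ids (colnames)")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate sample ids in protein matrix")
  if (anyDuplicated(colnames(mat))) stop("duplicate protein ids in protein matrix")
  if (any(is.infinite(mat))) stop("protein matrix contains non-finite values")
  mat
}
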