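#' Normalized reaction abundances per sample
#'
#' For each sample, the abundance of reaction i is the abundance-weighted
#' mean of the per-ASV reaction probabilities over the mapped ASVs:
#' \deqn{a_r(i) = \frac{\sum_j a_{ASV}(j)\,E(i,j)}{\sum_j a_{ASV}(j)}}
#' where the sums run over the ASVs present in the expectation matrix. ASVs
#' without a model match are excluded from both numerator and denominator,
#' so each value lies between the smallest and largest E entry of its row
#' and is invariant to rescaling a sample's counts.
#'
#' @param counts samples-by-ASVs count matrix (raw counts or relative
#'   abundances; the formula is scale-invariant per sample).
#' @param e_matrix reactions-by-ASVs expectation matrix from
#'   [build_expectation_matrix()]; every column must name an ASV of
#'   `counts`.
#' @return numeric matrix, samples (rows) by reactions (columns), values in
#'   \[0, 1\].
#' @export
compute_reaction_abundances <- function(counts, e_matrix) {
  asvs <- colnames(e_matrix)
  missing <- setdiff(asvs, colnames(counts))
  if (length(missing))
    abort_contract(sprintf("E-matrix ASVs absent from count table: %s",
                           paste(head(missing, 5L), collapse = ", ")))
  w <- counts[, asvs, drop = FALSE]
  storage.mode(w) <- "double"
  tot <- rowSums(w)
  zero <- tot == 0
  if (any(zero))
    abort_contract(sprintf("sample(s) with zero total mapped abundance: %s",
                           paste(rownames(counts)[zero], collapse = ", ")))
  A <- (w %*% t(e_matrix)) / tot
  dimnames(A) <- list(rownames(counts), rownames(e_matrix))
  A
}

#' Column-wise z-score standardization
#'
#' Standardizes each column (reaction or ASV) to mean 0 and unit variance
#' across samples (sd with denominator n - 1). Zero-variance columns are set
#' to all zeros and reported in the `constant_columns` attribute.
#'
#' @param x numeric matrix, samples (rows) by features (columns), >= 2 rows.
#' @return matrix of z-scores with attribute `constant_columns` (character
#'   vector of flagged column names).
#' @export
zscore_standardize <- function(x) {
  if (nrow(x) < 2L)
    abort_contract("z-score standardization needs at least two samples")
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  const <- s == 0 | is.na(s)
  s[const] <- 1
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, s, "/")
  z[, const] <- 0
  attr(z, "constant_columns") <- colnames(x)[const]
  z
}
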