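#' Principal component analysis of a sample-by-feature matrix
#'
#' PCA via singular value decomposition of the column-centered matrix
#' (stats::prcomp). For a reproducible orientation, each component is
#' flipped so that its largest-magnitude loading is positive. When sample
#' groups are supplied, per-group mean scores with 95% confidence intervals
#' (t distribution, n - 1 df per group) are reported — groups are small in
#' typical feeding trials (13 fish per diet), so the t critical value
#' matters.
#'
#' @param x numeric matrix, samples (rows) by features (columns). Typically
#'   a z-score matrix from [zscore_standardize()]; set `standardize = TRUE`
#'   to standardize internally.
#' @param n_components number of components to retain (default: all).
#' @param groups optional factor/character vector of group labels, one per
#'   sample.
#' @param standardize if TRUE, z-score columns first (zero-variance columns
#'   dropped from the PCA input).
#' @param conf confidence level for group-mean intervals.
#' @return list of class `reactcap_pca`: `scores` (samples x components),
#'   `loadings` (features x components, orthonormal), `var_explained_pct`
#'   (percent variance per retained component), `var_explained_pct_all`
#'   (all components; sums to 100), `center`, and optionally `group_means`
#'   (data.frame: group, component, mean, lower, upper, n).
#' @export
pca_ordination <- function(x, n_components = NULL, groups = NULL,
                           standardize = FALSE, conf = 0.95) {
  if (nrow(x) < 2L) abort_contract("PCA needs at least two samples")
  if (standardize) {
    x <- zscore_standardize(x)
    keep <- setdiff(colnames(x), attr(x, "constant_columns"))
    x <- x[, keep, drop = FALSE]
  }
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp)
    abort_contract(sprintf("n_components (%d) exceeds min(samples - 1, features) = %d",
                           n_components, max_comp))
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  # reproducible sign: largest-magnitude loading of each component positive
  flip <- vapply(seq_len(ncol(fit$rotation)), function(k) {
    v <- fit$rotation[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1L))
  flip[flip == 0] <- 1
  fit$rotation <- sweep(fit$rotation, 2L, flip, "*")
  fit$x <- sweep(fit$x, 2L, flip, "*")
  var_all <- fit$sdev^2
  pct_all <- 100 * var_all / sum(var_all)
  res <- list(
    scores = fit$x[, seq_len(n_components), drop = FALSE],
    loadings = fit$rotation[, seq_len(n_components), drop = FALSE],
    var_explained_pct = pct_all[seq_len(n_components)],
    var_explained_pct_all = pct_all,
    center = fit$center
  )
  if (!is.null(groups)) {
    if (length(groups) != nrow(x))
      abort_contract("groups must have one label per sample")
    res$group_means <- group_score_ci(res$scores, groups, conf)
  }
  class(res) <- "reactcap_pca"
  res
}

group_score_ci <- function(scores, groups, conf = 0.95) {
  groups <- as.character(groups)
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    s <- scores[groups == g, , drop = FALSE]
    n <- nrow(s)
    mu <- colMeans(s)
    se <- apply(s, 2L, sd) / sqrt(n)
    half <- if (n > 1L) qt(1 - (1 - conf) / 2, df = n - 1L) * se else rep(NA_real_, ncol(s))
    data.frame(group = g, component = colnames(s), mean = mu,
               lower = mu - half, upper = mu + half, n = n,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' @export
print.reactcap_pca <- function(x, ...) {
  k <- min(5L, length(x$var_explained_pct))
  cat(sprintf("PCA: %d samples, %d components retained\n", nrow(x$scores),
              ncol(x$scores)))
  cat("variance explained (%):",
      paste(sprintf("%s %.1f", colnames(x$scores)[seq_len(k)],
                    x$var_explained_pct[seq_len(k)]), collapse = ", "), "\n")
  invisible(x)
}
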