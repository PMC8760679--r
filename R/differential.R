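#' Two-sample t-test
#'
#' Student's pooled-variance two-sided t-test by default (Welch available);
#' the t statistic carries the sign of `mean(a) - mean(b)`. When the pooled
#' variance is zero the reaction is untestable: `t` and `p` are returned as
#' NA and `tested` is FALSE, and such features are excluded from the
#' multiple-testing universe downstream.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pooled-variance Student test if TRUE (default), Welch
#'   otherwise.
#' @return named list: `t`, `p`, `df`, `tested`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    abort_contract("each group needs at least two values")
  r <- row_t_stat(matrix(a, nrow = 1L), matrix(b, nrow = 1L), var_equal)
  list(t = r$t[1L], p = r$p[1L], df = r$df[1L], tested = r$tested[1L])
}

# Vectorized pooled/Welch t over matrix rows (features x samples).
row_t_stat <- function(A, B, var_equal = TRUE) {
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1L)
  v2 <- rowSums((B - m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  tested <- se > 0
  t <- ifelse(tested, (m1 - m2) / se, NA_real_)
  p <- ifelse(tested, 2 * pt(-abs(t), df), NA_real_)
  list(t = t, p = p, df = ifelse(tested, df, NA_real_), tested = tested,
       mean1 = m1, mean2 = m2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (via [stats::p.adjust()]): sort
#' ascending, multiply by m/rank, enforce monotonicity from the largest rank
#' down, cap at 1, restore input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0L))
  if (anyNA(p) || any(p < 0 | p > 1))
    abort_contract("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential reaction abundance between two diets
#'
#' Tests every reaction for a mean-abundance difference between two diet
#' groups with a two-sample t-test, then applies Benjamini-Hochberg
#' correction over the testable reactions (zero-pooled-variance reactions
#' are untestable and excluded from the correction universe). Reactions
#' with adjusted p <= `alpha` are flagged significant.
#'
#' @param abundance samples-by-reactions matrix from
#'   [compute_reaction_abundances()].
#' @param metadata sample metadata (sample_id, group).
#' @param diet_pair character vector of two diet labels; the difference and
#'   t statistic are oriented diet1 - diet2.
#' @param var_equal Student pooled-variance test if TRUE (default), Welch
#'   otherwise.
#' @param alpha significance level on the adjusted p-value.
#' @return data.frame, one row per reaction: diet1, diet2, reaction, mean1,
#'   mean2, diff, t, p, p_adj, significant, tested.
#' @export
differential_reactions <- function(abundance, metadata, diet_pair,
                                   var_equal = TRUE, alpha = 0.05) {
  metadata <- validate_sample_metadata(metadata)
  if (length(diet_pair) != 2L)
    abort_contract("diet_pair must name exactly two groups")
  unknown <- setdiff(diet_pair, metadata$group)
  if (length(unknown))
    abort_contract(sprintf("unknown diet label(s): %s", paste(unknown, collapse = ", ")))
  s1 <- intersect(rownames(abundance), metadata$sample_id[metadata$group == diet_pair[1L]])
  s2 <- intersect(rownames(abundance), metadata$sample_id[metadata$group == diet_pair[2L]])
  if (length(s1) < 2L || length(s2) < 2L)
    abort_contract("each diet needs at least two samples in the abundance matrix")
  A <- t(abundance[s1, , drop = FALSE])
  B <- t(abundance[s2, , drop = FALSE])
  r <- row_t_stat(A, B, var_equal)
  p_adj <- rep(NA_real_, length(r$p))
  p_adj[r$tested] <- benjamini_hochberg(r$p[r$tested])
  data.frame(
    diet1 = diet_pair[1L], diet2 = diet_pair[2L],
    reaction = colnames(abundance),
    mean1 = r$mean1, mean2 = r$mean2, diff = r$mean1 - r$mean2,
    t = r$t, p = r$p, p_adj = p_adj,
    significant = !is.na(p_adj) & p_adj <= alpha,
    tested = r$tested,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pathway (subsystem) enrichment among significant reactions
#'
#' For each subsystem with at least one tested reaction, a one-sided
#' (over-representation) Fisher's exact test on the 2x2 table of
#' significant/non-significant by in-subsystem/outside, over tested
#' reactions only, followed by Benjamini-Hochberg correction across
#' subsystems. The direction of an enriched subsystem follows the mean t
#' statistic of its significant reactions: `diet1` if positive, `diet2` if
#' negative, and `mixed` when the signs disagree and the mean's magnitude
#' is within its 95% confidence half-width. Reactions belonging to several
#' subsystems count once in each.
#'
#' @param diff_table output of [differential_reactions()].
#' @param catalog a `model_catalog` carrying the reaction-to-subsystem map.
#' @param alpha enrichment significance level on the adjusted p-value.
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @param conf confidence level for the mean-t interval.
#' @return data.frame, one row per subsystem: diet1, diet2, subsystem,
#'   n_sig_in, n_sig_out, n_nonsig_in, n_nonsig_out, p, p_adj, enriched,
#'   direction, mean_t, t_lower, t_upper.
#' @export
pathway_enrichment <- function(diff_table, catalog, alpha = 0.05,
                               alternative = c("greater", "two.sided"),
                               conf = 0.95) {
  stopifnot(inherits(catalog, "model_catalog"))
  alternative <- match.arg(alternative)
  tested <- diff_table[diff_table$tested, , drop = FALSE]
  if (nrow(tested) == 0L)
    abort_contract("no testable reactions in the differential table")
  sub_map <- catalog$subsystems[intersect(names(catalog$subsystems), tested$reaction)]
  membership <- data.frame(
    reaction = rep(names(sub_map), lengths(sub_map)),
    subsystem = unlist(sub_map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  subsystems <- sort(unique(membership$subsystem))
  sig <- tested$significant
  names(sig) <- tested$reaction
  tvals <- tested$t
  names(tvals) <- tested$reaction
  n_tested <- nrow(tested)
  rows <- lapply(subsystems, function(s) {
    in_sub <- unique(membership$reaction[membership$subsystem == s])
    in_sub <- intersect(in_sub, tested$reaction)
    if (length(in_sub) == 0L) return(NULL)  # no tested reaction: skipped
    a <- sum(sig[in_sub])                    # significant, in subsystem
    b <- sum(sig) - a                        # significant, outside
    c_ <- length(in_sub) - a                 # non-significant, in subsystem
    d <- n_tested - a - b - c_
    p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE),
                     alternative = alternative)$p.value
    sig_t <- tvals[in_sub][sig[in_sub]]
    mean_t <- if (length(sig_t)) mean(sig_t) else NA_real_
    half <- if (length(sig_t) > 1L)
      qt(1 - (1 - conf) / 2, df = length(sig_t) - 1L) * sd(sig_t) / sqrt(length(sig_t))
    else NA_real_
    direction <- if (!length(sig_t)) NA_character_
    else if (length(unique(sign(sig_t))) > 1L && !is.na(half) && abs(mean_t) < half) "mixed"
    else if (mean_t > 0) "diet1" else if (mean_t < 0) "diet2" else "mixed"
    data.frame(diet1 = diff_table$diet1[1L], diet2 = diff_table$diet2[1L],
               subsystem = s, n_sig_in = a, n_sig_out = b,
               n_nonsig_in = c_, n_nonsig_out = d, p = p,
               mean_t = mean_t,
               t_lower = if (is.na(half)) NA_real_ else mean_t - half,
               t_upper = if (is.na(half)) NA_real_ else mean_t + half,
               direction = direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) return(empty_enrichment_table())
  out$p_adj <- benjamini_hochberg(out$p)
  out$enriched <- out$p_adj <= alpha & out$n_sig_in >= 1L
  out[order(out$p_adj, out$subsystem),
      c("diet1", "diet2", "subsystem", "n_sig_in", "n_sig_out",
        "n_nonsig_in", "n_nonsig_out", "p", "p_adj", "enriched",
        "direction", "mean_t", "t_lower", "t_upper")]
}

empty_enrichment_table <- function() {
  data.frame(diet1 = character(0L), diet2 = character(0L),
             subsystem = character(0L), n_sig_in = integer(0L),
             n_sig_out = integer(0L), n_nonsig_in = integer(0L),
             n_nonsig_out = integer(0L), p = numeric(0L),
             p_adj = numeric(0L), enriched = logical(0L),
             direction = character(0L), mean_t = numeric(0L),
             t_lower = numeric(0L), t_upper = numeric(0L),
             stringsAsFactors = FALSE)
}

#' Differential testing and enrichment for every diet pair
#'
#' Runs [differential_reactions()] (and, when a catalog is supplied,
#' [pathway_enrichment()]) for every unordered pair of diet groups, in the
#' canonical order given by first appearance in the metadata: six diets
#' yield the 15 pairs of a full pairwise comparison.
#'
#' @inheritParams differential_reactions
#' @param catalog optional `model_catalog`; enables enrichment.
#' @param ... passed on to [differential_reactions()] and
#'   [pathway_enrichment()].
#' @return named list (`"diet1 vs diet2"`), each element a list with
#'   `differential` and (if a catalog was given) `enrichment`.
#' @export
pairwise_all <- function(abundance, metadata, catalog = NULL, alpha = 0.05,
                         var_equal = TRUE, ...) {
  metadata <- validate_sample_metadata(metadata)
  present <- metadata$group[metadata$sample_id %in% rownames(abundance)]
  diets <- unique(present)
  if (length(diets) < 2L) abort_contract("need at least two diet groups")
  pairs <- combn(diets, 2L, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    d <- differential_reactions(abundance, metadata, pr,
                                var_equal = var_equal, alpha = alpha)
    res <- list(differential = d)
    if (!is.null(catalog))
      res$enrichment <- pathway_enrichment(d, catalog, alpha = alpha, ...)
    res
  })
  names(out) <- vapply(pairs, function(pr) paste(pr, collapse = " vs "), character(1L))
  out
}

#' Direction matrix of enriched subsystems across diet pairs
#'
#' Machine-readable twin of a pairwise-enrichment heatmap: rows are
#' subsystems enriched in at least one pair, columns are diet pairs, cells
#' are +1 (enriched toward diet1), -1 (toward diet2), 0 (not enriched or
#' mixed).
#'
#' @param pairwise result of [pairwise_all()] run with a catalog.
#' @return integer matrix subsystems x pairs.
#' @export
enrichment_direction_matrix <- function(pairwise) {
  enr <- lapply(pairwise, `[[`, "enrichment")
  subs <- sort(unique(unlist(lapply(enr, function(e) e$subsystem[e$enriched]))))
  M <- matrix(0L, nrow = length(subs), ncol = length(pairwise),
              dimnames = list(subs, names(pairwise)))
  for (j in seq_along(enr)) {
    e <- enr[[j]]
    e <- e[e$enriched, , drop = FALSE]
    if (nrow(e) == 0L) next
    M[e$subsystem, j] <- ifelse(e$direction == "diet1", 1L,
                                ifelse(e$direction == "diet2", -1L, 0L))
  }
  M
}
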