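# Ground-truth oracle for the simulator. Everything here is written as
# plain exhaustive loops, deliberately independent of the pipeline code
# paths (match_asv_to_models / build_expectation_matrix /
# compute_reaction_abundances), so the two routes can be compared in tests.

# Exhaustive per-rank scan: for each ASV try species, genus, family against
# every catalog model of that rank; first rank with a hit wins.
gt_expectation_matrix <- function(taxonomy, catalog) {
  tab <- catalog$models
  all_rxns <- sort(names(catalog$subsystems))
  cols <- list()
  for (i in seq_len(nrow(taxonomy))) {
    hit_models <- character(0L)
    for (rank in c("species", "genus", "family")) {
      nm <- normalize_taxon_name(taxonomy[[rank]][i])
      if (is.na(nm)) next
      found <- character(0L)
      for (m in seq_len(nrow(tab))) {
        if (tab$rank[m] == rank && tab$name_norm[m] == nm)
          found <- c(found, tab$model_id[m])
      }
      if (length(found)) { hit_models <- found; break }
    }
    if (length(hit_models) == 0L) next
    col <- numeric(length(all_rxns)); names(col) <- all_rxns
    for (id in unique(hit_models)) {
      rxns <- unique(tab$reactions[[which(tab$model_id == id)]])
      col[rxns] <- col[rxns] + 1
    }
    cols[[taxonomy$asv_id[i]]] <- col / length(unique(hit_models))
  }
  if (length(cols) == 0L)
    return(matrix(numeric(0L), nrow = length(all_rxns), ncol = 0L,
                  dimnames = list(all_rxns, character(0L))))
  do.call(cbind, cols)
}

#' Expected per-group reaction abundances (ground-truth oracle)
#'
#' Computes, for each group, the expected normalized reaction abundance by
#' direct double summation over the true mean ASV proportions and the true
#' expectation matrix. This is a deliberately naive brute-force
#' implementation kept independent of the pipeline's matrix code path; it
#' serves as the oracle against which [compute_reaction_abundances()] is
#' verified.
#'
#' @param truth ground-truth list with `group_means` (groups x ASVs true
#'   mean proportions) and `e_matrix` (reactions x mapped ASVs).
#' @return numeric matrix, groups (rows) by reactions (columns).
#' @export
ground_truth_reaction_means <- function(truth) {
  E <- truth$e_matrix
  gm <- truth$group_means
  mapped <- colnames(E)
  out <- matrix(0, nrow = nrow(gm), ncol = nrow(E),
                dimnames = list(rownames(gm), rownames(E)))
  for (g in seq_len(nrow(gm))) {
    den <- 0
    for (j in mapped) den <- den + gm[g, j]
    for (i in seq_len(nrow(E))) {
      num <- 0
      for (j in mapped) num <- num + gm[g, j] * E[i, j]
      out[g, i] <- if (den > 0) num / den else 0
    }
  }
  out
}

# Reactions whose expected abundance differs by at least delta between some
# pair of groups.
gt_shifted_reactions <- function(expected_a_r, delta) {
  if (nrow(expected_a_r) < 2L || ncol(expected_a_r) == 0L) return(character(0L))
  rng <- apply(expected_a_r, 2L, function(v) max(v) - min(v))
  colnames(expected_a_r)[rng >= delta]
}
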