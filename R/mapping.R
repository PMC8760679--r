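#' Match ASVs to genome-scale metabolic models by taxonomy
#'
#' Each ASV is matched at the lowest available rank: the species name is
#' tried first against species-rank models, then genus against genus-rank
#' models, then family against family-rank models; the first rank with at
#' least one (normalized, exact) name match wins and all models at that rank
#' are returned. ASVs resolved only above family, or matching no model at
#' any of the three ranks, are unmatched — a value, not an error — and are
#' excluded from downstream reaction analysis.
#'
#' @param taxonomy taxonomy table (see [taxonomy_table()]).
#' @param catalog a `model_catalog`.
#' @return data.frame with one row per ASV: `asv_id`, `matched_rank`
#'   (species/genus/family/none) and a `models` list-column of model ids.
#' @export
match_asv_to_models <- function(taxonomy, catalog) {
  stopifnot(inherits(catalog, "model_catalog"))
  cat_tab <- catalog$models
  by_rank <- split(seq_len(nrow(cat_tab)), cat_tab$rank)
  matched_rank <- rep("none", nrow(taxonomy))
  models <- vector("list", nrow(taxonomy))
  for (i in seq_len(nrow(taxonomy))) {
    models[[i]] <- character(0L)
    for (rank in c("species", "genus", "family")) {
      nm <- normalize_taxon_name(taxonomy[[rank]][i])
      if (is.na(nm)) next
      idx <- by_rank[[rank]]
      hit <- idx[cat_tab$name_norm[idx] == nm]
      if (length(hit)) {
        matched_rank[i] <- rank
        models[[i]] <- cat_tab$model_id[hit]
        break
      }
    }
  }
  out <- data.frame(asv_id = taxonomy$asv_id, matched_rank = matched_rank,
                    stringsAsFactors = FALSE)
  out$models <- models
  out
}

#' Build the reaction-expectation matrix E
#'
#' For each matched ASV j and reaction i, `E(i, j)` is the frequency of
#' occurrence of reaction i among the models matched to ASV j: the number of
#' matched models containing the reaction divided by the number of matched
#' models. Rows cover the union of reactions over all matched models;
#' unmatched ASVs are excluded.
#'
#' @param matches match table from [match_asv_to_models()].
#' @param catalog a `model_catalog`.
#' @return numeric matrix, reactions (rows) by mapped ASVs (columns), all
#'   values in \[0, 1\], each column with at least one positive entry.
#' @export
build_expectation_matrix <- function(matches, catalog) {
  stopifnot(inherits(catalog, "model_catalog"))
  mapped <- which(matches$matched_rank != "none")
  if (length(mapped) == 0L)
    abort_contract("no ASV could be mapped to any model at family rank or lower")
  rxn_sets <- lapply(catalog$models$reactions, unique)
  names(rxn_sets) <- catalog$models$model_id
  reaction_ids <- sort(unique(unlist(rxn_sets[unique(unlist(matches$models[mapped]))])))
  E <- matrix(0, nrow = length(reaction_ids), ncol = length(mapped),
              dimnames = list(reaction_ids, matches$asv_id[mapped]))
  for (k in seq_along(mapped)) {
    ids <- unique(matches$models[[mapped[k]]])
    counts <- table(unlist(rxn_sets[ids]))
    E[names(counts), k] <- as.numeric(counts) / length(ids)
  }
  E
}

#' Summarize an ASV-to-GSMM mapping
#'
#' Reports, per rank, how many ASVs matched and the mean number of models
#' per matched ASV, the total number of distinct reactions, and — when a
#' reaction-abundance matrix is supplied — reaction ubiquity: the fraction
#' of reactions present (abundance > 0) in every sample and the minimum
#' per-sample fraction of reactions present.
#'
#' @param matches match table from [match_asv_to_models()].
#' @param e_matrix expectation matrix from [build_expectation_matrix()], or
#'   NULL when nothing mapped.
#' @param abundance optional samples-by-reactions matrix from
#'   [compute_reaction_abundances()].
#' @return list with `n_asvs`, `n_mapped`, `per_rank` (data.frame: rank,
#'   n_asvs, mean_models), `n_reactions`, and (if abundance given)
#'   `frac_reactions_in_all_samples` and `min_sample_reaction_frac`.
#' @export
mapping_summary <- function(matches, e_matrix = NULL, abundance = NULL) {
  ranks <- c("species", "genus", "family")
  per_rank <- data.frame(
    rank = ranks,
    n_asvs = vapply(ranks, function(r) sum(matches$matched_rank == r), integer(1L)),
    mean_models = vapply(ranks, function(r) {
      sel <- matches$matched_rank == r
      if (!any(sel)) return(0)
      mean(lengths(matches$models[sel]))
    }, numeric(1L)),
    stringsAsFactors = FALSE
  )
  out <- list(
    n_asvs = nrow(matches),
    n_mapped = sum(matches$matched_rank != "none"),
    per_rank = per_rank,
    n_reactions = if (is.null(e_matrix)) 0L else nrow(e_matrix),
    empty = is.null(e_matrix) || nrow(e_matrix) == 0L
  )
  if (!is.null(abundance)) {
    present <- abundance > 0
    out$frac_reactions_in_all_samples <- mean(colSums(present) == nrow(abundance))
    out$min_sample_reaction_frac <- min(rowMeans(present))
  }
  out
}
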