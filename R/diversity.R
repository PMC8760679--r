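#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads to `depth` without replacement
#' (multivariate hypergeometric, via [vegan::rrarefy()]); samples whose
#' total is below the target depth are dropped with a warning. The usual
#' target is the minimum sample total, so that no sample is dropped.
#'
#' @param counts samples-by-ASVs count matrix.
#' @param depth target depth (reads per sample), > 0; `"min"` uses the
#'   minimum sample total.
#' @param seed integer seed; rarefaction is the one stochastic step of the
#'   downstream summaries and is reproducible given the seed.
#' @return samples-by-ASVs integer matrix; every row sums to `depth`.
#' @export
rarefy_counts <- function(counts, depth = "min", seed = 1L) {
  totals <- rowSums(counts)
  if (identical(depth, "min")) depth <- min(totals)
  if (!is.numeric(depth) || depth <= 0) abort_contract("depth must be > 0")
  depth <- as.integer(depth)
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(rownames(counts)[!keep], collapse = ", ")),
            call. = FALSE)
    counts <- counts[keep, , drop = FALSE]
  }
  if (nrow(counts) == 0L) abort_contract("no sample reaches the rarefaction depth")
  set.seed(as.integer(seed))
  # vegan advises when count tables lack singletons; synthetic tables often
  # do, so that advisory is muffled while real warnings pass through
  out <- withCallingHandlers(
    vegan::rrarefy(counts, sample = depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  storage.mode(out) <- "integer"
  out
}

#' Per-sample alpha diversity
#'
#' Computes, for each sample: observed ASVs (count of ASVs with count > 0),
#' Shannon's index H = -sum p log p (natural log, over present ASVs),
#' Pielou's evenness H / log(observed) (defined as 0 for single-ASV
#' samples), and — when a tree is supplied — Faith's phylogenetic
#' diversity, the total branch length of the minimal subtree connecting the
#' root and all present leaves.
#'
#' @param counts samples-by-ASVs count matrix.
#' @param tree optional rooted ape `phylo` covering every ASV observed in
#'   the table (required for Faith's PD).
#' @return data.frame, one row per sample: sample_id, observed, shannon,
#'   pielou, and faith_pd if a tree was given.
#' @export
alpha_diversity <- function(counts, tree = NULL) {
  observed <- rowSums(counts > 0)
  shannon <- vegan::diversity(counts, index = "shannon")
  pielou <- ifelse(observed > 1L, shannon / log(observed), 0)
  out <- data.frame(sample_id = rownames(counts),
                    observed = as.integer(observed),
                    shannon = as.numeric(shannon),
                    pielou = as.numeric(pielou),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    tree <- validate_tree(tree)
    present_asvs <- colnames(counts)[colSums(counts) > 0]
    missing <- setdiff(present_asvs, tree$tip.label)
    if (length(missing))
      abort_contract(sprintf("tree lacks leaves for observed ASVs: %s",
                             paste(head(missing, 10L), collapse = ", ")))
    m <- counts[, intersect(colnames(counts), tree$tip.label), drop = FALSE]
    pd <- picante::pd(m, tree, include.root = TRUE)
    out$faith_pd <- pd$PD[match(rownames(m), rownames(pd))]
    out$faith_pd[observed == 0L] <- 0
  }
  out
}
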