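#' Aggregate relative abundances by taxon
#'
#' Sums counts per taxon label and divides by the sample total. The label is
#' either a fixed rank ("phylum", "genus", ...) or, in `"lowest"` mode, the
#' deepest non-missing rank name of each ASV (the "genus or lowest taxonomy
#' level" convention of composition barplots). ASVs with no assignment at
#' the requested level are pooled under "Unclassified".
#'
#' @param counts samples-by-ASVs count matrix.
#' @param taxonomy taxonomy table covering the ASVs.
#' @param rank a rank name, or `"lowest"`.
#' @return numeric matrix, samples by taxa, rows summing to 1 (all-zero
#'   samples stay zero, with a warning).
#' @export
aggregate_relative_abundance <- function(counts, taxonomy, rank = "lowest") {
  if (!rank %in% c(TAXONOMIC_RANKS, "lowest"))
    abort_contract(sprintf("unknown rank '%s'", rank))
  tax <- taxonomy[match(colnames(counts), taxonomy$asv_id), , drop = FALSE]
  if (anyNA(tax$asv_id))
    abort_contract("taxonomy does not cover all ASVs in the count table")
  if (rank == "lowest") {
    m <- as.matrix(tax[TAXONOMIC_RANKS])
    labels <- apply(m, 1L, function(z) {
      nz <- which(!is.na(z))
      if (length(nz)) z[max(nz)] else NA_character_
    })
  } else {
    labels <- tax[[rank]]
  }
  labels[is.na(labels)] <- "Unclassified"
  agg <- t(rowsum(t(counts), group = labels))
  tot <- rowSums(agg)
  if (any(tot == 0))
    warning(sprintf("sample(s) with zero counts: %s",
                    paste(rownames(counts)[tot == 0], collapse = ", ")), call. = FALSE)
  tot[tot == 0] <- 1
  agg / tot
}

#' Top-N taxa by mean relative abundance
#'
#' @param aggregated samples-by-taxa relative abundance matrix from
#'   [aggregate_relative_abundance()].
#' @param n number of taxa to report; if larger than the number of taxa,
#'   all are returned.
#' @return list: `taxa` (data.frame taxon, mean_abundance, ranked; ties
#'   broken lexicographically) and `coverage` (summed mean abundance of the
#'   reported taxa).
#' @export
top_taxa <- function(aggregated, n) {
  if (n < 1L) abort_contract("n must be >= 1")
  means <- colMeans(aggregated)
  ord <- order(-means, names(means))
  n <- min(n, length(means))
  sel <- ord[seq_len(n)]
  list(taxa = data.frame(taxon = names(means)[sel],
                         mean_abundance = unname(means[sel]),
                         stringsAsFactors = FALSE),
       coverage = sum(means[sel]))
}

#' Core ASVs at a prevalence threshold
#'
#' An ASV is present in a sample if its relative abundance reaches
#' `min_rel_abundance` (with the default 0, presence means count > 0). It is
#' core if its prevalence — the percentage of the selected samples in which
#' it is present — is at least `prevalence_threshold`.
#'
#' @param counts samples-by-ASVs count matrix.
#' @param samples sample ids to use (default: all).
#' @param prevalence_threshold prevalence cutoff in percent, in (0, 100].
#' @param min_rel_abundance presence floor on relative abundance (e.g.
#'   0.0005 for 0.05%); 0 means any positive count.
#' @return list of class `core_set`: `core` (character vector of core ASV
#'   ids), `prevalence` (named percent prevalence for all ASVs),
#'   `threshold`, `n_samples`.
#' @export
core_asvs <- function(counts, samples = rownames(counts),
                      prevalence_threshold = 80, min_rel_abundance = 0) {
  if (prevalence_threshold <= 0 || prevalence_threshold > 100)
    abort_contract("prevalence_threshold must be in (0, 100]")
  if (min_rel_abundance < 0) abort_contract("min_rel_abundance must be >= 0")
  samples <- intersect(samples, rownames(counts))
  if (length(samples) == 0L) abort_contract("empty sample subset")
  sub <- counts[samples, , drop = FALSE]
  present <- presence_matrix(sub, min_rel_abundance)
  prevalence <- 100 * colMeans(present)
  structure(list(core = colnames(sub)[prevalence >= prevalence_threshold],
                 prevalence = prevalence,
                 threshold = prevalence_threshold,
                 n_samples = length(samples)),
            class = "core_set")
}

presence_matrix <- function(counts, min_rel_abundance) {
  if (min_rel_abundance == 0) return(counts > 0)
  tot <- rowSums(counts)
  tot[tot == 0] <- 1
  (counts / tot) >= min_rel_abundance
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core set: %d ASVs at >= %g%% prevalence over %d samples\n",
              length(x$core), x$threshold, x$n_samples))
  invisible(x)
}

#' Venn-style intersection counts of 2-4 sets
#'
#' @param sets named list of 2 to 4 character vectors (e.g. core ASV sets).
#' @return data.frame with one row per region: a logical membership column
#'   per set and `count` (exclusive region sizes; they sum to the union).
#' @export
set_intersections <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 4L)
    abort_contract("set_intersections handles 2 to 4 sets; report pairwise overlaps for more")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_len(k))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L, dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))
  colnames(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
  patterns$count <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(m) all(m == as.logical(p))))
  })
  rownames(patterns) <- NULL
  patterns
}

#' Shared ASVs between two disjoint sample groups
#'
#' An ASV is present in a group if it reaches `min_rel_abundance` relative
#' abundance in at least one sample of the group (the convention used to
#' compare sample types such as digesta vs feed; the default floor is
#' 0.05%). Reports the shared set and, per sample, the fraction of total
#' abundance carried by the shared ASVs.
#'
#' @param counts samples-by-ASVs count matrix.
#' @param samples_a,samples_b disjoint sample id vectors.
#' @param min_rel_abundance presence floor (default 0.0005 = 0.05%).
#' @return list: `shared` (ASV ids), `n_shared`, `present_a`, `present_b`
#'   (group presence sets), `abundance_fraction` (named per-sample fraction
#'   of abundance from shared ASVs, for samples of both groups).
#' @export
shared_asvs <- function(counts, samples_a, samples_b,
                        min_rel_abundance = 0.0005) {
  if (length(intersect(samples_a, samples_b)))
    abort_contract("sample groups overlap")
  missing <- setdiff(c(samples_a, samples_b), rownames(counts))
  if (length(missing))
    abort_contract(sprintf("samples not in table: %s", paste(missing, collapse = ", ")))
  present_in_group <- function(samples) {
    p <- presence_matrix(counts[samples, , drop = FALSE], min_rel_abundance)
    colnames(counts)[colSums(p) > 0L]
  }
  pa <- present_in_group(samples_a)
  pb <- present_in_group(samples_b)
  shared <- intersect(pa, pb)
  all_samples <- c(samples_a, samples_b)
  tot <- rowSums(counts[all_samples, , drop = FALSE])
  tot[tot == 0] <- 1
  frac <- rowSums(counts[all_samples, shared, drop = FALSE]) / tot
  list(shared = shared, n_shared = length(shared),
       present_a = pa, present_b = pb,
       abundance_fraction = frac)
}
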