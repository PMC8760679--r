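#' Taxonomic ranks used throughout the package
#'
#' The seven canonical ranks, from domain down to species.
#'
#' @export
TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family",
                     "genus", "species")

#' Normalize a taxon name for matching
#'
#' Reference databases and GSMM catalogs spell taxon names inconsistently
#' (underscores vs spaces, stray whitespace, case). All name comparisons in
#' the package go through this normalization: trim outer whitespace, collapse
#' underscores to single spaces, collapse repeated internal whitespace, and
#' casefold.
#'
#' @param x character vector of taxon names (NA allowed).
#' @return character vector of normalized names; `NA` and empty strings map
#'   to `NA`.
#' @examples
#' normalize_taxon_name(c("  Bacillus_subtilis ", "BACILLUS  subtilis"))
#' @export
normalize_taxon_name <- function(x) {
  x <- as.character(x)
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  x <- trimws(x)
  x <- tolower(x)
  x[!nzchar(x) | is.na(x) | x == "na"] <- NA_character_
  x
}

#' Construct a validated taxonomy table
#'
#' A taxonomy table has one row per ASV with the seven canonical rank
#' columns. Ranks must be hierarchically truncated: a missing rank forces all
#' lower ranks to be missing (a gap below an assigned rank is filled with
#' missing values, with a warning), because a name below a gap cannot be
#' placed in the hierarchy.
#'
#' @param asv_id character vector of unique ASV identifiers.
#' @param ... the seven rank vectors, or a data.frame/matrix with rank
#'   columns; missing ranks may be `NA` or `""`.
#' @return data.frame with columns `asv_id` and the seven ranks, missing
#'   ranks as `NA`.
#' @export
taxonomy_table <- function(asv_id, ...) {
  dots <- list(...)
  if (length(dots) == 1L && (is.data.frame(dots[[1L]]) || is.matrix(dots[[1L]]))) {
    ranks <- as.data.frame(dots[[1L]], stringsAsFactors = FALSE)
  } else {
    ranks <- as.data.frame(dots, stringsAsFactors = FALSE)
  }
  asv_id <- as.character(asv_id)
  if (anyDuplicated(asv_id))
    abort_format(sprintf("duplicate ASV identifiers in taxonomy: %s",
                         paste(unique(asv_id[duplicated(asv_id)]), collapse = ", ")))
  missing_ranks <- setdiff(TAXONOMIC_RANKS, names(ranks))
  for (r in missing_ranks) ranks[[r]] <- NA_character_
  ranks <- ranks[TAXONOMIC_RANKS]
  for (r in TAXONOMIC_RANKS) {
    v <- as.character(ranks[[r]])
    v[!nzchar(trimws(ifelse(is.na(v), "", v)))] <- NA_character_
    v[!is.na(v) & trimws(v) == "NA"] <- NA_character_
    ranks[[r]] <- ifelse(is.na(v), NA_character_, trimws(v))
  }
  ranks <- enforce_rank_truncation(ranks)
  out <- cbind(data.frame(asv_id = asv_id, stringsAsFactors = FALSE), ranks)
  rownames(out) <- NULL
  out
}

# A missing rank implies all lower ranks missing; names found below a gap are
# dropped (warn) since they cannot be anchored in the hierarchy.
enforce_rank_truncation <- function(ranks) {
  m <- as.matrix(ranks[TAXONOMIC_RANKS])
  gap <- t(apply(is.na(m), 1L, cumany_))
  dropped <- !is.na(m) & gap
  if (any(dropped)) {
    warning(sprintf(
      "taxonomy: %d rank assignment(s) below a missing rank were set to missing",
      sum(dropped)), call. = FALSE)
    m[dropped] <- NA_character_
  }
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- TAXONOMIC_RANKS
  out
}

cumany_ <- function(x) cumsum(x) > 0L

#' Lowest assigned rank of each taxonomy row
#'
#' @param taxonomy a taxonomy table (see [taxonomy_table()]).
#' @return character vector: one of the seven ranks, or `NA` for rows with
#'   no assignment at all.
#' @export
lowest_assigned_rank <- function(taxonomy) {
  m <- !is.na(as.matrix(taxonomy[TAXONOMIC_RANKS]))
  idx <- apply(m, 1L, function(z) if (any(z)) max(which(z)) else NA_integer_)
  TAXONOMIC_RANKS[idx]
}
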