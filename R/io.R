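#' Read an ASV count table
#'
#' Reads a tab-separated count table with ASVs as rows and samples as
#' columns (first column = ASV id, header = sample ids) and returns it in
#' the samples-by-ASVs orientation used throughout the package (the vegan
#' convention: rows are samples).
#'
#' @param path path to a TSV file.
#' @return integer matrix, samples (rows) by ASVs (columns), with dimnames.
#' @export
read_asv_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) abort_format("ASV table must have an id column and at least one sample")
  asv_ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]
  m <- as.matrix(df[-1L])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1L)))[1L]
    abort_format(sprintf("non-numeric counts in sample column '%s'", sample_ids[bad]))
  }
  counts <- t(m)
  dimnames(counts) <- list(sample_ids, asv_ids)
  validate_asv_table(counts)
}

#' Validate a samples-by-ASVs count matrix
#'
#' @param counts numeric matrix, samples (rows) by ASVs (columns).
#' @return the validated matrix, storage mode integer.
#' @export
validate_asv_table <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) < 1L || ncol(counts) < 1L)
    abort_format("count table needs at least one sample and one ASV")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_format("count table must carry sample and ASV identifiers as dimnames")
  if (anyDuplicated(rownames(counts)))
    abort_format(sprintf("duplicate sample identifiers: %s",
                         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", ")))
  if (anyDuplicated(colnames(counts)))
    abort_format(sprintf("duplicate ASV identifiers: %s",
                         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", ")))
  if (anyNA(counts)) abort_format("count table contains missing values")
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1L, ]
    abort_format(sprintf("negative count for ASV '%s' in sample '%s'",
                         colnames(counts)[idx[2L]], rownames(counts)[idx[1L]]))
  }
  if (any(counts != round(counts)))
    abort_format("count table contains non-integer values")
  storage.mode(counts) <- "integer"
  counts
}

#' Write an ASV count table
#'
#' Inverse of [read_asv_table()]: writes ASVs as rows, samples as columns.
#'
#' @param counts samples-by-ASVs integer matrix.
#' @param path output path.
#' @export
write_asv_table <- function(counts, path) {
  counts <- validate_asv_table(counts)
  df <- data.frame(asv_id = colnames(counts), t(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Accepts either a TSV with an ASV id column plus the seven rank columns,
#' or a two-column TSV whose second column is a semicolon-delimited lineage
#' string (`domain;phylum;class;order;family;genus;species`, trailing ranks
#' may be empty). Missing ranks (`NA` or empty) are stored as `NA`;
#' assignments below a gap are forced missing with a warning.
#'
#' @param path path to a TSV file.
#' @return taxonomy data.frame (see [taxonomy_table()]).
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "",
                   colClasses = "character", na.strings = c("NA", ""))
  if (ncol(df) == 2L) {
    lineages <- ifelse(is.na(df[[2L]]), "", df[[2L]])
    parts <- strsplit(lineages, ";", fixed = TRUE)
    nrank <- lengths(parts)
    if (any(nrank > 7L))
      abort_format(sprintf("malformed lineage with %d fields for ASV '%s' (max 7)",
                           max(nrank), df[[1L]][which.max(nrank)]))
    ranks <- t(vapply(parts, function(p) {
      p <- trimws(p)
      c(p, rep(NA_character_, 7L - length(p)))
    }, character(7L)))
    colnames(ranks) <- TAXONOMIC_RANKS
    taxonomy_table(df[[1L]], ranks)
  } else {
    rank_cols <- intersect(tolower(colnames(df)), TAXONOMIC_RANKS)
    if (length(rank_cols) == 0L)
      abort_format("taxonomy file has neither a lineage column nor rank columns")
    colnames(df) <- tolower(colnames(df))
    taxonomy_table(df[[1L]], df[rank_cols])
  }
}

#' Write a taxonomy table
#'
#' @param taxonomy taxonomy data.frame.
#' @param path output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `group` (diet label) and optionally
#' `sample_type` (digesta/feed/water; defaults to "digesta").
#'
#' @param path path to a TSV file.
#' @return data.frame with columns sample_id, group, sample_type.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "",
                   colClasses = "character")
  validate_sample_metadata(df)
}

#' Validate sample metadata
#'
#' @param metadata data.frame with at least sample_id and group columns.
#' @param counts optional samples-by-ASVs matrix; every sample in it must
#'   have a metadata row.
#' @return validated metadata data.frame.
#' @export
validate_sample_metadata <- function(metadata, counts = NULL) {
  if (!all(c("sample_id", "group") %in% colnames(metadata)))
    abort_format("metadata requires 'sample_id' and 'group' columns")
  if (anyDuplicated(metadata$sample_id))
    abort_format("duplicate sample_id in metadata")
  if (is.null(metadata$sample_type)) metadata$sample_type <- "digesta"
  if (!is.null(counts)) {
    missing <- setdiff(rownames(counts), metadata$sample_id)
    if (length(missing))
      abort_contract(sprintf("samples missing from metadata: %s",
                             paste(missing, collapse = ", ")))
  }
  metadata[c("sample_id", "group", "sample_type")]
}

#' Write sample metadata
#' @param metadata metadata data.frame.
#' @param path output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GSMM catalog
#'
#' The catalog is a JSON file with `models`, an array of objects
#' `{id, rank, name, reactions}`, and `subsystems`, an object mapping
#' reaction ids to one or more subsystem names. Reactions absent from the
#' subsystem map are assigned "Unassigned".
#'
#' @param path path to a JSON file.
#' @return a `model_catalog` object (see [model_catalog()]).
#' @export
read_model_catalog <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) abort_format(paste("unparseable catalog JSON:",
                                                         conditionMessage(e))))
  if (is.null(obj$models)) abort_format("catalog JSON lacks a 'models' array")
  models <- lapply(obj$models, function(m) {
    list(model_id = as.character(m$id), rank = as.character(m$rank),
         name = as.character(m$name),
         reactions = as.character(unlist(m$reactions)))
  })
  subsystems <- lapply(obj$subsystems, function(s) as.character(unlist(s)))
  model_catalog(models, subsystems)
}

#' Construct a validated GSMM catalog
#'
#' @param models list of lists with fields model_id, rank (one of species,
#'   genus, family), name, reactions (non-empty character vector).
#' @param subsystems named list mapping reaction id to character vector of
#'   subsystem names; reactions not covered get "Unassigned".
#' @return object of class `model_catalog`: list with `models` (data.frame
#'   with a `reactions` list-column and a normalized `name_norm` column) and
#'   `subsystems` (named list covering every catalog reaction).
#' @export
model_catalog <- function(models, subsystems = list()) {
  if (length(models) == 0L) abort_format("catalog has no models")
  ids <- vapply(models, `[[`, character(1L), "model_id")
  if (anyDuplicated(ids))
    abort_format(sprintf("duplicate model ids: %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  ranks <- vapply(models, `[[`, character(1L), "rank")
  bad <- !ranks %in% c("species", "genus", "family")
  if (any(bad))
    abort_format(sprintf("model rank must be species, genus or family; got '%s' for model '%s'",
                         ranks[bad][1L], ids[bad][1L]))
  rxns <- lapply(models, `[[`, "reactions")
  if (any(lengths(rxns) == 0L))
    abort_format(sprintf("model '%s' has an empty reaction set",
                         ids[lengths(rxns) == 0L][1L]))
  names_ <- vapply(models, `[[`, character(1L), "name")
  tab <- data.frame(model_id = ids, rank = ranks, name = names_,
                    name_norm = normalize_taxon_name(names_),
                    stringsAsFactors = FALSE)
  tab$reactions <- rxns
  all_rxns <- sort(unique(unlist(rxns)))
  subsystems <- subsystems[intersect(names(subsystems), all_rxns)]
  uncovered <- setdiff(all_rxns, names(subsystems))
  if (length(uncovered))
    subsystems[uncovered] <- list("Unassigned")
  structure(list(models = tab, subsystems = subsystems[all_rxns]),
            class = "model_catalog")
}

#' @export
print.model_catalog <- function(x, ...) {
  cat(sprintf("GSMM catalog: %d models (%s), %d reactions, %d subsystems\n",
              nrow(x$models),
              paste(sprintf("%d %s", table(x$models$rank), names(table(x$models$rank))),
                    collapse = ", "),
              length(x$subsystems),
              length(unique(unlist(x$subsystems)))))
  invisible(x)
}

#' Write a GSMM catalog as JSON
#' @param catalog a `model_catalog`.
#' @param path output path.
#' @export
write_model_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "model_catalog"))
  obj <- list(
    models = lapply(seq_len(nrow(catalog$models)), function(i) {
      list(id = catalog$models$model_id[i], rank = catalog$models$rank[i],
           name = catalog$models$name[i],
           reactions = catalog$models$reactions[[i]])
    }),
    subsystems = catalog$subsystems
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a rooted phylogenetic tree over ASVs
#'
#' Newick input via ape. Leaf labels must be unique; missing branch lengths
#' are set to 0 with a warning.
#'
#' @param path path to a Newick file.
#' @return an ape `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort_format(paste("unparseable Newick:",
                                                          conditionMessage(e))))
  if (is.null(tree)) abort_format("unparseable Newick file")
  validate_tree(tree)
}

#' Validate a phylogenetic tree
#' @param tree an ape `phylo` object.
#' @return the validated tree (missing branch lengths replaced by 0).
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort_format("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    abort_format(sprintf("duplicate leaf labels: %s",
                         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                               collapse = ", ")))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; setting all to 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    abort_format("negative branch lengths")
  tree
}

#' Write a tree in Newick format
#' @param tree an ape `phylo` object.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
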