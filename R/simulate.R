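#' Simulation configuration
#'
#' Defines the study conditions a synthetic dataset emulates: a feeding
#' trial with several dietary groups of digesta samples (13 per group, as
#' in the 16S workflows this package targets), a taxonomy of mixed
#' resolution, a GSMM catalog whose reaction content differs among taxa,
#' and Dirichlet-multinomial counts with an optional planted multiplicative
#' shift on chosen ASVs in one group.
#'
#' @param n_groups number of diet groups (default 6).
#' @param samples_per_group digesta samples per group (default 13).
#' @param n_asvs number of ASVs.
#' @param n_models number of GSMMs in the catalog.
#' @param n_reactions number of distinct reactions.
#' @param n_subsystems number of subsystems (pathways); must not exceed
#'   `n_reactions`.
#' @param resolution_fractions named numeric (species, genus, family,
#'   above) summing to 1: fraction of ASVs whose taxonomy is resolved to
#'   each level ("above" means above family, hence unmappable).
#' @param dirichlet_concentration concentration of the per-sample Dirichlet
#'   around the group mean proportions; larger = less overdispersion;
#'   `Inf` disables the Dirichlet layer (pure multinomial).
#' @param depth_mean,depth_dispersion negative-binomial mean and size for
#'   per-sample sequencing depth; `depth_dispersion = Inf` fixes the depth
#'   at `depth_mean`.
#' @param planted_shift NULL, or a list with `asvs` (ASV ids such as
#'   "ASV0007", or integer indices), `fold` (> 0, scalar or per-ASV), and
#'   `group` (index of the group receiving the shift, default 2).
#' @param shift_delta absolute expected reaction-abundance difference above
#'   which a reaction counts as truly shifted in the ground truth.
#' @param group_labels diet labels; defaults to the six-diet design
#'   (CD, IM, DFIM, DCIM, IO, EX), extended as G7, G8, ... if needed.
#' @param n_families,genera_per_family,species_per_genus shape of the
#'   generated taxon hierarchy (shared genera/families make the
#'   expectation matrix non-trivial).
#' @param feed_samples_per_group,n_water_samples extra non-digesta samples
#'   (sample_type "feed"/"water") for overlap analyses; default 0.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 6L, samples_per_group = 13L,
                       n_asvs = 150L, n_models = 120L, n_reactions = 200L,
                       n_subsystems = 20L,
                       resolution_fractions = c(species = 0.10, genus = 0.45,
                                                family = 0.30, above = 0.15),
                       dirichlet_concentration = 50,
                       depth_mean = 20000, depth_dispersion = 10,
                       planted_shift = NULL, shift_delta = 0.02,
                       group_labels = NULL,
                       n_families = 10L, genera_per_family = 3L,
                       species_per_genus = 3L,
                       feed_samples_per_group = 0L, n_water_samples = 0L) {
  cfg <- as.list(environment())
  for (f in c("n_groups", "samples_per_group", "n_asvs", "n_models",
              "n_reactions", "n_subsystems", "n_families",
              "genera_per_family", "species_per_genus"))
    if (cfg[[f]] < 1L) abort_contract(sprintf("%s must be positive", f))
  if (n_reactions < n_subsystems)
    abort_contract("n_reactions must be >= n_subsystems")
  if (abs(sum(resolution_fractions) - 1) > 1e-8 ||
      !all(c("species", "genus", "family", "above") %in% names(resolution_fractions)))
    abort_contract("resolution_fractions must name species/genus/family/above and sum to 1")
  if (!is.null(planted_shift)) {
    if (is.null(planted_shift$asvs) || is.null(planted_shift$fold))
      abort_contract("planted_shift needs 'asvs' and 'fold'")
    if (any(planted_shift$fold <= 0)) abort_contract("fold-change must be > 0")
    if (is.null(planted_shift$group)) cfg$planted_shift$group <- 2L
  }
  if (is.null(group_labels)) {
    base <- c("CD", "IM", "DFIM", "DCIM", "IO", "EX")
    cfg$group_labels <- if (n_groups <= 6L) base[seq_len(n_groups)]
                        else c(base, paste0("G", 7L:n_groups))
  } else if (length(group_labels) != n_groups) {
    abort_contract("group_labels must have one label per group")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic GSMM catalog
#'
#' Builds a taxon hierarchy (families > genera > species), assigns each
#' model a taxonomy label at species, genus, or family rank (so that
#' several models share a genus or family and the expectation matrix is
#' non-trivial), and samples each model's reaction set with
#' reaction-specific base prevalences modulated by a per-family effect —
#' reaction content therefore differs among taxa, and planted
#' compositional shifts induce known reaction-level shifts.
#'
#' @param config a `sim_config`.
#' @param seed integer seed; output is deterministic given the seed.
#' @return a `model_catalog` with attribute `hierarchy` (data.frame:
#'   family, genus, species) and `family_of_model` (character vector).
#' @export
generate_model_catalog <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  hier <- expand.grid(sp = seq_len(config$species_per_genus),
                      g = seq_len(config$genera_per_family),
                      f = seq_len(config$n_families))
  hier <- data.frame(
    family = sprintf("Family%02d", hier$f),
    genus = sprintf("Genus%02d%02d", hier$f, hier$g),
    species = sprintf("Genus%02d%02d sp%d", hier$f, hier$g, hier$sp),
    stringsAsFactors = FALSE
  )
  reactions <- sprintf("rxn%04d", seq_len(config$n_reactions))
  subsystem_names <- sprintf("Subsystem%02d", seq_len(config$n_subsystems))
  sub_of <- sample(rep_len(seq_len(config$n_subsystems), config$n_reactions))
  subsystems <- lapply(seq_len(config$n_reactions), function(i) {
    s <- subsystem_names[sub_of[i]]
    if (runif(1) < 0.1)  # some reactions belong to two pathways
      s <- unique(c(s, sample(subsystem_names, 1L)))
    s
  })
  names(subsystems) <- reactions

  base_prev <- runif(config$n_reactions, 0.05, 0.95)
  fam_effect <- matrix(rnorm(config$n_families * config$n_reactions, 0, 1.5),
                       nrow = config$n_families)
  rank_probs <- c(species = 0.35, genus = 0.40, family = 0.25)
  models <- vector("list", config$n_models)
  fam_of_model <- integer(config$n_models)
  for (m in seq_len(config$n_models)) {
    row <- hier[sample.int(nrow(hier), 1L), ]
    fam_idx <- as.integer(sub("Family", "", row$family))
    rank <- sample(names(rank_probs), 1L, prob = rank_probs)
    name <- switch(rank, species = row$species, genus = row$genus,
                   family = row$family)
    p <- stats::plogis(stats::qlogis(base_prev) + fam_effect[fam_idx, ])
    has <- runif(config$n_reactions) < p
    if (!any(has)) has[sample.int(config$n_reactions, 1L, prob = p)] <- TRUE
    models[[m]] <- list(model_id = sprintf("M%03d", m), rank = rank,
                        name = name, reactions = reactions[has])
    fam_of_model[m] <- fam_idx
  }
  catalog <- model_catalog(models, subsystems)
  attr(catalog, "hierarchy") <- hier
  attr(catalog, "family_of_model") <- sprintf("Family%02d", fam_of_model)
  catalog
}

#' Generate a synthetic grouped community
#'
#' Draws per-group mean ASV proportions, applies the planted shift to the
#' configured group, and samples per-sample counts as
#' multinomial(depth, p) with p Dirichlet-distributed around the group
#' mean (two-layer noise emulating overdispersed amplicon data). The
#' taxonomy assigns each ASV a lineage from the catalog's hierarchy,
#' truncated to the configured resolution level; the tree is a random
#' coalescent over the ASVs. The returned ground truth carries the true
#' mean proportions, the true expectation matrix (computed by an
#' exhaustive per-rank scan independent of the pipeline's matcher), the
#' expected per-group reaction abundances, and the set of truly shifted
#' reactions.
#'
#' @param config a `sim_config`.
#' @param catalog a `model_catalog` from [generate_model_catalog()].
#' @param seed integer seed.
#' @return list with `counts` (samples x ASVs), `taxonomy`, `metadata`,
#'   `tree` (ape phylo), `truth` (see [ground_truth_reaction_means()]).
#' @export
generate_community <- function(config, catalog, seed = 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(catalog, "model_catalog"))
  set.seed(as.integer(seed))
  n <- config$n_asvs
  asv_ids <- sprintf("ASV%04d", seq_len(n))

  hier <- attr(catalog, "hierarchy")
  if (is.null(hier))
    abort_contract("catalog lacks a taxon hierarchy; use generate_model_catalog()")
  res_levels <- sample(rep(names(config$resolution_fractions),
                           diff(c(0, round(cumsum(config$resolution_fractions) * n)))))
  res_levels <- rep_len(res_levels, n)
  lineage <- hier[sample.int(nrow(hier), n, replace = TRUE), ]
  fam_idx <- as.integer(sub("Family", "", lineage$family))
  taxonomy <- taxonomy_table(
    asv_ids,
    domain = rep("Bacteria", n),
    phylum = sprintf("Phylum%02d", (fam_idx - 1L) %/% 4L + 1L),
    class = sprintf("Class%02d", (fam_idx - 1L) %/% 2L + 1L),
    order = sprintf("Order%02d", fam_idx),
    family = ifelse(res_levels == "above", NA_character_, lineage$family),
    genus = ifelse(res_levels %in% c("above", "family"), NA_character_, lineage$genus),
    species = ifelse(res_levels == "species", lineage$species, NA_character_)
  )

  # group mean proportions: lognormal baseline, planted fold-change in one group
  baseline <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  baseline <- baseline / sum(baseline)
  group_means <- matrix(rep(baseline, each = config$n_groups),
                        nrow = config$n_groups,
                        dimnames = list(config$group_labels, asv_ids))
  if (!is.null(config$planted_shift)) {
    ps <- config$planted_shift
    idx <- if (is.character(ps$asvs)) match(ps$asvs, asv_ids) else as.integer(ps$asvs)
    if (anyNA(idx) || any(idx < 1L | idx > n))
      abort_contract("planted ASV not present in the simulated table")
    g <- ps$group
    group_means[g, idx] <- group_means[g, idx] * ps$fold
    group_means[g, ] <- group_means[g, ] / sum(group_means[g, ])
  }

  sample_one <- function(mean_prop) {
    depth <- if (is.infinite(config$depth_dispersion)) config$depth_mean
             else max(1L, rnbinom(1L, size = config$depth_dispersion,
                                  mu = config$depth_mean))
    p <- if (is.infinite(config$dirichlet_concentration)) mean_prop
         else {
           gam <- rgamma(length(mean_prop),
                         shape = config$dirichlet_concentration * mean_prop)
           if (sum(gam) == 0) mean_prop else gam / sum(gam)
         }
    as.integer(rmultinom(1L, size = depth, prob = p))
  }

  rows <- list(); meta <- list()
  for (g in seq_len(config$n_groups)) {
    for (s in seq_len(config$samples_per_group)) {
      id <- sprintf("%s_%02d", config$group_labels[g], s)
      rows[[id]] <- sample_one(group_means[g, ])
      meta[[id]] <- c(config$group_labels[g], "digesta")
    }
    if (config$feed_samples_per_group > 0L) {
      # feed resembles its diet's community mixed with an independent profile
      feed_extra <- stats::rlnorm(n, 0, 1); feed_extra <- feed_extra / sum(feed_extra)
      feed_mean <- 0.6 * group_means[g, ] + 0.4 * feed_extra
      for (s in seq_len(config$feed_samples_per_group)) {
        id <- sprintf("%s_feed_%02d", config$group_labels[g], s)
        rows[[id]] <- sample_one(feed_mean)
        meta[[id]] <- c(config$group_labels[g], "feed")
      }
    }
  }
  if (config$n_water_samples > 0L) {
    water_mean <- stats::rlnorm(n, 0, 1); water_mean <- water_mean / sum(water_mean)
    for (s in seq_len(config$n_water_samples)) {
      id <- sprintf("water_%02d", s)
      rows[[id]] <- sample_one(water_mean)
      meta[[id]] <- c("water", "water")
    }
  }
  counts <- do.call(rbind, rows)
  dimnames(counts) <- list(names(rows), asv_ids)
  metadata <- data.frame(sample_id = names(meta),
                         group = vapply(meta, `[`, character(1L), 1L),
                         sample_type = vapply(meta, `[`, character(1L), 2L),
                         row.names = NULL, stringsAsFactors = FALSE)

  tree <- ape::rcoal(n, tip.label = sample(asv_ids))

  truth <- list(group_means = group_means,
                e_matrix = gt_expectation_matrix(taxonomy, catalog),
                delta = config$shift_delta)
  truth$expected_a_r <- ground_truth_reaction_means(truth)
  truth$shifted_reactions <- gt_shifted_reactions(truth$expected_a_r,
                                                  config$shift_delta)
  list(counts = validate_asv_table(counts), taxonomy = taxonomy,
       metadata = metadata, tree = tree, truth = truth)
}
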