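#' Null-simulation false discovery study
#'
#' Repeatedly simulates a community with no planted shift under the default
#' study design (six diet groups of 13 digesta samples), runs the full
#' reaction pipeline (mapping, reaction abundances, pairwise t-tests with
#' BH correction), and records, per replicate and diet pair, the false
#' discovery proportion V / max(R, 1). Under the null every discovery is
#' false, so the mean proportion estimates the achieved FDR of the BH-0.05
#' reaction calls.
#'
#' @param n_replicates number of simulation replicates.
#' @param config a `sim_config`; must have no planted shift.
#' @param seed integer seed driving the whole study (catalog and every
#'   replicate derive their seeds from it).
#' @param alpha BH significance level.
#' @return list: `mean_fdr`, `fdp` (replicate x pair matrix of false
#'   discovery proportions), `n_reactions_tested` (mean), `n_replicates`.
#' @export
null_fdr_study <- function(n_replicates = 200L, config = sim_config(),
                           seed = 1L, alpha = 0.05) {
  if (!is.null(config$planted_shift))
    abort_contract("null study requires a config without planted shift")
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates + 1L)
  catalog <- generate_model_catalog(config, seed = rep_seeds[1L])
  fdp <- NULL
  n_tested <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- generate_community(config, catalog, seed = rep_seeds[r + 1L])
    E <- build_expectation_matrix(match_asv_to_models(sim$taxonomy, catalog),
                                  catalog)
    A <- compute_reaction_abundances(sim$counts, E)
    pw <- pairwise_all(A, sim$metadata, alpha = alpha)
    row <- vapply(pw, function(x) {
      R <- sum(x$differential$significant)
      R / max(R, 1)  # V = R under the null
    }, numeric(1L))
    fdp <- rbind(fdp, row)
    n_tested[r] <- mean(vapply(pw, function(x) sum(x$differential$tested),
                               numeric(1L)))
  }
  rownames(fdp) <- sprintf("rep%03d", seq_len(n_replicates))
  list(mean_fdr = mean(fdp), fdp = fdp,
       n_reactions_tested = mean(n_tested), n_replicates = n_replicates)
}

#' Planted-shift recovery study
#'
#' Simulates two diet groups of 13 digesta samples at a fixed sequencing
#' depth, plants a multiplicative fold-change on a few ASVs in the second
#' group, and asks how well the reaction-level pipeline recovers the
#' reactions whose ground-truth expected abundance difference is at least
#' `min_effect`: sensitivity (fraction of such reactions called significant)
#' and sign agreement (fraction of detected ones whose observed mean
#' difference has the expected sign).
#'
#' @param n_replicates number of simulation replicates.
#' @param n_planted number of ASVs receiving the shift (the first
#'   `n_planted` ASV ids).
#' @param fold multiplicative fold-change planted in group 2.
#' @param depth fixed sequencing depth per sample.
#' @param min_effect ground-truth |expected a_r difference| defining the
#'   recoverable set.
#' @param config base `sim_config` for the two-group design; its
#'   planted-shift, depth and group-count fields are set by this function.
#' @param seed integer seed.
#' @param alpha BH significance level.
#' @return list: `sensitivity`, `sign_agreement`, `n_recoverable` (total
#'   (replicate, reaction) cases), `n_detected`, `n_replicates`.
#' @export
recovery_study <- function(n_replicates = 100L, n_planted = 3L, fold = 10,
                           depth = 50000, min_effect = 0.05,
                           config = sim_config(), seed = 1L, alpha = 0.05) {
  cfg <- sim_config(
    n_groups = 2L, samples_per_group = config$samples_per_group,
    n_asvs = config$n_asvs, n_models = config$n_models,
    n_reactions = config$n_reactions, n_subsystems = config$n_subsystems,
    resolution_fractions = config$resolution_fractions,
    dirichlet_concentration = config$dirichlet_concentration,
    depth_mean = depth, depth_dispersion = Inf,
    planted_shift = list(asvs = sprintf("ASV%04d", seq_len(n_planted)),
                         fold = fold, group = 2L),
    shift_delta = config$shift_delta,
    n_families = config$n_families,
    genera_per_family = config$genera_per_family,
    species_per_genus = config$species_per_genus)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates + 1L)
  catalog <- generate_model_catalog(cfg, seed = rep_seeds[1L])
  pair <- cfg$group_labels[1:2]
  n_recoverable <- 0L; n_detected <- 0L; n_sign_ok <- 0L
  for (r in seq_len(n_replicates)) {
    sim <- generate_community(cfg, catalog, seed = rep_seeds[r + 1L])
    exp_diff <- sim$truth$expected_a_r[pair[1L], ] -
      sim$truth$expected_a_r[pair[2L], ]
    strong <- names(exp_diff)[abs(exp_diff) >= min_effect]
    if (length(strong) == 0L) next
    E <- build_expectation_matrix(match_asv_to_models(sim$taxonomy, catalog),
                                  catalog)
    A <- compute_reaction_abundances(sim$counts, E)
    d <- differential_reactions(A, sim$metadata, pair, alpha = alpha)
    d <- d[match(strong, d$reaction), ]
    hit <- !is.na(d$significant) & d$significant
    n_recoverable <- n_recoverable + length(strong)
    n_detected <- n_detected + sum(hit)
    n_sign_ok <- n_sign_ok + sum(sign(d$diff[hit]) == sign(exp_diff[strong][hit]))
  }
  list(sensitivity = if (n_recoverable) n_detected / n_recoverable else NA_real_,
       sign_agreement = if (n_detected) n_sign_ok / n_detected else NA_real_,
       n_recoverable = n_recoverable, n_detected = n_detected,
       n_replicates = n_replicates)
}
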