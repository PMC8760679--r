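# Small in-code fixtures shared across test files.

make_counts <- function(m, samples = NULL, asvs = NULL) {
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(nrow(m)))
  if (is.null(asvs)) asvs <- sprintf("ASV%d", seq_len(ncol(m)))
  dimnames(m) <- list(samples, asvs)
  storage.mode(m) <- "integer"
  m
}

# catalog of hand-picked models for mapping tests
tiny_catalog <- function() {
  model_catalog(
    list(
      list(model_id = "M1", rank = "species", name = "Lactobacillus salivarius",
           reactions = c("r1", "r2")),
      list(model_id = "M2", rank = "genus", name = "Lactobacillus",
           reactions = c("r1", "r3")),
      list(model_id = "M3", rank = "genus", name = "Lactobacillus",
           reactions = c("r2", "r3")),
      list(model_id = "M4", rank = "family", name = "Lactobacillaceae",
           reactions = c("r3", "r4")),
      list(model_id = "M5", rank = "family", name = "Bacillaceae",
           reactions = c("r4"))
    ),
    subsystems = list(r1 = "S1", r2 = "S1", r3 = "S2", r4 = "S2")
  )
}

# random instance for oracle-equivalence sweeps: a count table plus a
# random expectation matrix over a mapped subset of the ASVs
random_instance <- function(max_asvs = 50, max_reactions = 100,
                            max_samples = 20) {
  n_asv <- sample(2:max_asvs, 1)
  n_rxn <- sample(1:max_reactions, 1)
  n_smp <- sample(2:max_samples, 1)
  counts <- make_counts(matrix(rpois(n_smp * n_asv, 50) + 1L, n_smp, n_asv))
  n_mapped <- sample(1:n_asv, 1)
  E <- matrix(runif(n_rxn * n_mapped), n_rxn, n_mapped,
              dimnames = list(sprintf("r%d", seq_len(n_rxn)),
                              colnames(counts)[sort(sample(n_asv, n_mapped))]))
  list(counts = counts, E = E)
}
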