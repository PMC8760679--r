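fixture_taxonomy <- function() {
  suppressWarnings(taxonomy_table(
    sprintf("a%d", 1:4),
    domain = "Bacteria", phylum = "Firmicutes", class = "Bacilli",
    order = "Lactobacillales",
    family = c("Lactobacillaceae", "Lactobacillaceae", "Enterococcaceae", "Streptococcaceae"),
    genus = c("Lactobacillus", "Lactobacillus", "Enterococcus", NA),
    species = NA
  ))
}

test_that("relative abundances aggregate by rank and by lowest assigned label", {
  counts <- make_counts(matrix(c(2L, 3L, 4L, 1L), 1, 4), asvs = sprintf("a%d", 1:4))
  tax <- fixture_taxonomy()
  agg <- aggregate_relative_abundance(counts, tax, rank = "genus")
  expect_equal(agg[1, "Lactobacillus"], 0.5)
  expect_equal(sum(agg[1, ]), 1)
  low <- aggregate_relative_abundance(counts, tax, rank = "lowest")
  # a4 is resolved only to family, so it is labelled by the family name
  expect_true("Streptococcaceae" %in% colnames(low))
  expect_equal(low[1, "Streptococcaceae"], 0.1)
  expect_equal(sum(low[1, ]), 1)
  phy <- aggregate_relative_abundance(counts, tax, rank = "phylum")
  expect_equal(unname(phy[1, "Firmicutes"]), 1)
})

test_that("empty samples aggregate to zero rows with a warning", {
  counts <- make_counts(matrix(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L), 2, 4, byrow = TRUE),
                        asvs = sprintf("a%d", 1:4))
  expect_warning(agg <- aggregate_relative_abundance(counts, fixture_taxonomy(),
                                                     rank = "genus"),
                 "zero counts")
  expect_equal(sum(agg[1, ]), 0)
  expect_equal(sum(agg[2, ]), 1)
})

test_that("top taxa are ranked by mean abundance with deterministic ties", {
  agg <- matrix(c(0.5, 0.3, 0.2), 1, 3,
                dimnames = list("s1", c("x", "z", "y")))
  tt <- top_taxa(agg, 2)
  expect_identical(tt$taxa$taxon, c("x", "z"))
  expect_equal(tt$coverage, 0.8)
  expect_equal(top_taxa(agg, 10)$coverage, 1)
  tie <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("s1", c("b", "a")))
  expect_identical(top_taxa(tie, 1)$taxa$taxon, "a")
})

test_that("core ASVs follow the prevalence rule at the threshold boundary", {
  counts <- make_counts(rbind(c(1L, 1L), c(1L, 0L), c(1L, 1L),
                              c(1L, 1L), c(1L, 1L)))
  cs <- core_asvs(counts, prevalence_threshold = 80)
  # present in 4 of 5 samples = 80% prevalence -> core under >= convention
  expect_setequal(cs$core, c("ASV1", "ASV2"))
  cs100 <- core_asvs(counts, prevalence_threshold = 100)
  expect_identical(cs100$core, "ASV1")
  expect_error(core_asvs(counts, samples = character(0)),
               class = "reactcap_contract_error")
})

test_that("presence uses counts by default and an abundance floor when set", {
  counts <- make_counts(rbind(c(1L, 9999L), c(1L, 9999L)))
  expect_setequal(core_asvs(counts, prevalence_threshold = 100)$core,
                  c("ASV1", "ASV2"))
  floored <- core_asvs(counts, prevalence_threshold = 100,
                       min_rel_abundance = 0.001)
  expect_identical(floored$core, "ASV2")
})

test_that("core sets shrink weakly as the threshold rises", {
  set.seed(21)
  counts <- make_counts(matrix(rbinom(20 * 30, 1, 0.6) * rpois(600, 20), 20, 30))
  sizes <- vapply(c(20, 50, 80, 100), function(th)
    length(core_asvs(counts, prevalence_threshold = th)$core), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("set intersections cover every region and sum to the union", {
  r <- set_intersections(list(g1 = c("A", "B"), g2 = c("B", "C")))
  expect_equal(sum(r$count), 3)
  expect_equal(r$count[r$g1 & r$g2], 1)
  expect_equal(r$count[r$g1 & !r$g2], 1)
  same <- set_intersections(list(a = c("X", "Y"), b = c("X", "Y")))
  expect_equal(same$count[same$a & same$b], 2)
  expect_equal(sum(same$count), 2)
  disj <- set_intersections(list(a = "X", b = "Y", c = "Z"))
  expect_equal(sum(disj$count[rowSums(disj[, 1:3]) > 1]), 0)
  expect_error(set_intersections(rep(list(c("A")), 5)),
               class = "reactcap_contract_error")
})

test_that("shared ASVs respect the 0.05% presence floor", {
  # ASV2 sits at 0.04% in every sample: below the floor, absent
  counts <- make_counts(rbind(c(9996L, 4L), c(9996L, 4L)),
                        samples = c("gut1", "feed1"))
  r <- shared_asvs(counts, "gut1", "feed1", min_rel_abundance = 0.0005)
  expect_identical(r$shared, "ASV1")
  expect_false("ASV2" %in% r$present_a)
})

test_that("shared-ASV counts and abundance fractions match hand counts", {
  # 5 ASVs; ASV1 and ASV2 common to both sample groups
  counts <- make_counts(rbind(
    c(50L, 30L, 20L, 0L, 0L),
    c(40L, 40L, 20L, 0L, 0L),
    c(30L, 30L, 0L, 20L, 20L),
    c(25L, 25L, 0L, 25L, 25L)
  ), samples = c("g1", "g2", "f1", "f2"))
  r <- shared_asvs(counts, c("g1", "g2"), c("f1", "f2"))
  expect_equal(r$n_shared, 2)
  expect_setequal(r$shared, c("ASV1", "ASV2"))
  expect_equal(unname(r$abundance_fraction["g1"]), 0.8)
  expect_equal(unname(r$abundance_fraction["f2"]), 0.5)
  ident <- shared_asvs(counts[c(1, 2), ], "g1", "g2")
  expect_equal(unname(ident$abundance_fraction), rep(1, 2))
  expect_error(shared_asvs(counts, c("g1", "g2"), c("g2", "f1")),
               class = "reactcap_contract_error")
})

test_that("rarefaction subsamples every kept sample to exactly the depth", {
  set.seed(31)
  counts <- make_counts(matrix(rpois(5 * 40, 60), 5, 40))
  depth <- min(rowSums(counts))
  r <- rarefy_counts(counts, depth = "min", seed = 9)
  expect_true(all(rowSums(r) == depth))
  expect_true(all(r <= counts))
  # a sample already at the target depth is unchanged
  one <- counts[1, , drop = FALSE]
  expect_identical(rarefy_counts(one, depth = sum(one), seed = 1), one)
  # determinism
  expect_identical(rarefy_counts(counts, depth, seed = 9),
                   rarefy_counts(counts, depth, seed = 9))
  expect_warning(rarefy_counts(counts, depth = max(rowSums(counts)), seed = 1),
                 "dropping")
  expect_error(rarefy_counts(counts, depth = 0), class = "reactcap_contract_error")
})

test_that("rarefaction is unbiased for relative abundances", {
  counts <- make_counts(matrix(c(600L, 300L, 100L), 1, 3))
  reps <- 400
  acc <- matrix(0, reps, 3)
  for (i in seq_len(reps))
    acc[i, ] <- rarefy_counts(counts, depth = 100, seed = i)[1, ] / 100
  target <- c(0.6, 0.3, 0.1)
  mc_se <- apply(acc, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(acc) - target) <= 3 * mc_se + 1e-9))
})

test_that("alpha diversity reproduces closed forms", {
  counts <- make_counts(rbind(c(5L, 5L, 5L, 5L, 0L), c(9L, 0L, 0L, 0L, 0L)),
                        asvs = c("A", "B", "C", "D", "E"))
  ad <- alpha_diversity(counts)
  expect_equal(ad$observed, c(4L, 1L))
  expect_equal(ad$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(ad$pielou[1], 1, tolerance = 1e-12)
  expect_equal(ad$shannon[2], 0)
  expect_equal(ad$pielou[2], 0)
})

test_that("Shannon is maximal at uniformity for fixed richness", {
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(2:12, 1)
    comp <- as.integer(rmultinom(1, 5000, prob = runif(k)))
    comp[comp == 0] <- 1L
    counts <- make_counts(matrix(comp, 1, k))
    expect_lte(alpha_diversity(counts)$shannon, log(k) + 1e-12)
  }
})

test_that("Faith's PD sums the branches of the spanned subtree", {
  # PD needs a rooted tree; resolve the star's basal polytomy with
  # zero-length internal edges, which leaves all branch sums unchanged
  star <- validate_tree(ape::multi2di(
    ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);"), random = FALSE))
  counts <- make_counts(matrix(c(1L, 2L, 3L, 0L, 0L), 1, 5),
                        asvs = c("A", "B", "C", "D", "E"))
  ad <- alpha_diversity(counts, star)
  expect_equal(ad$faith_pd, 3)
  # all leaves present -> total branch length
  full <- make_counts(matrix(1L, 1, 5), asvs = c("A", "B", "C", "D", "E"))
  expect_equal(alpha_diversity(full, star)$faith_pd, sum(star$edge.length))
  # adding a present ASV never decreases PD
  more <- make_counts(matrix(c(1L, 2L, 3L, 4L, 0L), 1, 5),
                      asvs = c("A", "B", "C", "D", "E"))
  expect_gte(alpha_diversity(more, star)$faith_pd, ad$faith_pd)
  # tree must cover observed ASVs
  bad <- make_counts(matrix(1L, 1, 2), asvs = c("A", "ZZ"))
  expect_error(alpha_diversity(bad, star), class = "reactcap_contract_error")
})
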