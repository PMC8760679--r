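#!/usr/bin/env Rscript
# Step 5 — community summaries: composition, core microbiota, gut-feed and
# gut-water overlap, rarefaction, and alpha diversity.

suppressMessages(library(reactcap))

sim_dir <- "results/sim"
out <- "results/community"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_asv_table(file.path(sim_dir, "asv_counts.tsv"))
taxonomy <- read_taxonomy(file.path(sim_dir, "taxonomy.tsv"))
metadata <- read_sample_metadata(file.path(sim_dir, "metadata.tsv"))
tree <- read_tree(file.path(sim_dir, "tree.nwk"))

digesta <- metadata$sample_id[metadata$sample_type == "digesta"]
feed <- metadata$sample_id[metadata$sample_type == "feed"]
water <- metadata$sample_id[metadata$sample_type == "water"]

## composition: top taxa at phylum and at the lowest assigned level
for (mode in c("phylum", "lowest")) {
  agg <- aggregate_relative_abundance(counts[digesta, ], taxonomy, rank = mode)
  tt <- top_taxa(agg, if (mode == "phylum") 10L else 15L)
  write.table(tt$taxa, file.path(out, sprintf("top_taxa_%s.tsv", mode)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("top %d taxa at %s level cover %.0f%% of abundance\n",
              nrow(tt$taxa), mode, 100 * tt$coverage))
}

## core microbiota at 80% prevalence, overall and per diet
core_all <- core_asvs(counts, digesta, prevalence_threshold = 80)
print(core_all)
diets <- unique(metadata$group[metadata$sample_type == "digesta"])
per_diet <- lapply(diets, function(d)
  core_asvs(counts, metadata$sample_id[metadata$group == d &
                                         metadata$sample_type == "digesta"],
            prevalence_threshold = 80)$core)
names(per_diet) <- diets
venn <- set_intersections(per_diet[1:4])
write.table(venn, file.path(out, "core_intersections.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(core_all$core, file.path(out, "core_asvs.txt"))

## gut-feed and gut-water overlap at the 0.05% presence floor
for (pairing in list(c("feed", "gut_feed"), c("water", "gut_water"))) {
  other <- if (pairing[1] == "feed") feed else water
  ov <- shared_asvs(counts, digesta, other, min_rel_abundance = 0.0005)
  cat(sprintf("%s: %d shared ASVs; mean shared-abundance fraction %.2f\n",
              pairing[2], ov$n_shared, mean(ov$abundance_fraction)))
  write.table(data.frame(sample_id = names(ov$abundance_fraction),
                         shared_fraction = ov$abundance_fraction),
              file.path(out, sprintf("overlap_%s.tsv", pairing[2])),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

## rarefaction to the minimum sample depth, then alpha diversity
rarefied <- rarefy_counts(counts[digesta, ], depth = "min", seed = 20240105L)
cat(sprintf("rarefied %d digesta samples to %d reads\n",
            nrow(rarefied), sum(rarefied[1, ])))
alpha <- alpha_diversity(rarefied, tree)
alpha$group <- metadata$group[match(alpha$sample_id, metadata$sample_id)]
write.table(alpha, file.path(out, "alpha_diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
agg_means <- aggregate(alpha[c("observed", "shannon", "pielou", "faith_pd")],
                       by = alpha["group"], FUN = mean)
print(agg_means, digits = 3)
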