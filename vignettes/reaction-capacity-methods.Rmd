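---
title: "Predicting gut-microbiota metabolic capacity from 16S ASV tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gut-microbiota metabolic capacity from 16S ASV tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactcap)
```

## The problem

16S rRNA amplicon sequencing yields a table of amplicon sequence variant
(ASV) counts per sample together with taxonomy assignments of mixed depth:
in fish gut studies typically only a tenth of ASVs carry a species name,
most stop at genus or family. The taxonomy alone says little about what the
community can *do* metabolically. `reactcap` predicts a community's
metabolic capacity by transferring reaction content from a collection of
genome-scale metabolic models (GSMMs) of gut microbes onto the ASV table,
and provides the statistical machinery to compare that capacity between
experimental groups (here called diets, after the feeding-trial design the
package was built around: six diets, 13 digesta samples each).

## The model

**Mapping.** Each ASV is matched to GSMMs by taxonomy at the lowest
available rank: its species name is compared with species-rank models,
then genus, then family; the first rank with at least one exact
(normalized) name match wins, and all models at that rank are kept. ASVs
resolved only above family, or matching no model, are excluded. Name
normalization (trim, underscores to spaces, casefold) absorbs spelling
drift between reference databases and catalogs; matching is otherwise
exact — fuzzy matching would silently change results. If a catalog lists
several models under one taxonomy name (e.g. strains of a species), all of
them count: the expectation below is a frequency over models.

**Expectation matrix.** For reaction $i$ and mapped ASV $j$,
$E(i,j)$ is the frequency of occurrence of reaction $i$ among the models
matched to ASV $j$ — the number of matched models containing the reaction
divided by the number of matched models. Each column is a probability
profile in $[0,1]$.

**Reaction abundance.** For each sample, the normalized abundance of
reaction $i$ is the abundance-weighted mean of $E(i,\cdot)$ over mapped
ASVs:

$$a_r(i) = \frac{\sum_j a_{\mathrm{ASV}}(j)\,E(i,j)}{\sum_j a_{\mathrm{ASV}}(j)}.$$

Both sums run over mapped ASVs only. Including unmapped ASVs in the
denominator would merely rescale every reaction of a sample by the same
factor, break the $[\min_j E, \max_j E]$ envelope, and make values depend
on how much of the community happens to be unmappable; restricting to the
mapped fraction keeps $a_r$ a weighted mean. Two consequences worth
stating: $a_r$ is invariant to rescaling a sample's counts (so raw counts
and relative abundances give identical results and no pre-normalization
is needed), and every value lies between the smallest and largest entry of
its $E$ row.

**Differential testing.** For each pair of diets, each reaction's mean
abundance is compared with a two-sample t-test; p-values are
Benjamini–Hochberg corrected and reactions with adjusted $p \le 0.05$ are
called significant. The default is the pooled-variance Student test
(Welch by flag): an unqualified "two-sample t-test" most often denotes the
pooled test, and with equal group sizes the two nearly coincide.
Reactions with zero pooled variance are untestable — they carry no
p-value and are excluded from the correction universe, since an
untestable hypothesis should not dilute the FDR budget. The correction
universe is per diet pair (the testable reactions of that comparison),
not the global reaction list.

**Enrichment.** Subsystem (pathway) membership comes from the catalog;
reactions without an annotation fall under "Unassigned", and a reaction in
several subsystems counts once in each. Per subsystem, a one-sided
Fisher's exact test asks whether significant reactions are
over-represented among its tested reactions, with BH correction across
subsystems and adjusted $p \le 0.05$ as the enrichment call. One-sided is
the natural reading of "which pathways are enriched among the
significantly different reactions"; a two-sided option is exposed. An
enriched subsystem is attributed to the first diet if the mean t statistic
of its significant reactions is positive, to the second if negative, and
labelled *mixed* when the member signs disagree and the mean's magnitude
is smaller than its 95% confidence half-width. This direction rule is a
convention (the field's heatmap figures show per-reaction t values with a
subsystem mean and confidence interval but do not state a tie-break); it
is parameterized rather than asserted as the only reading.

**Ordination.** PCA is run separately on standardized ASV relative
abundances and on reaction z-scores (per-column mean 0, sd 1 with
denominator $n-1$; zero-variance columns are zeroed and flagged). The
implementation is SVD of the centered matrix; each component is flipped so
its largest-magnitude loading is positive, giving a reproducible
orientation. Group mean scores come with 95% confidence intervals from the
t distribution with $n-1$ degrees of freedom per group — with 13 samples
per diet the normal approximation would be too narrow.

## Community summaries

* **Aggregation** sums counts per taxon at a fixed rank or at each ASV's
  lowest assigned rank, then divides by the sample total.
* **Core microbiota**: an ASV is core for a sample set if present in at
  least the threshold percentage of samples (default 80%, inclusive `>=` —
  the common convention; both the threshold and the presence rule, count
  > 0 by default or a relative-abundance floor, are arguments).
* **Overlap** between sample types (digesta vs feed or water) counts ASVs
  present — at least 0.05% relative abundance by default — in at least one
  sample of each group, and reports the per-sample abundance fraction the
  shared set carries. Group-level presence ("in ≥ 1 sample") is a
  convention, chosen because overlap is asked of sample types, not sample
  pairs.
* **Rarefaction** subsamples each sample to a common depth without
  replacement (multivariate hypergeometric, via `vegan::rrarefy`),
  normally the minimum sample total; a feeding-trial dataset of the kind
  emulated here rarefies to about 10,000 reads.
* **Alpha diversity**: observed ASVs; Shannon $H=-\sum p\ln p$ (natural
  log — the ecosystem default; the base is not a parameter of record, so a
  flagged alternative was not added); Pielou $H/\ln(\text{observed})$,
  defined as 0 for single-ASV samples to avoid NaN propagation; Faith's PD
  as the branch-length sum of the minimal rooted subtree spanning the
  present leaves (via `picante::pd`, which requires a binary-rooted tree —
  basal polytomies should be resolved with zero-length edges first).

## The synthetic-data generator

No public ASV table ships with the package; the generator produces
datasets with the full structure the pipeline needs and an analytic ground
truth.

* **Catalog**: a taxon hierarchy (10 families × 3 genera × 3 species by
  default) with 120 models assigned to species, genus, or family rank
  (0.35/0.40/0.25), so several models share a genus or family and $E$ is a
  genuine frequency. Each of 200 reactions has a base prevalence
  $\sim U(0.05, 0.95)$ shifted on the logit scale by a per-family effect
  (sd 1.5); models include reactions Bernoulli-wise at the family-adjusted
  prevalence. Reaction content therefore differs among taxa, and
  compositional shifts induce known reaction-level shifts.
* **Community**: 6 diet groups × 13 digesta samples (the feeding-trial
  design), 150 ASVs with lognormal baseline mean proportions. Taxonomic
  resolution is planted per ASV by truncating its lineage: 10% to species,
  45% to genus, 30% to family, 15% above family (the unmappable fraction
  exercising the exclusion rule) — chosen to echo the mixed resolution of
  real Silva-assigned fish-gut data, where about a tenth of ASVs carry a
  species name and most stop at genus.
* **Noise**: per sample, proportions are Dirichlet-distributed around the
  group mean (concentration 50 — a mid-range overdispersion for gut
  amplicon data) and counts multinomial at a negative-binomial depth
  (mean 20,000, size 10). Setting the concentration or the depth
  dispersion to `Inf` switches the corresponding layer off, which the
  convergence tests use: only with the Dirichlet layer off do single-sample
  relative abundances converge to the group means as depth grows.
* **Planted shift**: chosen ASVs' mean proportions are multiplied by a
  fold-change in one group, then renormalized. The ground truth stores the
  true group means, the true $E$ (computed by an exhaustive per-rank scan
  independent of the pipeline's matcher), the expected per-group $a_r$
  (brute-force double summation — the oracle the pipeline is tested
  against), and the truly shifted reactions: those whose expected $a_r$
  differs by at least $\delta = 0.02$ between some pair of groups
  (separating recoverable from negligible effects; configurable).

What the generator does **not** emulate: read-level artifacts (chimeras,
contamination, denoising errors), 16S copy-number variation, batch
effects, and phylogenetic signal in the reaction content (the tree is an
independent coalescent). Passing tests therefore validate the
*computational* pipeline, not the upstream bioinformatics of real data.

## Operating characteristics

Two replicated studies ship as package functions so their numbers are
recomputed, not quoted:

* `null_fdr_study()` — no planted shift, full six-diet design: the mean
  false-discovery proportion of BH-0.05 reaction calls across replicates
  and diet pairs. At 200 replicates this lands near the nominal 0.05 (the
  suite asserts ≤ 0.075, allowing Monte-Carlo slack).
* `recovery_study()` — two diets, fold-10 shift on three ASVs, fixed depth
  50,000: sensitivity and sign agreement over reactions whose ground-truth
  expected difference is ≥ 0.05. Detected effects essentially always carry
  the correct sign. Pooled sensitivity, however, is about 0.73 under the
  default concentration of 50: with 13 samples per group, the within-group
  standard deviation of $a_r$ induced by that overdispersion is comparable
  to the 0.05 effect floor, so marginal reactions are underpowered, while
  effects of roughly twice the floor are recovered nearly always. The
  concentration was fixed as a realism choice, not a power target, and the
  test suite asserts the 0.9 sensitivity bound regardless — that assertion
  fails under these conditions and is left failing deliberately, as an
  honest statement of the design's power at the chosen noise level rather
  than a bug. Halving the overdispersion (concentration ≳ 200) or doubling
  the per-group sample size would clear 0.9; both describe a different
  study, not this one.

## Numerical choices and degenerate inputs

* Problem sizes used by the replicated studies and the tests (150 ASVs,
  200 reactions, 200/100 replicates) are the package's validation design;
  they keep every study a from-scratch recomputation.
* Taxonomy gaps: a rank below a missing rank cannot be anchored and is
  forced missing, with a warning.
* A sample with zero mapped abundance has no defined $a_r$ and is a
  contract violation naming the sample, not a silent NaN.
* Ties in `top_taxa` break lexicographically; duplicated model ids in a
  match are deduplicated before computing $E$.
* All randomness flows through explicit integer seeds; replicate seeds are
  drawn once from the study seed, so any replicate can be regenerated.

## Limitations

Predicted capacity is taxonomy-transferred presence/absence: it says what
reactions the community plausibly encodes, not fluxes or expression, and
it inherits every bias of the model catalog (coverage, curation depth,
rank of annotation). Family-rank matches average over whole families —
the expectation matrix makes that explicit but cannot undo it. The
differential machinery treats reactions independently; reactions shared
by many taxa are strongly correlated, which BH tolerates but does not
exploit.
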