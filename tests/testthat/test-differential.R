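test_that("pooled t-test matches closed form and the reference implementation", {
  # closed form: pooled variance 5/3, df 6 -> t = -2/sqrt(5/6) = -2.1909
  r <- two_sample_t(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(r$t, -2.19089, tolerance = 1e-5)
  expect_equal(r$p, 0.070988, tolerance = 1e-4)
  expect_equal(r$df, 6)
  o <- oracle_pooled_t(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(r$t, o$t, tolerance = 1e-12)
  expect_equal(r$p, o$p, tolerance = 1e-12)
  ref <- t.test(c(1, 2, 3, 4), c(3, 4, 5, 6), var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
})

test_that("degenerate t-test inputs are handled per contract", {
  r <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r0 <- two_sample_t(c(0, 0, 0), c(1, 1, 1))
  expect_false(r0$tested)
  expect_true(is.na(r0$p))
  expect_error(two_sample_t(1, c(1, 2)), class = "reactcap_contract_error")
})

test_that("vectorized t agrees with t.test on random data, pooled and Welch", {
  set.seed(5)
  for (var_equal in c(TRUE, FALSE)) {
    for (rep in 1:20) {
      a <- rnorm(sample(3:15, 1)); b <- rnorm(sample(3:15, 1), sd = runif(1, 0.5, 2))
      r <- two_sample_t(a, b, var_equal = var_equal)
      ref <- t.test(a, b, var.equal = var_equal)
      expect_equal(r$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(r$p, ref$p.value, tolerance = 1e-10)
      expect_equal(r$df, unname(ref$parameter), tolerance = 1e-8)
    }
  }
})

test_that("Benjamini-Hochberg matches the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.1, 1.2)),
               class = "reactcap_contract_error")
  set.seed(8)
  for (rep in 1:100) {
    p <- runif(sample(1:50, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("differential table flags untestable reactions and respects labels", {
  set.seed(1)
  A <- cbind(matrix(rnorm(12, 0.5, 0.05), 6, 2), 0.3)
  dimnames(A) <- list(sprintf("s%d", 1:6), c("r1", "r2", "r_const"))
  md <- data.frame(sample_id = rownames(A), group = rep(c("CD", "IM"), each = 3))
  d <- differential_reactions(A, md, c("CD", "IM"))
  expect_false(d$tested[d$reaction == "r_const"])
  expect_true(is.na(d$p_adj[d$reaction == "r_const"]))
  expect_true(all(d$p_adj[d$tested] >= d$p[d$tested] - 1e-15))
  expect_true(all(d$significant[!d$tested] == FALSE))
  expect_error(differential_reactions(A, md, c("CD", "XX")),
               class = "reactcap_contract_error")
})

test_that("swapping diet labels negates t and differences, p unchanged", {
  set.seed(2)
  A <- matrix(rnorm(26 * 10, 0.5, 0.1), 26, 10,
              dimnames = list(sprintf("s%d", 1:26), sprintf("r%d", 1:10)))
  md <- data.frame(sample_id = rownames(A), group = rep(c("CD", "IM"), each = 13))
  d12 <- differential_reactions(A, md, c("CD", "IM"))
  d21 <- differential_reactions(A, md, c("IM", "CD"))
  expect_equal(d12$t, -d21$t)
  expect_equal(d12$diff, -d21$diff)
  expect_equal(d12$p, d21$p)
  expect_equal(d12$significant, d21$significant)
})

test_that("results do not depend on sample row order", {
  set.seed(4)
  A <- matrix(rnorm(12 * 6, 0.5, 0.1), 12, 6,
              dimnames = list(sprintf("s%d", 1:12), sprintf("r%d", 1:6)))
  md <- data.frame(sample_id = rownames(A), group = rep(c("CD", "IM"), 6))
  d1 <- differential_reactions(A, md, c("CD", "IM"))
  perm <- sample(nrow(A))
  d2 <- differential_reactions(A[perm, ], md, c("CD", "IM"))
  expect_equal(d1, d2)
})

test_that("one-sided Fisher enrichment p matches the hypergeometric tail sum", {
  # worked 2x2 table: 3 significant all inside a 3-reaction subsystem,
  # 3 non-significant all outside -> point mass 1/C(6,3) = 0.05
  expect_equal(oracle_fisher_greater(3, 0, 0, 3), 0.05)
  ft <- fisher.test(matrix(c(3, 0, 0, 3), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(ft$p.value, 0.05, tolerance = 1e-12)

  # all 2x2 tables with margins <= 12 (exhaustive within test budget;
  # the acceptance suite sweeps margins <= 30)
  for (n1 in 1:12) for (n2 in 1:12) {
    for (a in 0:n1) for (c_ in 0:n2) {
      p_pkg <- fisher.test(matrix(c(a, n1 - a, c_, n2 - c_), 2, byrow = TRUE),
                           alternative = "greater")$p.value
      expect_equal(p_pkg, oracle_fisher_greater(a, n1 - a, c_, n2 - c_),
                   tolerance = 1e-12)
    }
  }
})

test_that("pathway enrichment builds correct tables and directions", {
  # 6 tested reactions, r1-r3 significant with positive t, all in SubA
  d <- data.frame(
    diet1 = "CD", diet2 = "IM",
    reaction = sprintf("r%d", 1:6),
    mean1 = 0.5, mean2 = 0.4, diff = 0.1,
    t = c(5, 6, 4, 0.5, -0.2, 0.1),
    p = c(0.001, 0.001, 0.002, 0.6, 0.8, 0.9),
    p_adj = c(0.004, 0.004, 0.004, 0.7, 0.9, 0.9),
    significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    tested = TRUE, stringsAsFactors = FALSE
  )
  cat_ <- model_catalog(
    list(list(model_id = "M1", rank = "genus", name = "G",
              reactions = sprintf("r%d", 1:6))),
    subsystems = list(r1 = "SubA", r2 = "SubA", r3 = "SubA",
                      r4 = "SubB", r5 = "SubB", r6 = "SubB")
  )
  e <- pathway_enrichment(d, cat_)
  rowA <- e[e$subsystem == "SubA", ]
  expect_equal(rowA$n_sig_in, 3)
  expect_equal(rowA$n_nonsig_out, 3)
  expect_equal(rowA$n_sig_in + rowA$n_sig_out + rowA$n_nonsig_in +
                 rowA$n_nonsig_out, 6)
  expect_equal(rowA$p, 0.05, tolerance = 1e-12)
  expect_identical(rowA$direction, "diet1")
  expect_true(all(e$p_adj >= e$p - 1e-15))
  # enriched implies at least one significant member
  expect_true(all(e$n_sig_in[e$enriched] >= 1))

  # no significant reactions -> no enriched subsystem
  d0 <- d; d0$significant <- FALSE; d0$p_adj <- 0.9
  e0 <- pathway_enrichment(d0, cat_)
  expect_false(any(e0$enriched))
})

test_that("mixed-sign subsystems are labelled mixed when the mean t is weak", {
  d <- data.frame(
    diet1 = "CD", diet2 = "IM", reaction = sprintf("r%d", 1:4),
    mean1 = 0.5, mean2 = 0.4, diff = 0.1,
    t = c(3, -3.1, 2.9, -2.8), p = 0.01, p_adj = 0.02,
    significant = TRUE, tested = TRUE, stringsAsFactors = FALSE
  )
  cat_ <- model_catalog(
    list(list(model_id = "M1", rank = "genus", name = "G",
              reactions = sprintf("r%d", 1:4))),
    subsystems = list(r1 = "SubA", r2 = "SubA", r3 = "SubA", r4 = "SubA")
  )
  e <- pathway_enrichment(d, cat_)
  expect_identical(e$direction[e$subsystem == "SubA"], "mixed")
})

test_that("pairwise comparisons enumerate all unordered diet pairs", {
  set.seed(6)
  groups <- c("CD", "IM", "DFIM", "DCIM", "IO", "EX")
  A <- matrix(rnorm(18 * 4, 0.5, 0.1), 18, 4,
              dimnames = list(sprintf("s%d", 1:18), sprintf("r%d", 1:4)))
  md <- data.frame(sample_id = rownames(A), group = rep(groups, each = 3))
  pw <- pairwise_all(A, md)
  expect_length(pw, 15)
  expect_identical(names(pw)[1], "CD vs IM")
  md2 <- md[md$group %in% c("CD", "IM"), ]
  pw2 <- pairwise_all(A[md2$sample_id, ], md2)
  expect_length(pw2, 1)
})

test_that("the direction matrix encodes enrichment per pair", {
  set.seed(10)
  # plant a strong reaction-level difference confined to one subsystem
  A <- matrix(rnorm(26 * 20, 0.5, 0.02), 26, 20,
              dimnames = list(sprintf("s%d", 1:26), sprintf("r%02d", 1:20)))
  A[14:26, 1:5] <- A[14:26, 1:5] - 0.2
  md <- data.frame(sample_id = rownames(A), group = rep(c("CD", "IM"), each = 13))
  subs <- as.list(c(rep("Lifted", 5), rep("Background", 15)))
  names(subs) <- sprintf("r%02d", 1:20)
  cat_ <- model_catalog(
    list(list(model_id = "M1", rank = "genus", name = "G",
              reactions = sprintf("r%02d", 1:20))),
    subsystems = subs
  )
  pw <- pairwise_all(A, md, catalog = cat_)
  M <- enrichment_direction_matrix(pw)
  expect_identical(M["Lifted", "CD vs IM"], 1L)
})
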