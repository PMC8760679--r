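# Independent oracles, kept deliberately naive: plain loops and textbook
# definitions, no shared code with the package internals they check.

# weighted-mean reaction abundance by double summation
oracle_reaction_abundance <- function(counts, E) {
  samples <- rownames(counts)
  reactions <- rownames(E)
  mapped <- colnames(E)
  A <- matrix(NA_real_, length(samples), length(reactions),
              dimnames = list(samples, reactions))
  for (s in samples) {
    den <- 0
    for (j in mapped) den <- den + counts[s, j]
    for (i in reactions) {
      num <- 0
      for (j in mapped) num <- num + counts[s, j] * E[i, j]
      A[s, i] <- num / den
    }
  }
  A
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (k in (m - 1):1) if (m > 1) q[k] <- min(q[k], q[k + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# one-sided (over-representation) Fisher p as a hypergeometric tail sum:
# table rows = (significant, non-significant), cols = (in, out)
oracle_fisher_greater <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  K <- a + b        # significant
  m <- a + c_       # in subsystem
  kk <- a:min(K, m)
  sum(choose(m, kk) * choose(n - m, K - kk)) / choose(n, K)
}

# exhaustive per-rank scan matcher
oracle_match <- function(taxonomy_row, catalog) {
  for (rank in c("species", "genus", "family")) {
    nm <- normalize_taxon_name(taxonomy_row[[rank]])
    if (is.na(nm)) next
    hits <- character(0)
    for (m in seq_len(nrow(catalog$models))) {
      if (catalog$models$rank[m] == rank &&
          catalog$models$name_norm[m] == nm)
        hits <- c(hits, catalog$models$model_id[m])
    }
    if (length(hits)) return(list(rank = rank, models = hits))
  }
  list(rank = "none", models = character(0))
}

# pooled-variance two-sided t from the closed form
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}
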