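# Independent oracles used across test files. Each is a deliberately
# different code path from the package implementation it checks.

# Exact hypergeometric probability of a 2x2 table with fixed margins,
# via choose() arithmetic only.
oracle_table_prob <- function(a, r1, r2, c1) {
  choose(r1, a) * choose(r2, c1 - a) / choose(r1 + r2, c1)
}

# Fisher exact p by exhaustive enumeration over all tables with the
# observed margins.
oracle_fisher <- function(tab, alternative) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, oracle_table_prob, 0, r1 = r1, r2 = r2, c1 = c1)
  names(probs) <- lo:hi
  p_obs <- probs[as.character(a)]
  switch(alternative,
         greater = sum(probs[as.integer(names(probs)) >= a]),
         less = sum(probs[as.integer(names(probs)) <= a]),
         two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Pearson chi-squared via the 2x2 closed form.
oracle_chi2_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Ward minimum-variance agglomeration via the Lance-Williams update on
# squared Euclidean distances; returns the merge partitions after each step.
oracle_ward_partitions <- function(points) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))^2
  diag(d) <- Inf
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  partitions <- list()
  for (step in seq_len(n - 1)) {
    dd <- d
    dd[!active, ] <- Inf; dd[, !active] <- Inf
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    for (k in seq_len(n)) {
      if (!active[k] || k %in% c(i, j)) next
      d[i, k] <- d[k, i] <-
        ((sizes[i] + sizes[k]) * d[i, k] + (sizes[j] + sizes[k]) * d[j, k] -
           sizes[k] * d[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    part <- integer(n)
    for (ci in which(active)) part[members[[ci]]] <- ci
    partitions[[step]] <- part
  }
  partitions
}

# Two-group log-rank statistic by explicit per-event hypergeometric
# summation.
oracle_logrank <- function(times, events, group) {
  group <- as.integer(factor(group))
  ev_times <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & group == 1)
    d_j <- sum(times == t & events == 1)
    d1_j <- sum(times == t & events == 1 & group == 1)
    o_minus_e <- o_minus_e + d1_j - d_j * n1_j / n_j
    if (n_j > 1) {
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  o_minus_e^2 / v
}

# Weighted KS enrichment score by a full running sum over all positions
# (different code path from the package's hit-indexed version).
oracle_gsea_es <- function(stats_sorted, hit_idx) {
  n <- length(stats_sorted)
  hit <- seq_len(n) %in% hit_idx
  nr <- sum(abs(stats_sorted[hit]))
  steps <- ifelse(hit, abs(stats_sorted) / nr, -1 / (n - sum(hit)))
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

# Average ranks computed from first principles (no rank()).
oracle_ranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, 0)
}

# Spearman rho as the Pearson correlation of hand-rolled ranks.
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small cohort configuration for replicate-heavy tests; study-scale tests
# use cohort_config() defaults directly.
small_cohort_config <- function(seed, ...) {
  cohort_config(seed = seed, n_genes = 600L, genes_per_signature = 10L, ...)
}

# Adjusted Rand index between two label vectors.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Convenience: score a cohort and assign subtypes with the synthetic
# signature conventions.
subtype_cohort <- function(cohort, k = 3L) {
  sc <- score_signatures(zscore_matrix(cohort$expr), cohort$signatures)
  assign_immune_subtypes(sc, synthetic_tcell_signatures(),
                         cd8_signature = "Activated_CD8_T_cells", k = k)
}
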