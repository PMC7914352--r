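#' Two-group differential expression behind stringent filters
#'
#' Per gene: log2 fold-change `log2((mean_A + 1) / (mean_B + 1))` on the
#' normalized counts, a pluggable two-group test on log2(x+1) (two-sided
#' Wilcoxon rank-sum by default, Welch t as alternative), Benjamini-Hochberg
#' FDR across all genes, and a pass flag combining the quadruple filter:
#' raw p below `p_max`, FDR below `fdr_max`, absolute log2 fold-change of at
#' least `min_abs_lfc` (i.e. a minimum fold-change of 2 by default) and a
#' minimum average normalized count of `min_mean` across all samples.
#'
#' @param expr A counts-platform `ExpressionMatrix`.
#' @param group_labels Vector of two group labels, one per sample (named or
#'   in column order). Group A is the first level encountered.
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @param p_max,fdr_max,min_abs_lfc,min_mean Filter thresholds.
#' @return Data frame with columns `gene`, `log2_fc`, `mean_expr`,
#'   `p_value`, `fdr`, `pass`. Group A is reported in attribute
#'   `"group_a"`.
#' @export
differential_expression <- function(expr, group_labels,
                                    test = c("wilcoxon", "welch"),
                                    p_max = 0.01, fdr_max = 0.01,
                                    min_abs_lfc = 1, min_mean = 20) {
  test <- match.arg(test)
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$platform != "counts") {
    stop("differential expression expects normalized counts", call. = FALSE)
  }
  m <- expr$values
  if (!is.null(names(group_labels))) {
    group_labels <- group_labels[colnames(m)]
  }
  if (length(group_labels) != ncol(m)) {
    stop("one group label per sample is required", call. = FALSE)
  }
  groups <- factor(group_labels)
  if (nlevels(groups) != 2L) stop("exactly two groups are required", call. = FALSE)
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples", call. = FALSE)
  a <- groups == levels(groups)[1]
  lg <- log2(m + 1)
  mean_a <- rowMeans(m[, a, drop = FALSE])
  mean_b <- rowMeans(m[, !a, drop = FALSE])
  lfc <- log2((mean_a + 1) / (mean_b + 1))
  pvals <- apply(lg, 1L, function(x) {
    if (test == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(x[a], x[!a])$p.value)
    } else {
      stats::t.test(x[a], x[!a])$p.value
    }
  })
  fdr <- stats::p.adjust(pvals, method = "BH")
  mean_expr <- rowMeans(m)
  out <- data.frame(gene = rownames(m), log2_fc = lfc, mean_expr = mean_expr,
                    p_value = pvals, fdr = fdr,
                    pass = pvals < p_max & fdr < fdr_max &
                      abs(lfc) >= min_abs_lfc & mean_expr >= min_mean,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "group_a") <- levels(groups)[1]
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a query gene list against each gene set
#' within a universe: p = P(X >= overlap) with population = universe,
#' successes = set intersected with the universe, draws = query. Sets whose
#' overlap with the query falls below `min_overlap` are excluded before
#' testing; Benjamini-Hochberg adjustment runs over the tested sets only.
#'
#' @param query_genes Character vector of query genes (must lie in the
#'   universe).
#' @param sets A `SignatureCollection`.
#' @param universe Character vector of background genes.
#' @param min_overlap Minimum query genes in a set for the set to be tested
#'   (a per-collection knob: e.g. 5 for curated pathway collections, 3 for
#'   ontology terms).
#' @param fdr_max Significance threshold on the adjusted p-value.
#' @return Data frame with columns `set`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `fdr`, `significant`.
#' @export
ora_hypergeometric <- function(query_genes, sets, universe, min_overlap = 3L,
                               fdr_max = 0.05) {
  stopifnot(inherits(sets, "SignatureCollection"))
  universe <- unique(toupper(universe))
  query <- unique(toupper(query_genes))
  if (!length(universe) || !length(query)) {
    stop("query and universe must be non-empty", call. = FALSE)
  }
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(sets), function(s) {
    set_u <- intersect(sets[[s]], universe)
    ov <- length(intersect(set_u, query))
    if (ov < min_overlap) return(NULL)
    K <- length(set_u)
    p <- stats::phyper(ov - 1L, K, N - K, n_q, lower.tail = FALSE)
    data.frame(set = s, overlap = ov, set_size = K, query_size = n_q,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      fdr = numeric(), significant = logical()))
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr < fdr_max
  out[order(out$p_value), , drop = FALSE]
}

# Weighted Kolmogorov-Smirnov enrichment score (weight exponent 1 on |score|)
# for one set, given the ranking statistics sorted in decreasing order and
# the positions of the set members in that order. Returns the maximum
# deviation of the running sum from zero (signed).
gsea_es <- function(stats_sorted, hit_idx) {
  n <- length(stats_sorted)
  k <- length(hit_idx)
  hit_idx <- sort(hit_idx)
  w <- abs(stats_sorted[hit_idx])
  nr <- sum(w)
  if (nr == 0) return(0)
  if (k == n) return(1)          # degenerate: the set covers every gene
  miss_step <- 1 / (n - k)
  hit_cum <- cumsum(w) / nr
  # running sum just after each hit, and just before each hit
  after <- hit_cum - (hit_idx - seq_len(k)) * miss_step
  before <- c(0, hit_cum[-k]) - (hit_idx - 1 - (seq_len(k) - 1)) * miss_step
  top <- max(after)
  bottom <- min(before)
  if (top > -bottom) top else bottom
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment (weight exponent 1 on
#' the absolute ranking score). The null distribution per set comes from
#' random gene-label permutations: `n_perm` random sets of the same size, or
#' all `choose(n, k)` sets exhaustively when that count does not exceed
#' `n_perm`. The empirical p-value uses a +1 pseudo-count within the nulls
#' of matching sign, NES = ES divided by the mean |ES| of same-sign nulls,
#' and Benjamini-Hochberg adjustment runs jointly across all supplied sets
#' (sets must be scored together with their whole collection, not in
#' isolation).
#'
#' @param ranked_scores Named numeric vector: gene-level ranking statistic.
#' @param sets A `SignatureCollection`.
#' @param n_perm Number of permutations (>= 100; smaller nulls are unstable).
#' @param seed Integer seed for the permutation stream (mandatory).
#' @param min_size Sets with fewer than this many ranked genes are dropped.
#' @param fdr_max Significance threshold on the adjusted p-value.
#' @return Data frame with columns `set`, `size`, `es`, `nes`, `p_value`,
#'   `fdr`, `significant`, `n_perm`.
#' @export
gsea_preranked <- function(ranked_scores, sets, n_perm = 1000L, seed,
                           min_size = 3L, fdr_max = 0.05) {
  stopifnot(inherits(sets, "SignatureCollection"))
  if (missing(seed)) stop("`seed` is required for the permutation null", call. = FALSE)
  if (n_perm < 100L) stop("`n_perm` must be >= 100 (unstable null below)", call. = FALSE)
  if (length(ranked_scores) < 2L || is.null(names(ranked_scores))) {
    stop("`ranked_scores` must be a named vector of >= 2 genes", call. = FALSE)
  }
  ord <- order(ranked_scores, decreasing = TRUE)
  s_sorted <- ranked_scores[ord]
  genes_sorted <- toupper(names(s_sorted))
  n <- length(s_sorted)
  sizes <- vapply(sets, function(g) length(intersect(g, genes_sorted)), 1L)
  keep <- names(sets)[sizes >= min_size]
  if (!length(keep)) {
    stop("no set with >= ", min_size, " ranked genes", call. = FALSE)
  }
  with_seed(seed, {
    res <- lapply(keep, function(s) {
      hit <- which(genes_sorted %in% sets[[s]])
      k <- length(hit)
      es <- gsea_es(s_sorted, hit)
      nulls <- if (choose(n, k) <= n_perm) {
        combs <- utils::combn(n, k)
        apply(combs, 2L, function(idx) gsea_es(s_sorted, idx))
      } else {
        vapply(seq_len(n_perm), function(i) {
          gsea_es(s_sorted, sample.int(n, k))
        }, 0)
      }
      same <- if (es >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      data.frame(set = s, size = k, es = es, nes = nes, p_value = p,
                 n_perm = length(nulls), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$fdr <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$fdr < fdr_max
    out[order(out$p_value), c("set", "size", "es", "nes", "p_value", "fdr",
                              "significant", "n_perm")]
  })
}
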