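#' Per-pair Spearman correlation of ligand and receptor expression
#'
#' For counts data the Spearman correlation of the ligand and receptor gene
#' rows across samples. For probe-level intensity data (probe map required)
#' the "probe-max" rule is applied: the maximum Spearman correlation over
#' every (ligand probe, receptor probe) combination, with the achieving
#' probe pair reported. Pairs with either gene absent from the matrix are
#' reported with `rho = NA` (missing, never zero).
#'
#' @param expr An `ExpressionMatrix` (>= 5 samples).
#' @param db An `LRDatabase`.
#' @return Data frame with columns `ligand`, `receptor`, `rho`,
#'   `ligand_probe`, `receptor_probe` (probes are `NA` on the counts
#'   platform), `background`.
#' @export
pair_correlation <- function(expr, db) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(db, "LRDatabase"))
  if (ncol(expr$values) < 5L) {
    stop("rank correlations need >= 5 samples", call. = FALSE)
  }
  if (expr$platform == "intensity" && is.null(expr$probe_map)) {
    stop("intensity platform requires a probe map", call. = FALSE)
  }
  ranked <- apply(expr$values, 1L, rank)      # samples x features, average ranks
  probes_of <- if (!is.null(expr$probe_map)) {
    split(expr$probe_map$probe, expr$probe_map$gene)
  } else {
    stats::setNames(as.list(rownames(expr$values)), rownames(expr$values))
  }
  res <- lapply(seq_len(nrow(db)), function(i) {
    lp <- probes_of[[db$ligand[i]]]
    rp <- probes_of[[db$receptor[i]]]
    if (is.null(lp) || is.null(rp)) {
      return(data.frame(ligand = db$ligand[i], receptor = db$receptor[i],
                        rho = NA_real_, ligand_probe = NA_character_,
                        receptor_probe = NA_character_, stringsAsFactors = FALSE))
    }
    cors <- suppressWarnings(stats::cor(ranked[, lp, drop = FALSE],
                                        ranked[, rp, drop = FALSE]))
    if (all(is.na(cors))) {
      best <- c(NA_integer_, NA_integer_); rho <- NA_real_
    } else {
      best <- which(cors == max(cors, na.rm = TRUE), arr.ind = TRUE)[1, ]
      rho <- cors[best[1], best[2]]
    }
    data.frame(ligand = db$ligand[i], receptor = db$receptor[i], rho = rho,
               ligand_probe = if (is.na(best[1])) NA_character_ else lp[best[1]],
               receptor_probe = if (is.na(best[2])) NA_character_ else rp[best[2]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$background <- db$background
  out
}

#' Select confident pairs by correlation threshold
#'
#' Pairs whose Spearman correlation reaches `tau` (closed threshold: a rho
#' exactly at `tau` is included). Missing correlations never qualify.
#'
#' @param rhos Data frame from [pair_correlation()].
#' @param tau Correlation threshold in (0, 1).
#' @return The qualifying subset of `rhos` (possibly empty).
#' @export
select_confident <- function(rhos, tau) {
  if (!is.numeric(tau) || tau <= 0 || tau >= 1) {
    stop("`tau` must lie in (0, 1)", call. = FALSE)
  }
  rhos[!is.na(rhos$rho) & rhos$rho >= tau, , drop = FALSE]
}

#' Cross-platform consensus and background filtering
#'
#' Intersects the confident pair sets of two datasets and removes background
#' pairs, logging the size of every stage of the funnel (per-dataset counts,
#' consensus size, background removals, retained pairs).
#'
#' @param set_a,set_b Data frames with columns `ligand`, `receptor`
#'   (e.g. outputs of [select_confident()] on each platform).
#' @param background_pairs Optional data frame with columns `ligand`,
#'   `receptor` of pairs to discard.
#' @return List with `retained` (data frame of pairs) and `funnel` (named
#'   integer vector: `n_a`, `n_b`, `n_consensus`, `n_background_removed`,
#'   `n_retained`).
#' @export
consensus_and_filter <- function(set_a, set_b, background_pairs = NULL) {
  key_a <- pair_key(set_a$ligand, set_a$receptor)
  key_b <- pair_key(set_b$ligand, set_b$receptor)
  consensus <- intersect(key_a, key_b)
  bg <- if (!is.null(background_pairs) && nrow(background_pairs)) {
    pair_key(background_pairs$ligand, background_pairs$receptor)
  } else character()
  retained_keys <- setdiff(consensus, bg)
  idx <- match(retained_keys, key_a)
  retained <- set_a[idx, c("ligand", "receptor"), drop = FALSE]
  rownames(retained) <- NULL
  funnel <- c(n_a = length(key_a), n_b = length(key_b),
              n_consensus = length(consensus),
              n_background_removed = length(consensus) - length(retained_keys),
              n_retained = length(retained_keys))
  list(retained = retained, funnel = funnel)
}

#' Per-sample ligand-receptor score
#'
#' Regularized geometric mean of ligand and receptor expression: for sample
#' s, `score_s = sqrt(L_s R_s) / (sqrt(L_s R_s) + mu)` where L and R are the
#' normalized expressions (counts: log2(x+1); intensity: as-is, probes
#' averaged per gene) and `mu` is the mean of the whole normalized matrix.
#' Scores lie in `[0, 1)` and grow monotonically with either partner's
#' expression.
#'
#' @param expr An `ExpressionMatrix`.
#' @param ligand,receptor Gene symbols (both must be present).
#' @return Named per-sample numeric vector in `[0, 1)`.
#' @export
lr_score <- function(expr, ligand, receptor) {
  norm <- lr_normalized(expr)
  ligand <- toupper(ligand); receptor <- toupper(receptor)
  missing <- setdiff(c(ligand, receptor), rownames(norm))
  if (length(missing)) {
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  mu <- mean(norm)
  if (mu <= 0) stop("mean of the normalized matrix must be positive", call. = FALSE)
  g <- sqrt(pmax(norm[ligand, ] * norm[receptor, ], 0))
  g / (g + mu)
}

lr_normalized <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  e <- collapse_probes(expr)
  if (e$platform == "counts") log2(e$values + 1) else e$values
}

#' Ligand-receptor scores for a table of pairs
#'
#' @param expr An `ExpressionMatrix`.
#' @param pairs Data frame with columns `ligand`, `receptor`.
#' @return Matrix pairs x samples of L-R scores, rows named
#'   `"LIGAND:RECEPTOR"`.
#' @export
lr_score_matrix <- function(expr, pairs) {
  norm <- lr_normalized(expr)
  mu <- mean(norm)
  if (mu <= 0) stop("mean of the normalized matrix must be positive", call. = FALSE)
  out <- t(vapply(seq_len(nrow(pairs)), function(i) {
    g <- sqrt(pmax(norm[pairs$ligand[i], ] * norm[pairs$receptor[i], ], 0))
    g / (g + mu)
  }, numeric(ncol(norm))))
  rownames(out) <- paste(pairs$ligand, pairs$receptor, sep = ":")
  colnames(out) <- colnames(norm)
  out
}

#' Screen ligand-receptor pairs for infiltration-driven co-expression
#'
#' Spearman correlation (average-rank ties, t-approximation p-value) between
#' each pair's per-sample L-R score and the aggregate immune-infiltration
#' score, Benjamini-Hochberg adjusted across the supplied pairs. A pair is
#' flagged when rho exceeds `r_min` and the adjusted p-value stays below
#' `q_max`. Pairs with a constant score vector have no defined rank
#' correlation and are reported as missing, never flagged.
#'
#' @param lr_scores Matrix pairs x samples from [lr_score_matrix()].
#' @param infiltration Per-sample infiltration score
#'   (see [infiltration_score()]).
#' @param r_min Correlation threshold (strict: rho must exceed it).
#' @param q_max FDR threshold.
#' @return Data frame with columns `pair`, `rho`, `p_value`, `fdr`,
#'   `flagged`.
#' @export
infiltration_screen <- function(lr_scores, infiltration, r_min = 0.5, q_max = 0.05) {
  stopifnot(is.matrix(lr_scores))
  if (ncol(lr_scores) < 5L) stop("screen needs >= 5 samples", call. = FALSE)
  if (!is.null(names(infiltration))) {
    infiltration <- infiltration[colnames(lr_scores)]
  }
  if (length(infiltration) != ncol(lr_scores)) {
    stop("one infiltration value per sample is required", call. = FALSE)
  }
  res <- apply(lr_scores, 1L, function(x) spearman_rho_p(x, infiltration))
  rho <- vapply(res, `[[`, 0, "rho")
  p <- vapply(res, `[[`, 0, "p")
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(pair = rownames(lr_scores), rho = rho, p_value = p, fdr = fdr,
             flagged = !is.na(rho) & rho > r_min & !is.na(fdr) & fdr < q_max,
             row.names = NULL, stringsAsFactors = FALSE)
}
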