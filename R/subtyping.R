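#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of the matrix columns with Ward's minimum
#' variance criterion on Euclidean distances (`hclust` method `ward.D2`,
#' which implements classical Ward on unsquared Euclidean input).
#' Deterministic given the input order.
#'
#' @param m Numeric matrix, columns = samples.
#' @param k Number of clusters, 2 <= k <= n samples.
#' @return List with `labels` (named integer vector, 1..k in dendrogram cut
#'   order) and `linkage` (the `hclust` object with merge heights).
#' @export
ward_cluster <- function(m, k) {
  stopifnot(is.matrix(m))
  if (any(!is.finite(m))) stop("clustering input must be finite", call. = FALSE)
  n <- ncol(m)
  if (k < 2L || k > n) stop("`k` must satisfy 2 <= k <= n_samples", call. = FALSE)
  hc <- stats::hclust(stats::dist(t(m), method = "euclidean"), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  list(labels = labels, linkage = hc)
}

#' Assign immune subtypes from T-cell signature scores
#'
#' Samples are clustered on the T-cell signature score sub-matrix with Ward/
#' Euclidean linkage. With `k = 4` and `merge_smallest = TRUE` the two
#' smallest clusters are merged first (the microarray-view convention where
#' two small clusters form one biological group). The three final clusters
#' are then named deterministically: the cluster with the highest mean
#' activated-CD8 score becomes `immune_rich`; among the remaining clusters
#' the one with the lowest mean total T-cell score becomes `immune_poor`;
#' the rest is `immune_intermediate`.
#'
#' @param sig_scores A `SignatureScoreMatrix`.
#' @param tcell_signature_names Names of the T-cell signatures to cluster on.
#' @param cd8_signature Name of the activated-CD8 signature used to identify
#'   the immune-rich cluster (defaults to the first T-cell signature name).
#' @param k Number of clusters to cut (3 or 4).
#' @param merge_smallest Merge the two smallest clusters when `k = 4`.
#' @return An object of class `SubtypeAssignment`: data frame with columns
#'   `sample_id`, `cluster`, `subtype`, plus the linkage in attribute
#'   `"linkage"`.
#' @export
assign_immune_subtypes <- function(sig_scores, tcell_signature_names,
                                   cd8_signature = tcell_signature_names[1],
                                   k = 3L, merge_smallest = (k == 4L)) {
  stopifnot(inherits(sig_scores, "SignatureScoreMatrix"))
  if (!k %in% c(3L, 4L)) stop("`k` must be 3 or 4", call. = FALSE)
  sc <- sig_scores$scores
  missing <- setdiff(c(tcell_signature_names, cd8_signature), rownames(sc))
  if (length(missing)) {
    stop("signature(s) not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tc <- sc[tcell_signature_names, , drop = FALSE]
  cl <- ward_cluster(tc, k)
  labels <- cl$labels
  if (k == 4L) {
    if (!merge_smallest) {
      stop("k = 4 yields fewer than 3 subtype labels unless `merge_smallest` is TRUE",
           call. = FALSE)
    }
    sizes <- sort(table(labels))
    small <- as.integer(names(sizes)[1:2])
    labels[labels == small[2]] <- small[1]
    labels <- match(labels, sort(unique(labels)))   # relabel 1..3
    names(labels) <- colnames(tc)
  }
  if (length(unique(labels)) < 3L) {
    stop("fewer than 3 final clusters; cannot assign three immune subtypes", call. = FALSE)
  }
  cd8_mean <- tapply(sc[cd8_signature, names(labels)], labels, mean)
  total_tcell <- colMeans(tc)
  total_mean <- tapply(total_tcell[names(labels)], labels, mean)
  rich <- names(which.max(cd8_mean))
  rest <- setdiff(names(total_mean), rich)
  poor <- rest[which.min(total_mean[rest])]
  subtype <- rep("immune_intermediate", length(labels))
  subtype[labels == as.integer(rich)] <- "immune_rich"
  subtype[labels == as.integer(poor)] <- "immune_poor"
  out <- data.frame(sample_id = names(labels), cluster = as.integer(labels),
                    subtype = subtype, stringsAsFactors = FALSE)
  attr(out, "linkage") <- cl$linkage
  class(out) <- c("SubtypeAssignment", "data.frame")
  out
}

#' HLA class I/II down-regulation status
#'
#' Implements median dichotomization followed by clustering: for each HLA
#' gene, a sample is "low" when its expression lies strictly below the
#' cohort median for that gene (a value at the median counts as high).
#' When several cohorts are supplied the dichotomization is performed within
#' each cohort independently and the binary matrices are pooled. Samples are
#' Ward-clustered on the binary matrix into `k` clusters and each cluster is
#' named from its mean low-fractions f1 (class I genes) and f2 (class II
#' genes) against 0.5: both below 0.5 is `normal`, only f1 >= 0.5 is
#' `I_down`, only f2 >= 0.5 is `II_down`, otherwise `I_II_down`. Two
#' clusters mapping to the same name abort with an error asking for manual
#' review.
#'
#' @param expr An `ExpressionMatrix` or a list of them (one per cohort).
#'   Intensity matrices with a probe map are collapsed to gene level by
#'   probe averaging first.
#' @param class1_genes,class2_genes Gene symbols of the HLA class I and
#'   class II panels.
#' @param k Number of clusters (4 by default: normal + three down states).
#' @return An object of class `HLAStatus`: data frame with `sample_id`,
#'   `cluster`, `status`, plus the binary low/high matrix in attribute
#'   `"low_matrix"` and the linkage in `"linkage"`.
#' @export
hla_status <- function(expr, class1_genes, class2_genes, k = 4L) {
  cohorts <- if (inherits(expr, "ExpressionMatrix")) list(expr) else expr
  stopifnot(all(vapply(cohorts, inherits, TRUE, "ExpressionMatrix")))
  class1_genes <- toupper(class1_genes)
  class2_genes <- toupper(class2_genes)
  low_list <- lapply(cohorts, function(e) {
    e <- collapse_probes(e)
    genes <- c(class1_genes, class2_genes)
    found <- intersect(genes, rownames(e$values))
    if (!length(intersect(class1_genes, found)) || !length(intersect(class2_genes, found))) {
      stop("need at least one class I and one class II gene in every cohort", call. = FALSE)
    }
    m <- e$values[found, , drop = FALSE]
    med <- apply(m, 1L, stats::median)
    low <- (m < med) * 1L
    # align to the full panel; genes absent from this cohort become NA rows
    full <- matrix(NA_real_, length(genes), ncol(m),
                   dimnames = list(genes, colnames(m)))
    full[found, ] <- low
    full
  })
  low <- do.call(cbind, low_list)
  keep <- rowSums(is.na(low)) == 0
  low <- low[keep, , drop = FALSE]
  if (anyDuplicated(colnames(low))) {
    stop("duplicate sample ids across cohorts", call. = FALSE)
  }
  c1 <- intersect(class1_genes, rownames(low))
  c2 <- intersect(class2_genes, rownames(low))
  if (!length(c1) || !length(c2)) {
    stop("no HLA gene of one class is shared by all cohorts", call. = FALSE)
  }
  if (nrow(unique(t(low))) < k) {
    stop(sprintf("only %d distinct binary profiles; cannot form k = %d clusters",
                 nrow(unique(t(low))), k), call. = FALSE)
  }
  cl <- ward_cluster(low, k)
  labels <- cl$labels
  f1 <- tapply(colMeans(low[c1, , drop = FALSE]), labels, mean)
  f2 <- tapply(colMeans(low[c2, , drop = FALSE]), labels, mean)
  name_of <- ifelse(f1 < 0.5 & f2 < 0.5, "normal",
                    ifelse(f1 >= 0.5 & f2 < 0.5, "I_down",
                           ifelse(f1 < 0.5 & f2 >= 0.5, "II_down", "I_II_down")))
  if (anyDuplicated(name_of)) {
    stop("two clusters map to the same HLA status (",
         paste(name_of, collapse = ", "),
         "); manual review of the dendrogram is required", call. = FALSE)
  }
  out <- data.frame(sample_id = names(labels), cluster = as.integer(labels),
                    status = unname(name_of[as.character(labels)]),
                    stringsAsFactors = FALSE)
  attr(out, "low_matrix") <- low
  attr(out, "linkage") <- cl$linkage
  class(out) <- c("HLAStatus", "data.frame")
  out
}

#' Clip matrix extremes at global percentiles
#'
#' Display-oriented winsorization: values below the `fraction` percentile of
#' the whole matrix are set to that percentile, values above the
#' `1 - fraction` percentile likewise (linear-interpolation percentiles,
#' `quantile` type 7).
#'
#' @param m Numeric matrix.
#' @param fraction Fraction clipped at each tail, in `[0, 0.5)`.
#' @return Matrix of the same shape.
#' @export
clip_extremes <- function(m, fraction = 0.025) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 0.5) {
    stop("`fraction` must lie in [0, 0.5)", call. = FALSE)
  }
  if (any(!is.finite(m))) stop("matrix must be finite", call. = FALSE)
  if (fraction == 0) return(m)
  q <- stats::quantile(m, c(fraction, 1 - fraction), type = 7, names = FALSE)
  m[m < q[1]] <- q[1]
  m[m > q[2]] <- q[2]
  m
}
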