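#' Per-gene z-score standardization of an expression matrix
#'
#' Standardizes each gene row to mean 0 and unit sample standard deviation
#' (ddof = 1). Counts are log2(x+1)-transformed first (unless
#' `log_transform = FALSE`); intensities are assumed to be on a log scale
#' already. Zero-variance genes cannot be standardized: their rows are set
#' to 0 and flagged in the `"constant_genes"` attribute so that matrices
#' keep their shape.
#'
#' @param expr An `ExpressionMatrix` or a plain numeric matrix
#'   (genes x samples; a plain matrix is used as-is apart from the optional
#'   log transform).
#' @param log_transform Apply log2(x+1) before standardizing (only for
#'   counts-platform input or plain matrices).
#' @return Numeric matrix of z-scores with attribute `constant_genes`
#'   (character vector of flagged rows).
#' @export
zscore_matrix <- function(expr, log_transform = TRUE) {
  m <- if (inherits(expr, "ExpressionMatrix")) {
    if (expr$platform == "counts" && log_transform) log2(expr$values + 1) else expr$values
  } else {
    if (log_transform) log2(expr + 1) else expr
  }
  if (ncol(m) < 2L) {
    stop("z-scores need >= 2 samples (sample sd undefined otherwise)", call. = FALSE)
  }
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  constant <- sdv == 0
  sdv[constant] <- 1          # rows become exactly 0 below
  z <- (m - mu) / sdv
  z[constant, ] <- 0
  attr(z, "constant_genes") <- rownames(m)[constant]
  z
}

#' Signature scores as gene z-score averages
#'
#' The score of signature S in sample s is the mean of z[g, s] over the
#' signature genes found in the matrix. Signatures with no overlapping gene
#' are dropped with a warning; the number of genes actually used is recorded
#' per signature.
#'
#' @param z Gene x sample z-score matrix from [zscore_matrix()].
#' @param sigs A `SignatureCollection`.
#' @return An object of class `SignatureScoreMatrix`: list with `scores`
#'   (signature x sample matrix) and `n_genes_used` (named integer vector).
#' @export
score_signatures <- function(z, sigs) {
  stopifnot(is.matrix(z), inherits(sigs, "SignatureCollection"))
  genes <- rownames(z)
  overlaps <- lapply(sigs, function(g) intersect(g, genes))
  n_used <- vapply(overlaps, length, 1L)
  if (all(n_used == 0L)) {
    stop("no signature shares any gene with the expression matrix", call. = FALSE)
  }
  if (any(n_used == 0L)) {
    warning("dropping signature(s) with no overlapping genes: ",
            paste(names(sigs)[n_used == 0L], collapse = ", "), call. = FALSE)
  }
  keep <- names(sigs)[n_used > 0L]
  scores <- t(vapply(keep, function(s) colMeans(z[overlaps[[s]], , drop = FALSE]),
                     numeric(ncol(z))))
  dimnames(scores) <- list(keep, colnames(z))
  structure(list(scores = scores, n_genes_used = n_used[keep]),
            class = "SignatureScoreMatrix")
}

#' @export
print.SignatureScoreMatrix <- function(x, ...) {
  cat(sprintf("SignatureScoreMatrix: %d signatures x %d samples\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Aggregate immune-infiltration score
#'
#' Per sample, the sum of the named immune signature scores (stromal
#' signatures such as CAF/EC are deliberately excluded by the caller's name
#' list). Used to screen ligand-receptor pairs for infiltration-driven
#' co-expression.
#'
#' @param sig_scores A `SignatureScoreMatrix`.
#' @param immune_signature_names Names of the immune signatures to sum.
#' @return Named per-sample numeric vector.
#' @export
infiltration_score <- function(sig_scores, immune_signature_names) {
  stopifnot(inherits(sig_scores, "SignatureScoreMatrix"))
  missing <- setdiff(immune_signature_names, rownames(sig_scores$scores))
  if (length(missing)) {
    stop("unknown signature name(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  colSums(sig_scores$scores[immune_signature_names, , drop = FALSE])
}
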