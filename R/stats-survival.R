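validate_contingency <- function(tab, square2 = FALSE) {
  if (!is.matrix(tab) || !is.numeric(tab)) {
    stop("contingency table must be a numeric matrix", call. = FALSE)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("contingency table entries must be non-negative integers", call. = FALSE)
  }
  if (square2 && !all(dim(tab) == c(2L, 2L))) {
    stop("a 2x2 table is required", call. = FALSE)
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("table needs at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  }
  invisible(tab)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric tail probabilities at fixed margins: one-sided
#' tails, or the two-sided sum of all tables at most as probable as the
#' observed one.
#'
#' @param tab 2x2 integer matrix with positive margins.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (direction
#'   refers to the \[1,1\] cell / odds ratio).
#' @return The p-value.
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  validate_contingency(tab, square2 = TRUE)
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[alternative]
  stats::fisher.test(tab, alternative = alt)$p.value
}

#' Pearson chi-squared test of independence
#'
#' Pearson's statistic without continuity correction,
#' df = (r - 1)(c - 1), with the expected counts reported alongside.
#'
#' @param tab r x c integer matrix with positive margins.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi2_test <- function(tab) {
  validate_contingency(tab)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Spearman correlations of several vectors against one target, BH-adjusted
#'
#' Average-rank Spearman rho with the t-approximation p-value for each
#' supplied vector against `y`, and Benjamini-Hochberg adjustment across the
#' family. Constant vectors yield a missing result (rank correlation
#' undefined), never zero.
#'
#' @param x_vectors Named list of numeric vectors, or a matrix whose rows
#'   are the vectors.
#' @param y Numeric target vector of matching length.
#' @return Data frame with columns `name`, `rho`, `p_value`, `fdr`.
#' @export
spearman_bh <- function(x_vectors, y) {
  if (is.matrix(x_vectors)) {
    x_vectors <- stats::setNames(lapply(seq_len(nrow(x_vectors)),
                                        function(i) x_vectors[i, ]),
                                 rownames(x_vectors))
  }
  res <- lapply(x_vectors, spearman_rho_p, y = y)
  rho <- vapply(res, `[[`, 0, "rho")
  p <- vapply(res, `[[`, 0, "p")
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(name = names(x_vectors) %||% as.character(seq_along(x_vectors)),
             rho = rho, p_value = p, fdr = fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with right censoring (a thin wrapper over
#' `survival::survfit` exposing the step function and censoring marks).
#'
#' @param times Non-negative event/censoring times.
#' @param events 0/1 event indicators (1 = event).
#' @return An object of class `SurvivalCurve`: list with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (non-increasing, starting from 1 at time
#'   0) and `censor_times`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("survival times must be non-negative", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, surv = fit$surv,
                 censor_times = sort(times[events == 0])),
            class = "SurvivalCurve")
}

#' @export
print.SurvivalCurve <- function(x, ...) {
  cat(sprintf("SurvivalCurve: %d time points, %d events, %d censored\n",
              length(x$time), sum(x$n_event), sum(x$n_censor)))
  invisible(x)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected log-rank statistic with hypergeometric
#' variance (via `survival::survdiff`), chi-squared with
#' `n_groups - 1` degrees of freedom.
#'
#' @param times Non-negative event/censoring times.
#' @param events 0/1 event indicators.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (sum(events) == 0) stop("no events observed in any group", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(fit$n) - 1L
  p <- stats::pchisq(fit$chisq, df = df, lower.tail = FALSE)
  list(statistic = unname(fit$chisq), df = df, p_value = p)
}

#' Median split of a numeric score
#'
#' Strictly above the median maps to `"high"`; at or below the median maps
#' to `"low"` (the documented tie rule, so an all-equal vector is all low).
#'
#' @param values Numeric vector (n >= 2).
#' @return Character vector of `"high"`/`"low"` labels (named like
#'   `values`).
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("median split needs >= 2 values", call. = FALSE)
  med <- stats::median(values)
  out <- ifelse(values > med, "high", "low")
  names(out) <- names(values)
  out
}

#' Association table of categorical covariates versus group labels
#'
#' Cross-tabulates each covariate against the group labels and applies the
#' Pearson chi-squared test (no continuity correction), producing a
#' cohort-description table of covariate-by-subtype dependence.
#'
#' @param clin A `ClinicalTable`.
#' @param groups Named vector of group labels (names = sample ids).
#' @param covariates Covariate columns to test (default: all).
#' @return Data frame with columns `covariate`, `statistic`, `df`,
#'   `p_value`.
#' @export
association_table <- function(clin, groups, covariates = clinical_covariates(clin)) {
  stopifnot(inherits(clin, "ClinicalTable"))
  g <- groups[clin$sample_id]
  rows <- lapply(covariates, function(cv) {
    tab <- table(clin[[cv]], g)
    res <- tryCatch(chi2_test(unclass(as.matrix(tab))),
                    error = function(e) NULL)
    data.frame(covariate = cv,
               statistic = if (is.null(res)) NA_real_ else res$statistic,
               df = if (is.null(res)) NA_integer_ else res$df,
               p_value = if (is.null(res)) NA_real_ else res$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
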