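#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# session RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Spearman rank correlation with average-rank ties and the t-approximation
# for the p-value (adequate for cohort sizes in the tens).  Returns rho = NA
# when either vector is constant: a rank correlation is undefined there and
# callers must report the pair as missing, never as zero.
spearman_rho_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("Spearman correlation requires >= 5 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = p, n = n)
}

# Pair keys used to intersect ligand-receptor sets.
pair_key <- function(ligand, receptor) paste(ligand, receptor, sep = "\r")

`%||%` <- function(a, b) if (is.null(a)) b else a
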