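#' Construct a validated expression matrix
#'
#' The central data container: a numeric feature-by-sample matrix tagged with
#' its platform. RNA-seq data arrive as normalized counts (`platform =
#' "counts"`, non-negative), microarray data as log2 probe intensities
#' (`platform = "intensity"`), optionally with a many-to-one probe-to-gene
#' map. Downstream operations dispatch on the platform tag: counts are
#' log2(x+1)-transformed where a log scale is required, intensities are used
#' as-is.
#'
#' @param values Numeric matrix, rows = features (genes or probes), columns =
#'   samples. Row and column names are mandatory and become the feature and
#'   sample ids.
#' @param platform Either `"counts"` or `"intensity"`.
#' @param probe_map Optional data frame with columns `probe` and `gene`
#'   mapping feature ids (probes) to gene symbols. Every mapped probe must
#'   exist among the feature ids; probes absent from the map are retained in
#'   the matrix but excluded from gene-level operations.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, platform = c("counts", "intensity"),
                              probe_map = NULL) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry feature (row) and sample (column) names", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  if (platform == "counts" && any(values < 0)) {
    stop("counts platform requires non-negative values", call. = FALSE)
  }
  if (is.null(probe_map) && anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate feature id(s) without a probe map: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!is.null(probe_map)) {
    if (!is.data.frame(probe_map) || !all(c("probe", "gene") %in% names(probe_map))) {
      stop("`probe_map` must be a data frame with columns `probe` and `gene`",
           call. = FALSE)
    }
    probe_map$probe <- as.character(probe_map$probe)
    probe_map$gene <- toupper(as.character(probe_map$gene))
    missing <- setdiff(probe_map$probe, rownames(values))
    if (length(missing)) {
      stop("probe map refers to absent feature id(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(values = values, platform = platform, probe_map = probe_map),
    class = "ExpressionMatrix"
  )
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d features x %d samples\n",
              x$platform, nrow(x$values), ncol(x$values)))
  if (!is.null(x$probe_map)) {
    cat(sprintf("  probe map: %d probes -> %d genes\n",
                nrow(x$probe_map), length(unique(x$probe_map$gene))))
  }
  invisible(x)
}

#' Feature and sample identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from a tab-separated file
#'
#' Expects a header row of sample ids and a first column of feature ids;
#' remaining cells must be numeric ('.' decimal separator). Validation
#' applies the `ExpressionMatrix` invariants: duplicate sample ids and
#' non-finite cells are rejected, counts must be non-negative, and duplicate
#' feature ids are only allowed when a probe map is supplied (several probes
#' may interrogate the same gene, but a probe id itself must be unique).
#'
#' @param path Path to the TSV file.
#' @param platform `"counts"` or `"intensity"`.
#' @param probe_map_path Optional path to a two-column TSV (probe, gene).
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, platform = c("counts", "intensity"),
                            probe_map_path = NULL) {
  platform <- match.arg(platform)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2L) stop("expression file needs a feature column plus >= 1 sample", call. = FALSE)
  ids <- raw[[1]]
  sample_names <- names(raw)[-1]     # before subsetting: `[.data.frame` would
  mat <- as.matrix(raw[, -1, drop = FALSE])  # silently uniquify duplicates
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(ids, sample_names)))
  bad <- which(is.na(num) & !(mat %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s' in %s",
                 mat[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(mat)[bad[1, 2]], path), call. = FALSE)
  }
  probe_map <- if (!is.null(probe_map_path)) read_probe_map(probe_map_path) else NULL
  expression_matrix(num, platform, probe_map)
}

#' Write an expression matrix as TSV
#'
#' Values are written at full double precision so a write/read round trip
#' preserves them to better than 1e-12.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output file path.
#' @param id_column Header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "feature_id") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV with header `probe`, `gene`. Gene symbols are upper-cased.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `probe` and `gene`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(c("probe", "gene") %in% names(df))) {
    stop("probe map must have columns `probe` and `gene`", call. = FALSE)
  }
  if (anyDuplicated(df$probe)) stop("duplicate probe ids in probe map", call. = FALSE)
  df$gene <- toupper(df$gene)
  df[, c("probe", "gene")]
}

#' Write a probe-to-gene map as TSV
#' @param probe_map Data frame with columns `probe`, `gene`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_probe_map <- function(probe_map, path) {
  utils::write.table(probe_map[, c("probe", "gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Collapse a probe-level intensity matrix to gene level by averaging the
# probes of each mapped gene. Unmapped probes are dropped (they cannot enter
# gene-level operations). Counts matrices pass through unchanged.
collapse_probes <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(x$probe_map)) return(x)
  pm <- x$probe_map
  vals <- x$values[pm$probe, , drop = FALSE]
  agg <- rowsum(vals, group = pm$gene, reorder = TRUE)
  counts <- as.vector(table(pm$gene)[rownames(agg)])
  expression_matrix(agg / counts, x$platform, probe_map = NULL)
}
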