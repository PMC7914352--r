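#' Read contingency tables from a long-format TSV
#'
#' Parses a file with columns `table_id`, `row_label`, `col_label`, `count`
#' into a named list of integer matrices, preserving the row and column
#' order of first appearance. The package ships such a file
#' (`clinical_association_counts.tsv` under `extdata`) holding the published
#' cohort cross-tabulations of clinical covariates by immune subtype, so the
#' contingency statistics can be recomputed from counts alone.
#'
#' @param path Path to the TSV file.
#' @return Named list of contingency matrices.
#' @export
read_contingency_tables <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("table_id", "row_label", "col_label", "count")
  if (!all(need %in% names(df))) {
    stop("contingency file needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  lapply(split(df, factor(df$table_id, levels = unique(df$table_id))), function(d) {
    rows <- unique(d$row_label)
    cols <- unique(d$col_label)
    m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
    m[cbind(d$row_label, d$col_label)] <- as.integer(d$count)
    m
  })
}
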