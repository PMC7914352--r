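#' Construct a validated clinical table
#'
#' Per-sample survival endpoints (overall and relapse-free survival, in
#' months) with 0/1 event indicators, plus arbitrary categorical covariates.
#'
#' @param df Data frame with columns `sample_id`, `os_time`, `os_event`,
#'   `rfs_time`, `rfs_event`; any further columns are treated as categorical
#'   covariates.
#' @return A data frame of class `ClinicalTable`.
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "os_time", "os_event", "rfs_time", "rfs_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in clinical table", call. = FALSE)
  for (col in c("os_time", "rfs_time")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.finite(df[[col]])) || any(df[[col]] < 0)) {
      stop("`", col, "` must be finite and non-negative", call. = FALSE)
    }
  }
  for (col in c("os_event", "rfs_event")) {
    df[[col]] <- as.numeric(df[[col]])
    if (!all(df[[col]] %in% c(0, 1))) {
      stop("`", col, "` must contain only 0/1", call. = FALSE)
    }
  }
  covars <- setdiff(names(df), need)
  for (col in covars) df[[col]] <- as.character(df[[col]])
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Read a clinical table from TSV
#' @param path Path to the TSV file (see [clinical_table()] for the schema).
#' @return A `ClinicalTable`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  clinical_table(df)
}

#' Write a clinical table as TSV
#' @param clin A `ClinicalTable`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clin, path) {
  stopifnot(inherits(clin, "ClinicalTable"))
  utils::write.table(as.data.frame(clin), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Covariate column names of a clinical table
#' @param clin A `ClinicalTable`.
#' @return Character vector of covariate names.
#' @export
clinical_covariates <- function(clin) {
  setdiff(names(clin), c("sample_id", "os_time", "os_event", "rfs_time", "rfs_event"))
}
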