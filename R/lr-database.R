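#' Construct a validated ligand-receptor pair database
#'
#' Curated ligand-receptor gene pairs with free-form pathway tags and an
#' optional background flag marking pairs regarded as tissue-resident
#' background (e.g. constitutive brain interactions) to be discarded from
#' tumor-specific reports.
#'
#' @param ligand,receptor Character vectors of gene symbols (upper-cased).
#' @param pathways Character vector of semicolon-separated pathway tags
#'   (may be empty strings).
#' @param background Logical vector; `TRUE` marks background pairs.
#' @return A data frame of class `LRDatabase`.
#' @export
lr_database <- function(ligand, receptor, pathways = "", background = FALSE) {
  ligand <- toupper(as.character(ligand))
  receptor <- toupper(as.character(receptor))
  if (!length(ligand) || length(ligand) != length(receptor)) {
    stop("`ligand` and `receptor` must be non-empty and of equal length", call. = FALSE)
  }
  if (any(!nzchar(ligand)) || any(!nzchar(receptor))) {
    stop("ligand/receptor symbols must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(pair_key(ligand, receptor))) {
    stop("duplicate (ligand, receptor) pair(s) in database", call. = FALSE)
  }
  df <- data.frame(ligand = ligand, receptor = receptor,
                   pathways = rep_len(as.character(pathways), length(ligand)),
                   background = rep_len(as.logical(background), length(ligand)),
                   stringsAsFactors = FALSE)
  class(df) <- c("LRDatabase", "data.frame")
  df
}

#' Read a ligand-receptor database from TSV
#'
#' Required columns: `ligand`, `receptor`. Optional: `pathways`
#' (semicolon-separated tags) and `background` (0/1 or TRUE/FALSE).
#'
#' @param path Path to the TSV file.
#' @return An `LRDatabase`.
#' @export
read_lr_database <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  need <- c("ligand", "receptor")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("L-R database missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bg <- if ("background" %in% names(df)) {
    df$background %in% c("1", "TRUE", "true", "yes")
  } else FALSE
  lr_database(df$ligand, df$receptor,
              pathways = if ("pathways" %in% names(df)) df$pathways else "",
              background = bg)
}

#' Write a ligand-receptor database as TSV
#' @param db An `LRDatabase`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lr_database <- function(db, path) {
  stopifnot(inherits(db, "LRDatabase"))
  out <- as.data.frame(db)
  out$background <- as.integer(out$background)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
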