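#' Construct a validated signature collection
#'
#' A named list of gene sets (character vectors of gene symbols). Symbols are
#' upper-cased and de-duplicated within each set; empty sets are rejected.
#'
#' @param sets Named list of character vectors.
#' @param provenance Free-text label describing the origin of the collection
#'   (e.g. "immune cell signatures", "hallmark").
#' @return An object of class `SignatureCollection`.
#' @export
signature_collection <- function(sets, provenance = "unspecified") {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("`sets` must be a named list of gene vectors", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) stop("duplicate signature names", call. = FALSE)
  sets <- lapply(sets, function(g) {
    g <- unique(toupper(as.character(g)))
    g[nzchar(g)]
  })
  empty <- names(sets)[vapply(sets, length, 1L) == 0L]
  if (length(empty)) {
    stop("empty gene set(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  structure(sets, class = "SignatureCollection", provenance = provenance)
}

#' @export
print.SignatureCollection <- function(x, ...) {
  cat(sprintf("SignatureCollection (%s): %d sets, %d-%d genes\n",
              attr(x, "provenance"), length(x),
              if (length(x)) min(lengths(x)) else 0L,
              if (length(x)) max(lengths(x)) else 0L))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene symbols
#' (the MSigDB interchange dialect). Duplicate genes within a line are
#' de-duplicated; an empty file yields an empty collection so pipelines can
#' run with pruned signature files.
#'
#' @param path Path to the GMT file.
#' @param provenance Provenance label stored on the collection.
#' @return A `SignatureCollection`.
#' @export
read_gmt <- function(path, provenance = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(structure(stats::setNames(list(), character()),
                     class = "SignatureCollection", provenance = provenance))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields in %s", short[1], path),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  signature_collection(sets, provenance = provenance)
}

#' Write a signature collection in GMT format
#' @param sigs A `SignatureCollection`.
#' @param path Output file path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigs, path, descriptions = NULL) {
  stopifnot(inherits(sigs, "SignatureCollection"))
  desc <- descriptions %||% rep("na", length(sigs))
  lines <- vapply(seq_along(sigs), function(i) {
    paste(c(names(sigs)[i], desc[i], sigs[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
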