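#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param sets named list of gene id vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "tissueome") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(ln) {
    strsplit(ln, "\t", fixed = TRUE)[[1]][1]
  }, "")
  out
}

#' Write an annotation table (gene_id, term_id, evidence) as TSV
#'
#' @param annotations data.frame with columns gene, term and optionally
#'   evidence.
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

# deterministic JSON writer used for truth files, venn blocks and manifests
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
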