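#' Tab-separated I/O helpers
#'
#' Plain TSV writers/readers with fixed, locale-independent formatting so
#' reruns are byte-identical.
#'
#' @name io
NULL

#' @param df data.frame to write.
#' @param path output path.
#' @rdname io
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname io
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}

# BED has no header
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an activity TSV (first column entity id, remaining columns samples)
#'
#' @rdname io
#' @export
read_activity_tsv <- function(path) {
  as_activity_matrix(read_tsv(path))
}

write_activity_tsv <- function(m, id_col, path) {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Read a two-column sample -> population map TSV
#'
#' @rdname io
#' @export
read_sample_map <- function(path) {
  as_sample_map(read_tsv(path))
}
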