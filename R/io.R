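#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector (accession -> sequence); the accession is
#'   the first whitespace-delimited token of the header.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  setNames(as.character(x), names(x))
}

#' Write protein sequences as FASTA
#'
#' @param proteins named character vector.
#' @param path output file.
#' @export
write_protein_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}

#' Write a domain-hit table as TSV
#'
#' Alignment-map list columns are dropped; E-values are written in
#' scientific notation.
#'
#' @param hits hit table from [scan_database()].
#' @param path output file.
#' @export
write_hits_tsv <- function(hits, path) {
  keep <- setdiff(names(hits), c("prof_cols", "sub_pos"))
  df <- as.data.frame(hits)[, keep, drop = FALSE]
  if ("e_value" %in% names(df))
    df$e_value <- formatC(df$e_value, format = "e", digits = 3)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generic table as TSV
#' @param x data frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
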