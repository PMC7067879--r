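#' Read a protein FASTA into a named character vector
#'
#' Accessions are taken from the second `|`-field of UniProt-style headers
#' (`sp|P08571|CD14_HUMAN` -> `P08571`), otherwise from the first
#' whitespace-delimited token. Sequences are uppercased and stop characters
#' (`*`) stripped.
#'
#' @param path FASTA file.
#' @return Named character vector, accession -> amino-acid sequence.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  token <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)
  acc <- vapply(token, function(tok) {
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 3L && parts[1] %in% c("sp", "tr")) parts[2] else tok
  }, "", USE.NAMES = FALSE)
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  seqs <- toupper(gsub("*", "", as.character(aa), fixed = TRUE))
  stats::setNames(seqs, acc)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (accession -> sequence).
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}
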