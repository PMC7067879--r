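#' PSM table input/output
#'
#' The PSM table is a TSV dialect with columns `spectrum_id`, `peptide`,
#' `proteins` (';'-separated accessions), `score`, `is_decoy` (0/1),
#' `ms1_max_intensity`, `isolation_specificity`, then per design channel
#' `int_<label>` and `noise_<label>`. Missing reporter measurements are
#' empty cells (a zero intensity is a legal measurement, distinct from "no
#' peak in the window").
#'
#' @param path TSV file.
#' @param design A `surfprot_design`; reporter columns must match its
#'   channels.
#' @return A `surfprot_psms` data frame; reporter columns are numeric with
#'   `NA` for missing channels. The design is attached as attribute
#'   `"design"`.
#' @rdname psm_io
#' @export
read_psm_table <- function(path, design) {
  design <- as_study_design(design)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  base_cols <- c("spectrum_id", "peptide", "proteins", "score", "is_decoy",
                 "ms1_max_intensity", "isolation_specificity")
  rep_cols <- c(paste0("int_", design$channel), paste0("noise_", design$channel))
  miss <- setdiff(base_cols, names(df))
  if (length(miss)) stop("PSM table missing required column(s): ",
                         paste(miss, collapse = ", "))
  miss_rep <- setdiff(rep_cols, names(df))
  if (length(miss_rep)) {
    stop("PSM table reporter columns do not match the design (",
         plex_size(design), "-plex); missing: ", paste(miss_rep, collapse = ", "))
  }
  extra_rep <- setdiff(grep("^(int|noise)_", names(df), value = TRUE), rep_cols)
  if (length(extra_rep)) {
    stop("PSM table reporter columns do not match the design (",
         plex_size(design), "-plex); unexpected: ",
         paste(extra_rep, collapse = ", "))
  }
  for (col in c("score", "ms1_max_intensity", "isolation_specificity", rep_cols)) {
    df[[col]] <- suppressWarnings(as.numeric(ifelse(df[[col]] == "", NA, df[[col]])))
  }
  df$is_decoy <- df$is_decoy %in% c("1", "TRUE", "true")
  validate_psms(df, design)
  attr(df, "design") <- design
  class(df) <- c("surfprot_psms", "data.frame")
  df
}

validate_psms <- function(df, design) {
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- function(cond, what) {
    if (any(cond)) {
      stop("malformed PSM row(s) [", what, "] at line(s): ",
           paste(utils::head(line[cond], 10L), collapse = ", "))
    }
  }
  bad(!grepl("^[ACDEFGHIKLMNPQRSTVWYUX]+$", df$peptide), "peptide alphabet")
  bad(!nzchar(df$proteins), "empty protein list")
  bad(is.na(df$score), "non-numeric score")
  bad(is.na(df$ms1_max_intensity) | df$ms1_max_intensity < 0, "ms1_max_intensity")
  bad(is.na(df$isolation_specificity) | df$isolation_specificity < 0 |
        df$isolation_specificity > 1, "isolation_specificity outside [0,1]")
  noise <- as.matrix(df[paste0("noise_", design$channel)])
  bad(apply(!is.na(noise) & noise <= 0, 1L, any), "non-positive noise")
  invisible(df)
}

#' @param psms A `surfprot_psms` (or compatible data frame).
#' @rdname psm_io
#' @export
write_psm_table <- function(psms, path) {
  out <- as.data.frame(psms)
  out$is_decoy <- as.integer(out$is_decoy)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Reporter signal-to-noise matrix of a PSM table
#'
#' @inheritParams write_psm_table
#' @param design The design (defaults to the table's attached design).
#' @return Numeric matrix, PSMs x channels; `NA` where the channel is
#'   missing. S:N = intensity / noise per channel.
#' @export
psm_sn_matrix <- function(psms, design = attr(psms, "design")) {
  design <- as_study_design(design)
  int <- as.matrix(psms[paste0("int_", design$channel)])
  noise <- as.matrix(psms[paste0("noise_", design$channel)])
  sn <- int / noise
  colnames(sn) <- design$channel
  sn
}

#' Annotation table input/output
#'
#' GO cellular-compartment snapshot: columns `accession`, `go_cc_terms`
#' ('|'-separated term names) and `term_part_counts` ('|'-separated lineage
#' part counts, aligned with the terms).
#'
#' @param path TSV file.
#' @return Data frame with list-columns `go_cc_terms` (character vectors)
#'   and `term_part_counts` (integer vectors).
#' @rdname annot_io
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL)
  need <- c("accession", "go_cc_terms", "term_part_counts")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "))
  terms <- strsplit(df$go_cc_terms, "|", fixed = TRUE)
  counts <- lapply(strsplit(df$term_part_counts, "|", fixed = TRUE), as.integer)
  ok <- mapply(function(t, n) length(t) == length(n) && all(!is.na(n)) && all(n >= 1L),
               terms, counts)
  if (!all(ok)) stop("terms/part-counts mismatch at line(s): ",
                     paste(which(!ok) + 1L, collapse = ", "))
  data.frame(accession = df$accession,
             go_cc_terms = I(terms),
             term_part_counts = I(counts),
             stringsAsFactors = FALSE)
}

#' @param annot Annotation data frame as returned by [read_annotation_table()].
#' @rdname annot_io
#' @export
write_annotation_table <- function(annot, path) {
  out <- data.frame(
    accession = annot$accession,
    go_cc_terms = vapply(annot$go_cc_terms, paste, "", collapse = "|"),
    term_part_counts = vapply(annot$term_part_counts, paste, "", collapse = "|"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Theoretical TMT 10-plex reporter-ion m/z values
#'
#' Standard monoisotopic reporter masses, bundled as an editable table
#' (`inst/extdata/tmt10_reporter_mz.tsv`); override by supplying your own
#' two-column (channel, mz) table to the extraction step.
#'
#' @param channels Channel labels to return (default: all ten).
#' @return Named numeric vector of m/z values (Th).
#' @export
tmt_reporter_mz <- function(channels = NULL) {
  path <- system.file("extdata", "tmt10_reporter_mz.tsv", package = "surfprot")
  tab <- utils::read.delim(path, colClasses = c("character", "numeric"))
  mz <- stats::setNames(tab$mz, tab$channel)
  if (is.null(channels)) return(mz)
  missing <- setdiff(channels, names(mz))
  if (length(missing)) stop("no theoretical m/z for channel(s): ",
                            paste(missing, collapse = ", "))
  mz[channels]
}
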