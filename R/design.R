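#' Construct the TMT sample design for a study arm
#'
#' The 9-plex design interleaves three monocyte subsets across three donors
#' over channels 126..130C; the 3-plex design carries classical monocytes
#' from three donors on channels 126..127C.
#'
#' @param kind `"classical_3plex"` or `"subsets_9plex"`.
#' @return A `surfprot_design` data frame with columns `channel`, `subset`
#'   (one of classical/intermediate/nonclassical) and `donor`.
#' @examples
#' make_study_design("subsets_9plex")
#' @export
make_study_design <- function(kind = c("subsets_9plex", "classical_3plex")) {
  kind <- match.arg(kind)
  if (kind == "subsets_9plex") {
    d <- data.frame(
      channel = c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N", "130C"),
      subset  = rep(c("classical", "intermediate", "nonclassical"), times = 3),
      donor   = rep(c("d1", "d2", "d3"), each = 3),
      stringsAsFactors = FALSE
    )
  } else {
    d <- data.frame(
      channel = c("126", "127N", "127C"),
      subset  = "classical",
      donor   = c("d1", "d2", "d3"),
      stringsAsFactors = FALSE
    )
  }
  as_study_design(d)
}

#' Validate and classify a sample-design table
#'
#' @param d Data frame with columns `channel`, `subset`, `donor`.
#' @return The validated design with class `surfprot_design`.
#' @export
as_study_design <- function(d) {
  stopifnot(is.data.frame(d))
  need <- c("channel", "subset", "donor")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  }
  d$channel <- as.character(d$channel)
  d$subset <- as.character(d$subset)
  d$donor <- as.character(d$donor)
  if (anyDuplicated(d$channel)) {
    stop("duplicate channel labels in design: ",
         paste(unique(d$channel[duplicated(d$channel)]), collapse = ", "))
  }
  if (any(!nzchar(d$subset)) || any(!nzchar(d$donor)) || anyNA(d$subset) || anyNA(d$donor)) {
    stop("every channel needs a non-empty subset and donor")
  }
  if (anyDuplicated(paste(d$subset, d$donor))) {
    stop("(subset, donor) pairs must be unique")
  }
  class(d) <- c("surfprot_design", "data.frame")
  d
}

#' @export
plex_size <- function(design) nrow(design)

#' Read / write a design table (TSV with channel, subset, donor)
#'
#' @param path File path.
#' @rdname design_io
#' @export
read_design <- function(path) {
  as_study_design(utils::read.delim(path, colClasses = "character"))
}

#' @param design A `surfprot_design`.
#' @rdname design_io
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
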