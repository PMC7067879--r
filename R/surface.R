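#' Classify a protein's surface status from GO cellular-compartment terms
#'
#' A protein is called surface when annotated 'plasma membrane' (PM), 'cell
#' surface' (CS), 'extracellular' (XC, matching e.g. 'extracellular
#' region'), or carrying a short 4- or 5-part GO CC term including
#' 'integral to membrane' (or its modern wording 'integral component of
#' membrane') with no other term assigning a specific subcellular
#' compartment (ShG). Matching is case-insensitive substring on term names.
#'
#' @param terms Character vector of GO CC term names (may be empty).
#' @param part_counts Integer vector of lineage part counts per term.
#' @return List of logicals `PM`, `CS`, `XC`, `ShG`, `is_surface`.
#' @export
classify_surface <- function(terms, part_counts = rep(NA_integer_, length(terms))) {
  t <- tolower(terms)
  pm <- any(grepl("plasma membrane", t, fixed = TRUE))
  cs <- any(grepl("cell surface", t, fixed = TRUE))
  xc <- any(grepl("extracellular", t, fixed = TRUE))
  integral <- grepl("integral to membrane", t, fixed = TRUE) |
    grepl("integral component of membrane", t, fixed = TRUE)
  short <- integral & !is.na(part_counts) & part_counts %in% c(4L, 5L)
  # ShG requires that no *other* term names a specific compartment
  generic <- integral | t %in% c("membrane", "cellular_component", "cellular component")
  shg <- any(short) && all(generic)
  list(PM = pm, CS = cs, XC = xc, ShG = shg,
       is_surface = pm || cs || xc || shg)
}

#' Filter a quantified protein set to the surfaceome
#'
#' Applies [classify_surface()] per protein and returns the surface subset
#' with the category accounting used in the study: per-flag counts and the
#' count of proteins annotated extracellular but neither plasma membrane
#' nor cell surface.
#'
#' @param accessions Character vector of quantified protein accessions
#'   (unique).
#' @param annot Annotation data frame from [read_annotation_table()];
#'   proteins absent from it get all flags false.
#' @return List with `calls` (data frame: accession, PM, CS, XC, ShG,
#'   is_surface), `surface` (accessions called surface) and `counts`
#'   (n_total, n_surface, PM, CS, XC, ShG, XC_not_PM_CS).
#' @export
filter_surfaceome <- function(accessions, annot) {
  if (anyDuplicated(accessions)) {
    stop("duplicate accession(s): ",
         paste(unique(accessions[duplicated(accessions)]), collapse = ", "))
  }
  idx <- match(accessions, annot$accession)
  calls <- do.call(rbind, lapply(seq_along(accessions), function(i) {
    if (is.na(idx[i])) {
      fl <- list(PM = FALSE, CS = FALSE, XC = FALSE, ShG = FALSE, is_surface = FALSE)
    } else {
      fl <- classify_surface(annot$go_cc_terms[[idx[i]]],
                             annot$term_part_counts[[idx[i]]])
    }
    data.frame(accession = accessions[i], as.data.frame(fl),
               stringsAsFactors = FALSE)
  }))
  if (is.null(calls)) {
    calls <- data.frame(accession = character(0), PM = logical(0), CS = logical(0),
                        XC = logical(0), ShG = logical(0), is_surface = logical(0))
  }
  counts <- c(
    n_total = nrow(calls),
    n_surface = sum(calls$is_surface),
    PM = sum(calls$PM), CS = sum(calls$CS), XC = sum(calls$XC),
    ShG = sum(calls$ShG),
    XC_not_PM_CS = sum(calls$XC & !calls$PM & !calls$CS)
  )
  list(calls = calls, surface = calls$accession[calls$is_surface],
       counts = counts)
}
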