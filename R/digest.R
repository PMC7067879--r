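#' In-silico tryptic digestion
#'
#' Trypsin cleaves C-terminal to K or R except when the next residue is
#' proline; zero missed cleavages. U (selenocysteine) and X are tolerated
#' but never cleaved after.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet (plus U/X).
#' @return Character vector of peptides in sequence order; their
#'   concatenation equals the input.
#' @examples
#' digest_trypsin("AAKRPAAK")  # c("AAK", "RPAAK")
#' @export
digest_trypsin <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty string")
  }
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYUX]", sequence)
  if (bad > 0L) {
    stop("illegal character '", substr(sequence, bad, bad), "' at position ", bad)
  }
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut < n & res[cut + 1L] != "P"]
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  substring(sequence, starts, ends)
}

#' Count theoretically observable tryptic peptides
#'
#' Observable peptides are those with length in `[len_min, len_max]`
#' (default 7-30 residues, both ends inclusive) — the denominator of the
#' iBAQ-style abundance estimate.
#'
#' @param peptides Character vector from [digest_trypsin()].
#' @param len_min,len_max Inclusive length bounds.
#' @return Integer count.
#' @export
count_observable <- function(peptides, len_min = 7L, len_max = 30L) {
  len <- nchar(peptides)
  sum(len >= len_min & len <= len_max)
}

#' iBAQ-style abundance estimate
#'
#' Summed MS1 maximum precursor intensity over all matching peptides,
#' divided by the number of theoretically observable tryptic peptides.
#'
#' @param summed_ms1 Non-negative summed MS1 intensity.
#' @param observable_count Positive integer.
#' @return The abundance estimate.
#' @export
ibaq <- function(summed_ms1, observable_count) {
  stopifnot(summed_ms1 >= 0)
  if (any(observable_count < 1L)) stop("observable_count must be >= 1")
  summed_ms1 / observable_count
}

#' iBAQ abundance table from PSMs and protein sequences
#'
#' For each protein group, MS1 maximum precursor intensities are summed over
#' distinct matching peptides (a peptide observed in several PSMs counts
#' once, at its maximum MS1 intensity) and divided by the observable-peptide
#' count from in-silico digestion of the group representative's sequence.
#' Groups whose sequence yields no observable peptide are flagged
#' non-estimable and excluded from contribution percentages with a warning.
#'
#' @param psms Kept (filtered) `surfprot_psms`.
#' @param inference Result of [assemble_parsimony()].
#' @param fasta Named character vector accession -> sequence.
#' @param len_min,len_max Observable length bounds.
#' @return Data frame: `accession`, `summed_ms1`, `observable_count`,
#'   `ibaq`, `contribution_pct` (over estimable proteins; sums to 100),
#'   `estimable`.
#' @export
ibaq_table <- function(psms, inference, fasta, len_min = 7L, len_max = 30L) {
  grp <- inference$assignment[psms$peptide]
  pep_ms1 <- stats::aggregate(ms1_max_intensity ~ peptide, data = psms, FUN = max)
  pep_grp <- inference$assignment[pep_ms1$peptide]
  summed <- tapply(pep_ms1$ms1_max_intensity, pep_grp, sum)
  ids <- inference$groups$group_id
  out <- data.frame(accession = ids,
                    summed_ms1 = as.numeric(summed[ids]),
                    stringsAsFactors = FALSE)
  out$summed_ms1[is.na(out$summed_ms1)] <- 0
  seqs <- fasta[ids]
  if (anyNA(seqs)) {
    stop("no sequence in FASTA for group accession(s): ",
         paste(utils::head(ids[is.na(seqs)], 5L), collapse = ", "))
  }
  out$observable_count <- vapply(seqs, function(s) {
    count_observable(digest_trypsin(s), len_min, len_max)
  }, 0L)
  out$estimable <- out$observable_count >= 1L
  if (any(!out$estimable)) {
    warning(sum(!out$estimable),
            " protein(s) with no observable tryptic peptide; excluded from contributions")
  }
  out$ibaq <- ifelse(out$estimable, out$summed_ms1 / out$observable_count, NA_real_)
  tot <- sum(out$ibaq[out$estimable])
  out$contribution_pct <- ifelse(out$estimable, 100 * out$ibaq / tot, NA_real_)
  out
}

#' Relative contributions to the surface proteome
#'
#' Converts abundance estimates into percentage contributions. An optional
#' grouping (e.g. summing all MHC class I alleles into one entry, and class
#' II into another, to absorb donor-specific allele differences) is applied
#' before percentages. For display, entries contributing less than
#' `other_below` percent are aggregated into `"other"`; the full table is
#' always returned alongside.
#'
#' @param estimates Data frame with `accession` and `ibaq` (non-estimable
#'   rows dropped).
#' @param grouping Optional named character vector accession -> class label;
#'   unlisted accessions keep their own accession as label.
#' @param other_below Display threshold in percent (default 1).
#' @return List with `full` (label, ibaq, contribution_pct; sums to 100)
#'   and `display` (entries below the threshold pooled into "other").
#' @export
relative_contributions <- function(estimates, grouping = NULL, other_below = 1) {
  est <- estimates[!is.na(estimates$ibaq), , drop = FALSE]
  if (!nrow(est)) stop("no estimable proteins")
  label <- est$accession
  if (!is.null(grouping)) {
    hit <- label %in% names(grouping)
    label[hit] <- grouping[label[hit]]
  }
  ib <- tapply(est$ibaq, label, sum)
  full <- data.frame(label = names(ib), ibaq = as.numeric(ib),
                     stringsAsFactors = FALSE)
  full$contribution_pct <- 100 * full$ibaq / sum(full$ibaq)
  full <- full[order(-full$contribution_pct), , drop = FALSE]
  rownames(full) <- NULL
  small <- full$contribution_pct < other_below
  display <- full[!small, , drop = FALSE]
  if (any(small)) {
    display <- rbind(display, data.frame(
      label = "other", ibaq = sum(full$ibaq[small]),
      contribution_pct = sum(full$contribution_pct[small])))
  }
  rownames(display) <- NULL
  list(full = full, display = display)
}

#' MHC class grouping map
#'
#' Heavy/alpha and beta chains of the classical MHC molecules, keyed by gene
#' symbol: class I covers HLA-A/B/C/E/F/G heavy chains, class II the
#' HLA-DR/DQ/DP alpha and beta chains. Beta-2-microglobulin is not part of
#' the class I sum.
#'
#' @param genes Character vector of gene symbols.
#' @return Named character vector (gene -> "MHC class I"/"MHC class II") for
#'   the MHC genes among `genes`.
#' @export
mhc_grouping <- function(genes) {
  class1 <- c("HLA-A", "HLA-B", "HLA-C", "HLA-E", "HLA-F", "HLA-G")
  class2 <- paste0("HLA-D", c("RA", "RB1", "RB3", "RB4", "RB5",
                              "QA1", "QA2", "QB1", "QB2",
                              "PA1", "PB1", "PB2"))
  out <- c(stats::setNames(rep("MHC class I", length(class1)), class1),
           stats::setNames(rep("MHC class II", length(class2)), class2))
  out[names(out) %in% genes]
}

#' Inter-donor coefficient of variation profile
#'
#' Percent CV per protein across donor channels, computed on
#' loading-factor-normalized channel S:N (each column divided by its
#' loading factor first, so pipetting differences between channels do not
#' inflate the biological CV). Reports the fraction of proteins below a
#' threshold and the Spearman correlation between log abundance and %CV
#' (a check that low-abundance proteins are not systematically noisier).
#'
#' @param sn Numeric matrix proteins x donor channels (>= 2 columns).
#' @param cv_threshold Percent threshold (default 30).
#' @param normalize Apply loading-factor normalization first (default TRUE).
#' @return List with `cv` (per protein; NA where the mean is not positive),
#'   `fraction_below`, `abundance_cv_cor`, `threshold`.
#' @export
donor_cv <- function(sn, cv_threshold = 30, normalize = TRUE) {
  stopifnot(is.matrix(sn), ncol(sn) >= 2L)
  if (normalize) {
    f <- loading_normalization_factors(sn)$factors
    sn <- sweep(sn, 2L, f, `/`)
  }
  mu <- rowMeans(sn)
  sdv <- apply(sn, 1L, stats::sd)
  cv <- ifelse(mu > 0, 100 * sdv / mu, NA_real_)
  if (anyNA(cv)) warning(sum(is.na(cv)), " protein(s) with zero mean excluded from %CV")
  ok <- !is.na(cv)
  list(cv = cv,
       fraction_below = mean(cv[ok] < cv_threshold),
       abundance_cv_cor = suppressWarnings(
         stats::cor(log(mu[ok & mu > 0]), cv[ok & mu > 0], method = "spearman")),
       threshold = cv_threshold)
}
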