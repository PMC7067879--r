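#' Extract TMT reporter ions from an MS3 peak list
#'
#' Scans a window (default 0.003 Th) around each channel's theoretical m/z;
#' among candidate peaks the maximum-intensity peak is taken, ties broken by
#' proximity to the theoretical mass (`rule = "nearest"` inverts the
#' priority). Channels with no candidate peak are missing. S:N is intensity
#' divided by the scan noise baseline.
#'
#' @param peaks Data frame with numeric columns `mz` (Th, > 0) and
#'   `intensity` (>= 0); may have zero rows.
#' @param noise Scan noise baseline (> 0).
#' @param theoretical_mz Named numeric vector of reporter m/z per channel,
#'   e.g. [tmt_reporter_mz()] subset to the design.
#' @param window Half-width of the match window in Th (> 0).
#' @param rule `"max_intensity"` (default) or `"nearest"`.
#' @return List with named vectors `intensity` and `sn` (NA = missing).
#' @export
extract_reporters <- function(peaks, noise, theoretical_mz, window = 0.003,
                              rule = c("max_intensity", "nearest")) {
  rule <- match.arg(rule)
  if (!is.numeric(window) || window <= 0) stop("window must be positive")
  stopifnot(is.numeric(noise), noise > 0)
  if (nrow(peaks) > 0L) stopifnot(all(peaks$mz > 0), all(peaks$intensity >= 0))
  intensity <- rep(NA_real_, length(theoretical_mz))
  names(intensity) <- names(theoretical_mz)
  for (ch in names(theoretical_mz)) {
    delta <- abs(peaks$mz - theoretical_mz[[ch]])
    cand <- which(delta <= window)
    if (!length(cand)) next
    # order by the primary criterion, break ties with the secondary one
    o <- if (rule == "max_intensity") {
      cand[order(-peaks$intensity[cand], delta[cand])]
    } else {
      cand[order(delta[cand], -peaks$intensity[cand])]
    }
    intensity[[ch]] <- peaks$intensity[o[1L]]
  }
  list(intensity = intensity, sn = intensity / noise)
}

#' PSM quality and isolation-specificity filtering
#'
#' Applies the MS3 quality rules: a PSM is dropped when it has no reporter
#' measurements at all (`drop_no_ms3`), when more than
#' `max_missing_channels` channels are missing (`drop_missing_channels`),
#' when the combined (summed) reporter S:N falls below `sn_threshold`
#' (`drop_low_sn`; 135 for the 9-plex, 45 for the 3-plex — a PSM exactly at
#' the floor is kept), or when isolation specificity falls below
#' `isolation_specificity_min` (`drop_low_specificity`).
#'
#' @param psms A `surfprot_psms` table.
#' @param cfg A `surfprot_config`.
#' @param design Sample design (defaults to the table's attached design).
#' @return List with `kept` (the surviving PSM table), `disposition`
#'   (factor, one level per PSM) and `report` (named counts; the counts sum
#'   to the input size).
#' @export
filter_psms <- function(psms, cfg, design = attr(psms, "design")) {
  design <- as_study_design(design)
  if (plex_size(design) != cfg$plex_size) {
    stop("config plex_size (", cfg$plex_size, ") does not match design (",
         plex_size(design), ")")
  }
  sn <- psm_sn_matrix(psms, design)
  n_missing <- rowSums(is.na(sn))
  combined <- rowSums(sn, na.rm = TRUE)
  disposition <- rep("kept", nrow(psms))
  disposition[psms$isolation_specificity < cfg$isolation_specificity_min] <-
    "drop_low_specificity"
  disposition[combined < cfg$sn_threshold] <- "drop_low_sn"
  disposition[n_missing > cfg$max_missing_channels] <- "drop_missing_channels"
  disposition[n_missing == ncol(sn)] <- "drop_no_ms3"
  disposition <- factor(disposition, levels = c(
    "kept", "drop_missing_channels", "drop_low_sn", "drop_low_specificity",
    "drop_no_ms3"))
  kept <- psms[disposition == "kept", , drop = FALSE]
  attr(kept, "design") <- design
  class(kept) <- class(psms)
  list(kept = kept, disposition = disposition, report = table(disposition))
}

#' @rdname filter_psms
#' @param min_spec Minimum isolation specificity in [0,1].
#' @return `filter_isolation_specificity`: character vector of dispositions
#'   (`"kept"` / `"drop_low_specificity"`).
#' @export
filter_isolation_specificity <- function(psms, min_spec) {
  spec <- psms$isolation_specificity
  if (any(is.na(spec) | spec < 0 | spec > 1)) {
    stop("isolation_specificity outside [0,1]")
  }
  ifelse(spec < min_spec, "drop_low_specificity", "kept")
}

#' Target-decoy FDR threshold
#'
#' Finds the smallest score threshold t such that
#' (#decoys with score >= t) / (#targets with score >= t) does not exceed
#' `level`; records scoring exactly t are kept. When no threshold achieves
#' the level an empty result is returned with a warning.
#'
#' @param score Numeric scores.
#' @param is_decoy Logical, same length.
#' @param level FDR level in (0, 1].
#' @return List with `threshold`, `keep` (logical over the input: target
#'   records at/above threshold) and `fdr` (achieved decoy/target ratio).
#' @export
fdr_filter <- function(score, is_decoy, level) {
  stopifnot(length(score) == length(is_decoy), level > 0, level <= 1)
  if (!length(score)) return(list(threshold = Inf, keep = logical(0), fdr = 0))
  o <- order(score, decreasing = TRUE)
  dec <- cumsum(is_decoy[o])
  tar <- cumsum(!is_decoy[o])
  s <- score[o]
  # candidate thresholds: last index of each tied score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  ok <- last[tar[last] > 0 & dec[last] / tar[last] <= level]
  if (!length(ok)) {
    warning("no score threshold achieves FDR <= ", level)
    return(list(threshold = Inf, keep = rep(FALSE, length(score)), fdr = NA_real_))
  }
  i <- max(ok)  # lowest feasible threshold keeps the most targets
  threshold <- s[i]
  list(threshold = threshold,
       keep = score >= threshold & !is_decoy,
       fdr = dec[i] / tar[i])
}

#' Peptide- then protein-level FDR filtering of a PSM table
#'
#' Scores are reduced to the best (maximum) score per peptide and the
#' target-decoy threshold applied at `fdr_peptide`; surviving peptides are
#' then reduced to the best score per protein accession and thresholded at
#' `fdr_protein`. Kept PSMs are target PSMs whose peptide passed and that
#' reference at least one passing protein.
#'
#' @inheritParams filter_psms
#' @return List with `psms` (kept target PSMs), `peptide` and `protein`
#'   (each a [fdr_filter()] result plus the number kept).
#' @export
fdr_filter_psms <- function(psms, cfg) {
  pep_best <- stats::aggregate(score ~ peptide + is_decoy, data = psms, FUN = max)
  pep_res <- fdr_filter(pep_best$score, pep_best$is_decoy, cfg$fdr_peptide)
  pep_pass <- pep_best$score >= pep_res$threshold  # targets and decoys alike
  kept_pep <- pep_best[pep_pass, , drop = FALSE]

  # protein level on surviving peptides: best peptide score per accession
  acc_by_pep <- lapply(split(psms$proteins, psms$peptide),
                       function(p) unique(unlist(strsplit(p, ";", fixed = TRUE))))
  accs <- acc_by_pep[kept_pep$peptide]
  prot <- data.frame(
    accession = unlist(accs, use.names = FALSE),
    score = rep(kept_pep$score, lengths(accs)),
    is_decoy = rep(kept_pep$is_decoy, lengths(accs)),
    stringsAsFactors = FALSE
  )
  if (!nrow(prot)) {
    empty <- psms[0, , drop = FALSE]
    attr(empty, "design") <- attr(psms, "design")
    return(list(psms = empty, peptide = pep_res, protein = NULL))
  }
  prot_best <- stats::aggregate(score ~ accession + is_decoy, data = prot, FUN = max)
  prot_res <- fdr_filter(prot_best$score, prot_best$is_decoy, cfg$fdr_protein)
  prot_pass <- prot_best$accession[prot_best$score >= prot_res$threshold &
                                     !prot_best$is_decoy]

  pep_keep <- kept_pep$peptide[!kept_pep$is_decoy]
  hits_kept_protein <- vapply(strsplit(psms$proteins, ";", fixed = TRUE),
                              function(a) any(a %in% prot_pass), TRUE)
  keep_rows <- !psms$is_decoy & psms$peptide %in% pep_keep & hits_kept_protein
  kept <- psms[keep_rows, , drop = FALSE]
  attr(kept, "design") <- attr(psms, "design")
  class(kept) <- class(psms)
  list(psms = kept,
       peptide = c(pep_res[c("threshold", "fdr")], n_kept = sum(pep_res$keep)),
       protein = c(prot_res[c("threshold", "fdr")], n_kept = length(prot_pass)))
}

#' Parsimony protein inference (greedy minimal set cover)
#'
#' Produces the smallest protein set necessary to account for all observed
#' peptides: proteins indistinguishable by peptide evidence are merged into
#' one group, groups holding a peptide no other group can explain (anchor
#' proteins, part of every admissible cover) are selected first, and the
#' remaining groups are selected greedily by the number of unexplained
#' peptides they cover (ties: larger total peptide set, then lexicographic
#' accession). Every peptide is assigned to exactly one selected group — the
#' group that first covered it.
#'
#' @param peptide_proteins Named list: peptide sequence -> character vector
#'   of protein accessions (each non-empty).
#' @return List with `groups` (data frame: `group_id`, `members`
#'   ';'-separated, `n_peptides`) and `assignment` (named character vector,
#'   peptide -> group_id).
#' @export
assemble_parsimony <- function(peptide_proteins) {
  if (!length(peptide_proteins)) {
    return(list(groups = data.frame(group_id = character(0),
                                    members = character(0),
                                    n_peptides = integer(0)),
                assignment = character(0)))
  }
  if (any(lengths(peptide_proteins) == 0L)) {
    stop("every peptide must map to at least one protein")
  }
  peptides <- names(peptide_proteins)
  prot_peps <- split(
    rep(peptides, lengths(peptide_proteins)),
    unlist(peptide_proteins)
  )
  prot_peps <- lapply(prot_peps, function(p) sort(unique(p)))
  # merge proteins with identical peptide evidence
  key <- vapply(prot_peps, paste, "", collapse = "\r")
  grp_members <- split(names(prot_peps), key)
  grp_members <- lapply(grp_members, sort)
  grp_id <- vapply(grp_members, `[`, "", 1L)  # lexicographic representative
  grp_peps <- prot_peps[grp_id]
  names(grp_members) <- grp_id

  # greedy cover with incrementally maintained cover counts
  pep_idx <- stats::setNames(seq_along(peptides), peptides)
  grp_ids <- names(grp_peps)
  grp_pep_i <- lapply(grp_peps, function(p) unname(pep_idx[p]))
  pep2grp <- vector("list", length(peptides))
  for (gi in seq_along(grp_pep_i)) {
    for (pi in grp_pep_i[[gi]]) pep2grp[[pi]] <- c(pep2grp[[pi]], gi)
  }
  cover <- lengths(grp_pep_i)
  total <- lengths(grp_pep_i)
  explained <- rep(FALSE, length(peptides))
  chosen <- character(0)
  assignment <- stats::setNames(rep(NA_character_, length(peptides)), peptides)
  # groups holding a uniquely-explained peptide belong to every possible
  # cover; select them first (anchor proteins), then fall back to greedy
  forced <- sort(unique(grp_ids[unlist(pep2grp[lengths(pep2grp) == 1L])]))
  for (gid in forced) {
    g <- match(gid, grp_ids)
    newly <- grp_pep_i[[g]][!explained[grp_pep_i[[g]]]]
    assignment[newly] <- gid
    chosen <- c(chosen, gid)
    explained[newly] <- TRUE
    for (pi in newly) for (gi in pep2grp[[pi]]) cover[gi] <- cover[gi] - 1L
    cover[g] <- 0L
  }
  while (!all(explained)) {
    best <- which(cover == max(cover))
    if (length(best) > 1L) {
      best <- best[total[best] == max(total[best])]
      best <- best[order(grp_ids[best])]
    }
    g <- best[1L]
    newly <- grp_pep_i[[g]][!explained[grp_pep_i[[g]]]]
    assignment[newly] <- grp_ids[g]
    chosen <- c(chosen, grp_ids[g])
    explained[newly] <- TRUE
    for (pi in newly) for (gi in pep2grp[[pi]]) cover[gi] <- cover[gi] - 1L
    cover[g] <- 0L
  }
  groups <- data.frame(
    group_id = chosen,
    members = vapply(grp_members[chosen], paste, "", collapse = ";"),
    n_peptides = as.integer(table(factor(assignment, levels = chosen))[chosen]),
    stringsAsFactors = FALSE
  )
  rownames(groups) <- NULL
  list(groups = groups, assignment = assignment)
}

#' Sum reporter signal to the protein level
#'
#' Per protein group, the channel S:N values of all matching PSMs are summed
#' (missing channels contribute zero), weighting peptides by their own
#' reporter yield. Shared peptides contribute only to the parsimony group
#' they are assigned to.
#'
#' @inheritParams filter_psms
#' @param inference Result of [assemble_parsimony()].
#' @param gene_map Optional named character vector accession -> gene symbol.
#' @return Protein quantitation data frame: `accession` (group id), `gene`,
#'   `n_psms`, `n_peptides`, `peptides` (';'-joined), and one `sn_<channel>`
#'   column per design channel.
#' @export
sum_protein_reporters <- function(psms, inference, design = attr(psms, "design"),
                                  gene_map = NULL) {
  design <- as_study_design(design)
  grp <- inference$assignment[psms$peptide]
  if (anyNA(grp)) {
    stop("PSM peptide(s) not assigned to any protein group: ",
         paste(utils::head(unique(psms$peptide[is.na(grp)]), 5L), collapse = ", "))
  }
  sn <- psm_sn_matrix(psms, design)
  sn[is.na(sn)] <- 0
  ids <- inference$groups$group_id
  agg <- rowsum(sn, group = factor(grp, levels = ids), na.rm = FALSE)
  out <- data.frame(
    accession = ids,
    gene = if (is.null(gene_map)) ids else unname(gene_map[ids]),
    n_psms = as.integer(table(factor(grp, levels = ids))),
    stringsAsFactors = FALSE
  )
  peps <- split(psms$peptide, factor(grp, levels = ids))
  out$n_peptides <- vapply(peps, function(p) length(unique(p)), 0L)
  out$peptides <- vapply(peps, function(p) paste(sort(unique(p)), collapse = ";"), "")
  snc <- as.data.frame(agg)
  names(snc) <- paste0("sn_", design$channel)
  out <- cbind(out, snc)
  out <- out[out$n_psms >= 1L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "design") <- design
  out
}

#' Fractional (max = 1) TMT signal per protein
#'
#' Each protein's channel S:N vector is divided by its maximum, so the
#' brightest channel is exactly 1 — correcting for differences in peptide
#' numbers between proteins before cross-subset comparison.
#'
#' @param pq Protein quantitation table from [sum_protein_reporters()].
#' @param design Sample design.
#' @return `pq` with added `frac_<channel>` columns.
#' @export
fractional_signal <- function(pq, design = attr(pq, "design")) {
  design <- as_study_design(design)
  sn <- as.matrix(pq[paste0("sn_", design$channel)])
  mx <- apply(sn, 1L, max)
  if (any(mx <= 0)) {
    stop("protein(s) with no positive channel signal: ",
         paste(utils::head(pq$accession[mx <= 0], 5L), collapse = ", "))
  }
  frac <- sn / mx
  colnames(frac) <- paste0("frac_", design$channel)
  out <- cbind(pq, as.data.frame(frac))
  attr(out, "design") <- design
  out
}

#' Per-channel loading normalization factors
#'
#' Checks that peptide loading was similar across TMT channels: each
#' channel's factor is its total signal divided by the mean channel total.
#' The check passes when every factor lies strictly inside (0.33, 3.0); the
#' data themselves are reported unscaled — this mirrors a loading check, not
#' a correction.
#'
#' @param sn Numeric matrix of channel S:N (PSMs or proteins x channels).
#' @return List with `factors` (named), `pass` (logical) and `totals`.
#' @export
loading_normalization_factors <- function(sn) {
  totals <- colSums(sn, na.rm = TRUE)
  if (all(totals == 0)) stop("all channel totals are zero")
  factors <- totals / mean(totals)
  list(factors = factors, pass = all(factors > 0.33 & factors < 3.0),
       totals = totals)
}

#' Full PSM-to-protein quantitation chain
#'
#' Runs quality filtering, peptide- and protein-level target-decoy FDR,
#' parsimony assembly, protein reporter summation and fractional signals in
#' the study's order.
#'
#' @inheritParams filter_psms
#' @param gene_map Optional accession -> gene map.
#' @return List with `proteins` (quant table incl. fractional columns),
#'   `filter_report`, `fdr` (peptide/protein summaries), `inference`, and
#'   `loading` (normalization-factor check on the protein S:N matrix).
#' @export
quantify_proteins <- function(psms, cfg, design = attr(psms, "design"),
                              gene_map = NULL) {
  design <- as_study_design(design)
  flt <- filter_psms(psms, cfg, design)
  fdr <- fdr_filter_psms(flt$kept, cfg)
  kept <- fdr$psms
  if (!nrow(kept)) stop("no PSMs survive filtering")
  pep_map <- lapply(split(kept$proteins, kept$peptide),
                    function(p) unique(unlist(strsplit(p, ";", fixed = TRUE))))
  inference <- assemble_parsimony(pep_map)
  pq <- sum_protein_reporters(kept, inference, design, gene_map = gene_map)
  pq <- fractional_signal(pq, design)
  loading <- loading_normalization_factors(
    as.matrix(pq[paste0("sn_", design$channel)]))
  list(proteins = pq, psms = kept, filter_report = flt$report,
       fdr = fdr[c("peptide", "protein")], inference = inference,
       loading = loading)
}
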