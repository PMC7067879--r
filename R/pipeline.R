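#' Run the full post-search pipeline and write per-stage outputs
#'
#' Executes the quantitation chain (quality filters, target-decoy FDR,
#' parsimony assembly, reporter summation, fractional signals, loading
#' check), the surfaceome filter, iBAQ abundance estimation and — for
#' multi-subset designs — the cross-subset analyses (PCA, k-means scan and
#' elbow, clustering, BH-corrected pairwise tests, marker calls). Each
#' stage's table is written as TSV under `out_dir` together with a run log
#' of record counts and filter tallies.
#'
#' @param psms A `surfprot_psms` table (see [read_psm_table()]).
#' @param fasta Named sequences (see [read_fasta()]).
#' @param annot Annotation table (see [read_annotation_table()]).
#' @param design A `surfprot_design`.
#' @param cfg A `surfprot_config` (defaults to the design's plex).
#' @param out_dir Output directory; created if needed.
#' @param k Cluster count for the final clustering; `NULL` (default) uses
#'   the detected elbow.
#' @param q_cutoff Marker significance cutoff.
#' @param gene_map Optional accession -> gene map.
#' @return Invisibly, a list of all stage results.
#' @export
run_pipeline <- function(psms, fasta, annot, design,
                         cfg = pipeline_config(plex_size = plex_size(design)),
                         out_dir, k = NULL, q_cutoff = 0.05, gene_map = NULL) {
  design <- as_study_design(design)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(paste0(format(Sys.time(), "%H:%M:%S "), ...,
                                   "\n"), file = log_path, append = TRUE)
  cat("", file = log_path)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }

  logf("input PSMs: ", nrow(psms), " (", sum(psms$is_decoy), " decoys)")
  quant <- quantify_proteins(psms, cfg, design, gene_map = gene_map)
  for (nm in names(quant$filter_report)) {
    logf("quality filter ", nm, ": ", quant$filter_report[[nm]])
  }
  logf("peptide FDR threshold ", signif(quant$fdr$peptide$threshold, 4),
       " (achieved ", signif(quant$fdr$peptide$fdr, 3), "), kept ",
       quant$fdr$peptide$n_kept, " peptides")
  logf("protein FDR threshold ", signif(quant$fdr$protein$threshold, 4),
       " (achieved ", signif(quant$fdr$protein$fdr, 3), "), kept ",
       quant$fdr$protein$n_kept, " proteins")
  logf("protein groups quantified: ", nrow(quant$proteins))
  logf("loading factors ", paste(signif(quant$loading$factors, 3),
                                 collapse = " "),
       " -> ", if (quant$loading$pass) "pass" else "FAIL")
  tsv(quant$proteins[, setdiff(names(quant$proteins), "peptides")],
      "protein_quant.tsv")
  tsv(data.frame(disposition = names(quant$filter_report),
                 n = as.integer(quant$filter_report)), "filter_report.tsv")

  surf <- filter_surfaceome(quant$proteins$accession, annot)
  logf("surfaceome: ", surf$counts[["n_surface"]], " of ",
       surf$counts[["n_total"]], " proteins (PM ", surf$counts[["PM"]],
       ", CS ", surf$counts[["CS"]], ", XC ", surf$counts[["XC"]],
       ", ShG ", surf$counts[["ShG"]], ", XC-only ",
       surf$counts[["XC_not_PM_CS"]], ")")
  tsv(surf$calls, "surface_calls.tsv")

  ib <- ibaq_table(quant$psms, quant$inference, fasta,
                   cfg$peptide_len_min, cfg$peptide_len_max)
  surface_ib <- ib[ib$accession %in% surf$surface & ib$estimable, , drop = FALSE]
  contrib <- relative_contributions(surface_ib)
  tsv(ib, "abundance.tsv")
  tsv(contrib$full, "contributions.tsv")
  logf("abundance estimates: ", sum(ib$estimable), " estimable proteins; top ",
       contrib$full$label[1], " at ",
       signif(contrib$full$contribution_pct[1], 3), "%")

  results <- list(quant = quant, surface = surf, abundance = ib,
                  contributions = contrib)

  pq <- quant$proteins[quant$proteins$accession %in% surf$surface, , drop = FALSE]
  attr(pq, "design") <- design
  if (length(unique(design$subset)) >= 3L && nrow(pq) > cfg$kmax) {
    m <- profile_matrix(pq, design)
    pca <- pca_samples(m)
    tsv(data.frame(sample = rownames(pca$scores), pca$scores), "pca_scores.tsv")
    scan <- kmeans_scan(m, kmax = cfg$kmax, restarts = cfg$kmeans_restarts,
                        seed = cfg$random_seed)
    chosen <- detect_elbow(scan)
    if (is.null(k)) k <- max(chosen, 2L)
    logf("k-means scan 1..", cfg$kmax, ": elbow at k = ", chosen,
         "; clustering with k = ", k)
    tsv(scan, "elbow_curve.tsv")
    cl <- kmeans_cluster(m, k, design, restarts = cfg$kmeans_restarts,
                         seed = cfg$random_seed)
    tsv(data.frame(accession = names(cl$cluster), cluster = cl$cluster),
        "clusters.tsv")
    tsv(cl$summary, "cluster_summary.tsv")
    tests <- pairwise_tests(m, design)
    tsv(tests, "subset_tests.tsv")
    markers <- rank_markers(cl, tests, m, design, q_cutoff = q_cutoff)
    tsv(markers, "markers.tsv")
    logf("markers called at q < ", q_cutoff, ": ", nrow(markers))
    tree <- hierarchical_cluster(m, metric = cfg$distance_metric)
    writeLines(tree_newick(tree), file.path(out_dir, "protein_tree.nwk"))
    results <- c(results, list(pca = pca, scan = scan, chosen_k = chosen,
                               clusters = cl, tests = tests, markers = markers,
                               tree = tree))
  } else if (length(unique(design$subset)) == 1L) {
    # classical-only arm: inter-donor variability on normalized S:N
    sn <- as.matrix(pq[paste0("sn_", design$channel)])
    rownames(sn) <- pq$accession
    cv <- donor_cv(sn)
    tsv(data.frame(accession = pq$accession, cv_pct = cv$cv), "donor_cv.tsv")
    logf(signif(100 * cv$fraction_below, 3), "% of proteins below ",
         cv$threshold, "% CV")
    results <- c(results, list(cv = cv))
  }
  invisible(results)
}
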