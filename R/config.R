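#' Pipeline configuration
#'
#' Collects the tunable thresholds of the quantitation chain. Defaults follow
#' the study settings: a combined reporter S:N floor of 15 per channel (135
#' for the 9-plex, 45 for the 3-plex), at least one measured channel, a 0.70
#' isolation-specificity minimum, 1% peptide- and protein-level FDR,
#' observable tryptic peptides of 7-30 residues, and a k-means scan to 20
#' classes.
#'
#' @param plex_size Number of TMT channels (3 or 9 in the study).
#' @param sn_threshold Combined (summed over channels) S:N floor per PSM.
#'   Default `15 * plex_size`, reproducing the stated 135/45 floors.
#' @param max_missing_channels Maximum missing reporter channels tolerated;
#'   default `plex_size - 1` (at least one measured channel).
#' @param isolation_specificity_min Minimum isolation specificity in [0,1].
#' @param fdr_peptide,fdr_protein Target-decoy FDR levels.
#' @param peptide_len_min,peptide_len_max Observable tryptic peptide length
#'   bounds (inclusive).
#' @param kmax Largest class count in the k-means scan.
#' @param kmeans_restarts Restarts per k (k-means++ seeding).
#' @param random_seed Seed for stochastic steps.
#' @param distance_metric `"euclidean"` or `"uncentered_correlation"` for
#'   hierarchical clustering.
#' @return A `surfprot_config` list.
#' @export
pipeline_config <- function(plex_size = 9L,
                            sn_threshold = 15 * plex_size,
                            max_missing_channels = plex_size - 1L,
                            isolation_specificity_min = 0.70,
                            fdr_peptide = 0.01,
                            fdr_protein = 0.01,
                            peptide_len_min = 7L,
                            peptide_len_max = 30L,
                            kmax = 20L,
                            kmeans_restarts = 50L,
                            random_seed = 1L,
                            distance_metric = c("euclidean", "uncentered_correlation")) {
  distance_metric <- match.arg(distance_metric)
  cfg <- list(
    plex_size = as.integer(plex_size),
    sn_threshold = sn_threshold,
    max_missing_channels = as.integer(max_missing_channels),
    isolation_specificity_min = isolation_specificity_min,
    fdr_peptide = fdr_peptide,
    fdr_protein = fdr_protein,
    peptide_len_min = as.integer(peptide_len_min),
    peptide_len_max = as.integer(peptide_len_max),
    kmax = as.integer(kmax),
    kmeans_restarts = as.integer(kmeans_restarts),
    random_seed = as.integer(random_seed),
    distance_metric = distance_metric
  )
  validate_config(cfg)
  class(cfg) <- "surfprot_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$plex_size >= 1L,
    cfg$sn_threshold >= 0,
    cfg$max_missing_channels >= 0L,
    cfg$isolation_specificity_min >= 0, cfg$isolation_specificity_min <= 1,
    cfg$fdr_peptide > 0, cfg$fdr_peptide <= 1,
    cfg$fdr_protein > 0, cfg$fdr_protein <= 1,
    cfg$peptide_len_min <= cfg$peptide_len_max,
    cfg$kmax >= 2L,
    cfg$kmeans_restarts >= 1L
  )
  invisible(cfg)
}

#' Read / write a flat key-value configuration file
#'
#' Format: one `key = value` pair per line; `#` starts a comment. Keys
#' mirror [pipeline_config()] arguments; absent keys take their defaults.
#'
#' @param path File path.
#' @param plex_size Used for defaults when the file omits plex-dependent keys.
#' @rdname config_io
#' @export
read_config <- function(path, plex_size = 9L) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  args <- list(plex_size = plex_size)
  numeric_keys <- c("plex_size", "sn_threshold", "max_missing_channels",
                    "isolation_specificity_min", "fdr_peptide", "fdr_protein",
                    "peptide_len_min", "peptide_len_max", "kmax",
                    "kmeans_restarts", "random_seed")
  for (k in names(vals)) {
    if (k %in% numeric_keys) {
      args[[k]] <- as.numeric(vals[[k]])
    } else if (k == "distance_metric") {
      args[[k]] <- vals[[k]]
    } else {
      stop("unknown config key: ", k)
    }
  }
  do.call(pipeline_config, args)
}

#' @param cfg A `surfprot_config`.
#' @rdname config_io
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(unclass(cfg)), function(k) paste(k, "=", cfg[[k]]), "")
  writeLines(lines, path)
  invisible(path)
}
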