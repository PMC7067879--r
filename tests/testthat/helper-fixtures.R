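# shared fixtures built in code

design3 <- function() make_study_design("classical_3plex")
design9 <- function() make_study_design("subsets_9plex")

# minimal valid PSM data frame for a given design
toy_psms <- function(design, n = 3L, seed = 1L) {
  set.seed(seed)
  nch <- plex_size(design)
  df <- data.frame(
    spectrum_id = paste0("scan", seq_len(n)),
    peptide = replicate(n, paste(sample(c("A", "G", "K", "L", "S", "V"), 9,
                                        replace = TRUE), collapse = "")),
    proteins = paste0("P", seq_len(n)),
    score = runif(n, 2, 5),
    is_decoy = FALSE,
    ms1_max_intensity = runif(n, 1e5, 1e6),
    isolation_specificity = runif(n, 0.8, 1),
    stringsAsFactors = FALSE
  )
  int <- matrix(runif(n * nch, 100, 1000), n, nch)
  noise <- matrix(runif(n * nch, 5, 15), n, nch)
  colnames(int) <- paste0("int_", design$channel)
  colnames(noise) <- paste0("noise_", design$channel)
  df <- cbind(df, as.data.frame(int), as.data.frame(noise))
  attr(df, "design") <- design
  class(df) <- c("surfprot_psms", "data.frame")
  df
}

# textbook Benjamini-Hochberg, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)          # rank of p[i]
    q[i] <- min(pmin(1, m * p[o][r:m] / (r:m)))
  }
  q
}

# exhaustive target-decoy threshold scan
fdr_oracle <- function(score, is_decoy, level) {
  cand <- sort(unique(score))
  feas <- vapply(cand, function(t) {
    ta <- sum(score >= t & !is_decoy)
    de <- sum(score >= t & is_decoy)
    ta > 0 && de / ta <= level
  }, TRUE)
  if (!any(feas)) return(Inf)
  min(cand[feas])
}
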