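test_that("reporter extraction follows the windowed max-intensity rule", {
  mz <- tmt_reporter_mz(c("126", "127N"))
  # single in-window peak: S:N = intensity / scan noise
  peaks <- data.frame(mz = mz[["126"]] + 0.001, intensity = 500)
  out <- extract_reporters(peaks, noise = 10, theoretical_mz = mz)
  expect_equal(unname(out$sn[["126"]]), 50)
  expect_true(is.na(out$sn[["127N"]]))       # nothing within 0.003 Th
  # two candidates: higher intensity wins even when farther
  peaks <- data.frame(mz = mz[["126"]] + c(0.002, 0.0005),
                      intensity = c(800, 300))
  out <- extract_reporters(peaks, 10, mz)
  expect_equal(unname(out$intensity[["126"]]), 800)
  # nearest-first alternative rule picks the closer peak
  out2 <- extract_reporters(peaks, 10, mz, rule = "nearest")
  expect_equal(unname(out2$intensity[["126"]]), 300)
  expect_error(extract_reporters(peaks, 10, mz, window = 0), "window")
})

test_that("extraction matches a brute-force scan over random peak lists", {
  mz <- tmt_reporter_mz(design9()$channel)
  set.seed(4)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    peaks <- data.frame(
      mz = sample(mz, n, replace = TRUE) + runif(n, -0.005, 0.005),
      intensity = runif(n, 10, 1000))
    got <- extract_reporters(peaks, 12, mz)$intensity
    for (ch in names(mz)) {
      d <- abs(peaks$mz - mz[[ch]])
      cand <- peaks[d <= 0.003, , drop = FALSE]
      dc <- d[d <= 0.003]
      if (!nrow(cand)) {
        expect_true(is.na(got[[ch]]))
      } else {
        top <- cand$intensity == max(cand$intensity)
        expect_equal(unname(got[[ch]]),
                     cand$intensity[top][which.min(dc[top])])
      }
    }
  }
})

test_that("combined S:N floor is strict and missing-channel rules apply", {
  d9 <- design9()
  cfg9 <- pipeline_config(plex_size = 9L)
  mk <- function(design, sn_per_channel, miss = integer(0)) {
    p <- toy_psms(design, n = 1L)
    nch <- plex_size(design)
    for (i in seq_len(nch)) {
      p[[paste0("noise_", design$channel[i])]] <- 10
      p[[paste0("int_", design$channel[i])]] <- 10 * sn_per_channel[i]
    }
    for (i in miss) {
      p[[paste0("int_", design$channel[i])]] <- NA
      p[[paste0("noise_", design$channel[i])]] <- NA
    }
    p
  }
  # 9-plex at combined 134.9 -> dropped for low S:N
  p <- mk(d9, rep(134.9 / 9, 9))
  expect_equal(as.character(filter_psms(p, cfg9)$disposition), "drop_low_sn")
  # 3-plex at exactly 45 is kept ("less than 45" excludes)
  d3 <- design3(); cfg3 <- pipeline_config(plex_size = 3L)
  p <- mk(d3, rep(15, 3))
  expect_equal(as.character(filter_psms(p, cfg3)$disposition), "kept")
  expect_equal(as.character(filter_psms(mk(d3, rep(14.99, 3)), cfg3)$disposition),
               "drop_low_sn")
  # all channels missing -> no MS3 spectrum at all
  p <- mk(d9, rep(100, 9), miss = 1:9)
  expect_equal(as.character(filter_psms(p, cfg9)$disposition), "drop_no_ms3")
  # more than max_missing_channels missing
  cfg_tight <- pipeline_config(plex_size = 9L, max_missing_channels = 2L)
  p <- mk(d9, rep(100, 9), miss = 1:3)
  expect_equal(as.character(filter_psms(p, cfg_tight)$disposition),
               "drop_missing_channels")
})

test_that("filter dispositions partition the input exactly", {
  d <- design9()
  set.seed(9)
  psms <- toy_psms(d, n = 120L)
  # push some PSMs into each failure mode
  psms$isolation_specificity[1:20] <- runif(20, 0, 0.6)
  for (ch in d$channel) psms[[paste0("int_", ch)]][21:40] <- NA
  for (ch in d$channel) psms[[paste0("noise_", ch)]][21:40] <- NA
  for (ch in d$channel) psms[[paste0("int_", ch)]][41:60] <- runif(20, 0, 100)
  res <- filter_psms(psms, pipeline_config(plex_size = 9L))
  expect_equal(sum(res$report), nrow(psms))
  expect_equal(nrow(res$kept), sum(res$disposition == "kept"))
  expect_equal(length(res$disposition), nrow(psms))
})

test_that("isolation-specificity filter thresholds and validates", {
  d <- design3()
  psms <- toy_psms(d, n = 3L)
  psms$isolation_specificity <- c(0.95, 0.50, 0.70)
  expect_equal(filter_isolation_specificity(psms, 0.70),
               c("kept", "drop_low_specificity", "kept"))
  expect_equal(filter_isolation_specificity(psms, 0),
               rep("kept", 3))
  psms$isolation_specificity[1] <- -0.1
  expect_error(filter_isolation_specificity(psms, 0.7), "\\[0,1\\]")
})

test_that("FDR threshold equals the exhaustive scan on random instances", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(50:2000, 1)
    score <- c(rnorm(n, 3), rnorm(n, 0))
    is_decoy <- rep(c(FALSE, TRUE), each = n)
    lvl <- sample(c(0.01, 0.05, 0.2), 1)
    res <- fdr_filter(score, is_decoy, lvl)
    expect_equal(res$threshold, fdr_oracle(score, is_decoy, lvl))
    # achieved FDR at the returned threshold respects the level
    expect_lte(sum(is_decoy & score >= res$threshold) /
                 sum(!is_decoy & score >= res$threshold), lvl)
    expect_equal(res$keep, score >= res$threshold & !is_decoy)
  }
})

test_that("FDR filter edge cases: no decoys, vacuous level, unreachable level", {
  res <- fdr_filter(c(5, 4, 3), rep(FALSE, 3), 0.01)
  expect_equal(sum(res$keep), 3L)
  res <- fdr_filter(c(5, 4, 3, 2), c(FALSE, TRUE, FALSE, TRUE), 1.0)
  expect_equal(sum(res$keep), 2L)  # every target kept at level 1
  expect_warning(res <- fdr_filter(c(1, 2), c(TRUE, TRUE), 0.5), "no score")
  expect_equal(sum(res$keep), 0L)
})

test_that("ties at the threshold score are kept", {
  score <- c(5, 4, 4, 4, 3.9)
  is_decoy <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  res <- fdr_filter(score, is_decoy, 0.5)
  expect_equal(res$threshold, 4)
  expect_equal(sum(res$keep), 3L)  # targets scoring exactly 4 stay
})

test_that("parsimony covers all peptides with the minimal greedy set", {
  # no sharing: one group per protein
  res <- assemble_parsimony(list(pep1 = "A", pep2 = "B"))
  expect_equal(sort(res$groups$group_id), c("A", "B"))
  # subsumed protein removed
  res <- assemble_parsimony(list(pep1 = c("A", "B"), pep2 = "A"))
  expect_equal(res$groups$group_id, "A")
  expect_equal(unname(res$assignment[c("pep1", "pep2")]), c("A", "A"))
  # indistinguishable proteins merge into one group
  res <- assemble_parsimony(list(p1 = c("A", "B"), p2 = c("A", "B")))
  expect_equal(nrow(res$groups), 1L)
  expect_equal(res$groups$members, "A;B")
  # empty input
  res <- assemble_parsimony(list())
  expect_equal(nrow(res$groups), 0L)
})

test_that("parsimony output always covers peptides, never exceeds trivial cover", {
  set.seed(33)
  for (i in 1:30) {
    n_pep <- sample(5:15, 1); n_prot <- sample(3:6, 1)
    prots <- LETTERS[seq_len(n_prot)]
    m <- lapply(seq_len(n_pep), function(j) {
      sample(prots, sample(seq_len(min(3, n_prot)), 1))
    })
    names(m) <- paste0("pep", seq_len(n_pep))
    res <- assemble_parsimony(m)
    expect_false(anyNA(res$assignment))
    expect_lte(nrow(res$groups), n_pep)
    # every peptide's assigned group actually contains one of its proteins
    for (p in names(m)) {
      members <- strsplit(
        res$groups$members[res$groups$group_id == res$assignment[[p]]], ";")[[1]]
      expect_true(any(members %in% m[[p]]))
    }
  }
})

test_that("protein summation is additive, linear and permutation-invariant", {
  d <- design3()
  psms <- toy_psms(d, n = 2L)
  psms$peptide <- c("AAAK", "CCCK")
  psms$proteins <- "P1"
  for (i in 1:3) {
    psms[[paste0("noise_", d$channel[i])]] <- c(1, 1)
    psms[[paste0("int_", d$channel[i])]] <- c(c(10, 20, 30)[i], c(1, 2, 3)[i])
  }
  inf <- assemble_parsimony(list(AAAK = "P1", CCCK = "P1"))
  pq <- sum_protein_reporters(psms, inf, d)
  expect_equal(unname(unlist(pq[1, paste0("sn_", d$channel)])), c(11, 22, 33))
  expect_equal(pq$n_psms, 2L)
  # doubling reporter blocks doubles the protein row
  psms2 <- psms
  for (ch in d$channel) psms2[[paste0("int_", ch)]] <- 2 * psms2[[paste0("int_", ch)]]
  pq2 <- sum_protein_reporters(psms2, inf, d)
  expect_equal(as.numeric(pq2[1, paste0("sn_", d$channel)]),
               2 * as.numeric(pq[1, paste0("sn_", d$channel)]))
  # permuting PSMs changes nothing
  pq3 <- sum_protein_reporters(psms[2:1, ], inf, d)
  expect_equal(pq3, pq)
  # PSM with an unassigned peptide is an error
  psms$peptide[2] <- "GGGK"
  expect_error(sum_protein_reporters(psms, inf, d), "not assigned")
})

test_that("fractional signals hit max 1 and reject all-zero proteins", {
  d <- design3()
  pq <- data.frame(accession = c("P1", "P2"), gene = c("g1", "g2"),
                   n_psms = 1L, n_peptides = 1L, peptides = "X",
                   sn_126 = c(2, 5), sn_127N = c(4, 5), sn_127C = c(8, 5))
  out <- fractional_signal(pq, d)
  expect_equal(unname(unlist(out[1, paste0("frac_", d$channel)])),
               c(0.25, 0.5, 1))
  expect_equal(unname(unlist(out[2, paste0("frac_", d$channel)])), c(1, 1, 1))
  pq$sn_126[1] <- 0; pq$sn_127N[1] <- 0; pq$sn_127C[1] <- 0
  expect_error(fractional_signal(pq, d), "P1")
  # invariance under positive rescaling of a row
  pq2 <- data.frame(accession = "P", gene = "g", n_psms = 1L, n_peptides = 1L,
                    peptides = "X", sn_126 = 3, sn_127N = 6, sn_127C = 9)
  f1 <- fractional_signal(pq2, d)
  pq2[paste0("sn_", d$channel)] <- pq2[paste0("sn_", d$channel)] * 7.3
  f2 <- fractional_signal(pq2, d)
  expect_equal(as.numeric(f1[paste0("frac_", d$channel)]),
               as.numeric(f2[paste0("frac_", d$channel)]))
})

test_that("loading factors reproduce the bounds check", {
  sn <- rbind(c(50, 100, 150), c(50, 100, 150))
  res <- loading_normalization_factors(sn)
  expect_equal(unname(res$factors), c(0.5, 1, 1.5))
  expect_true(res$pass)
  expect_true(loading_normalization_factors(matrix(5, 3, 4))$pass)
  # a dominant channel beyond 3x the mean fails the (0.33, 3.0) bounds
  sn <- matrix(rep(c(350, rep(10, 8)), 2), 2, 9, byrow = TRUE)
  res <- loading_normalization_factors(sn)
  expect_gt(max(res$factors), 3)
  expect_false(res$pass)
  # an underloaded channel below 0.33x fails too
  res_low <- loading_normalization_factors(rbind(c(10, 300, 320)))
  expect_lt(min(res_low$factors), 0.33)
  expect_false(res_low$pass)
  expect_error(loading_normalization_factors(matrix(0, 2, 3)), "zero")
})

test_that("peptide- then protein-level FDR keeps calibrated targets", {
  d <- design3()
  set.seed(5)
  n <- 400L
  psms <- toy_psms(d, n = n)
  psms$peptide <- paste0("PEPTIDE", rep(1:100, each = 4), "K")
  psms$proteins <- paste0("P", rep(1:25, each = 16))
  psms$score <- rnorm(n, 4)
  dec <- psms
  dec$peptide <- paste0("REVPEP", rep(1:100, each = 4), "K")
  dec$proteins <- paste0("rev_P", rep(1:25, each = 16))
  dec$score <- rnorm(n, 0)
  dec$is_decoy <- TRUE
  all_psms <- rbind(psms, dec)
  attr(all_psms, "design") <- d
  res <- fdr_filter_psms(all_psms, pipeline_config(plex_size = 3L))
  expect_false(any(res$psms$is_decoy))
  expect_gt(nrow(res$psms), 0.9 * n)    # nearly all true targets survive
  expect_lte(res$peptide$fdr, 0.01)
  expect_lte(res$protein$fdr, 0.01)
})
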