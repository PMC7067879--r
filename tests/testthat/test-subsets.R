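test_that("normalize-then-average follows the stated order", {
  subsets <- rep(c("classical", "intermediate", "nonclassical"), each = 1)
  expect_equal(unname(normalize_max1(c(2, 4, 8), subsets)), c(0.25, 0.5, 1))
  expect_equal(unname(normalize_max1(c(5, 5, 5), subsets)), c(1, 1, 1))
  expect_error(normalize_max1(c(0, 0, 0), subsets), "positive")
  # with replicates the two orders differ measurably
  d <- design9()
  set.seed(2)
  x <- matrix(runif(9, 0.1, 1), 1, 9)
  norm_avg <- normalize_max1(x, d$subset)
  avg <- sapply(unique(d$subset), function(s) mean(x[, d$subset == s]))
  avg_norm <- avg / max(avg)
  expect_gt(max(abs(norm_avg - avg_norm)), 1e-3)
  expect_true(all(norm_avg <= 1))
})

test_that("sample PCA is duplicate-invariant with bounded explained variance", {
  set.seed(6)
  m <- matrix(runif(60), 20, 3)
  m <- cbind(m, m[, 3])  # duplicated sample
  colnames(m) <- paste0("s", 1:4)
  res <- pca_samples(m)
  expect_equal(res$scores[3, ], res$scores[4, ], tolerance = 1e-9)
  expect_lte(sum(res$explained), 1 + 1e-12)
  expect_gte(min(res$explained), 0)
})

test_that("classical samples separate on PCA of structured profiles", {
  d <- design9()
  cfg <- sim_config(seed = 31L)
  pro <- generate_proteome(cfg)
  m <- simulate_profile_matrix(cfg, pro, d)
  res <- pca_samples(m)
  pc1 <- res$scores[, 1]
  cl <- d$subset == "classical"
  gap <- abs(mean(pc1[cl]) - mean(pc1[!cl]))
  spread <- max(tapply(pc1, d$subset, sd))
  expect_gt(gap, spread)  # classical centroid clearly separated on PC1
})

test_that("k-means scan: closed form at k=1, zero at true k, non-increasing", {
  set.seed(10)
  m <- matrix(rnorm(40 * 4), 40, 4)
  scan <- kmeans_scan(m, kmax = 6L, restarts = 10L, seed = 1L)
  expect_equal(scan$wcv[1], sum(sweep(m, 2, colMeans(m))^2), tolerance = 1e-9)
  expect_true(all(diff(scan$wcv) <= 1e-9))
  # three exact clusters: wcv(3) = 0
  m0 <- rbind(matrix(0, 10, 2), matrix(5, 10, 2), matrix(c(9, -3), 10, 2,
                                                         byrow = TRUE))
  scan0 <- kmeans_scan(m0, kmax = 5L, restarts = 10L, seed = 1L)
  expect_equal(scan0$wcv[3], 0)
  expect_error(kmeans_scan(m0, kmax = 30L), "smaller")
})

test_that("elbow detection: breakpoint curves, straight lines, errors", {
  k <- 1:20
  brk <- data.frame(k = k, wcv = ifelse(k <= 8, 100 - 10 * k,
                                        20 - 0.5 * (k - 8)))
  expect_equal(detect_elbow(brk), 8L)
  line <- data.frame(k = k, wcv = 210 - 10 * k)
  expect_equal(detect_elbow(line), 1L)
  # power-law tail with a breakpoint
  pw <- data.frame(k = k, wcv = ifelse(k <= 8, 300 * exp(-0.5 * k),
                                       300 * exp(-4) * (k / 8)^(-0.3)))
  expect_equal(detect_elbow(pw), 8L)
  expect_error(detect_elbow(brk, tail_len = 20L), "tail_len")
})

test_that("k-means clustering recovers exact classes and is order-invariant", {
  d <- design9()
  templates <- rbind(c(1, 0.4, 0.4), c(0.4, 1, 0.4), c(0.4, 0.4, 1))
  cls <- rep(1:3, each = 15)
  m <- templates[cls, match(d$subset, c("classical", "intermediate",
                                        "nonclassical"))]
  rownames(m) <- paste0("P", seq_len(nrow(m)))
  colnames(m) <- d$channel
  res <- kmeans_cluster(m, 3L, d, restarts = 10L, seed = 2L)
  expect_equal(adjusted_rand(cls, res$cluster), 1)
  # cluster labels name the enriched subset
  lab <- res$summary$enriched_subset[res$cluster[cls == 1][1]]
  expect_equal(lab, "classical")
  # permuting rows permutes assignments identically
  perm <- sample(nrow(m))
  res2 <- kmeans_cluster(m[perm, ], 3L, d, restarts = 10L, seed = 2L)
  agree <- adjusted_rand(res$cluster[perm], res2$cluster)
  expect_equal(agree, 1)
  expect_error(kmeans_cluster(m, 50L, d), "smaller")
})

test_that("uncentered correlation distance is a proper self-zero measure", {
  x <- c(1, 2, 3)
  expect_equal(uncentered_correlation_dist(x, x), 0)
  expect_equal(uncentered_correlation_dist(x, 2 * x), 0)  # scale-free
  expect_equal(uncentered_correlation_dist(c(1, 0), c(0, 1)), 1)
  expect_equal(uncentered_correlation_dist(x, -x), 2)
  expect_error(uncentered_correlation_dist(c(0, 0), x), "zero")
})

test_that("centroid clustering merges identical rows first at height zero", {
  m <- rbind(a = c(1, 1), b = c(1, 1), c = c(5, 9), d = c(0, 4))
  h <- hierarchical_cluster(m, "euclidean")
  expect_equal(h$height[1], 0)
  first <- sort(-h$merge[1, ])
  expect_equal(sort(h$labels[first]), c("a", "b"))
  expect_s3_class(h, "hclust")
  nwk <- tree_newick(h)
  expect_match(nwk, "^\\(")
  expect_true(all(c("a", "b", "c", "d") %in%
                    ape::read.tree(text = nwk)$tip.label))
})

test_that("centroid merge order equals a brute-force agglomeration oracle", {
  oracle <- function(m, dfun) {
    items <- lapply(seq_len(nrow(m)), function(i) i)
    cents <- m
    merges <- list()
    while (length(items) > 1L) {
      best <- c(NA, NA); bd <- Inf
      for (i in seq_along(items)) for (j in seq_along(items)) {
        if (i < j) {
          dd <- dfun(cents[i, ], cents[j, ])
          if (dd < bd) { bd <- dd; best <- c(i, j) }
        }
      }
      i <- best[1]; j <- best[2]
      merged <- c(items[[i]], items[[j]])
      merges[[length(merges) + 1L]] <- sort(merged)
      newc <- colMeans(m[merged, , drop = FALSE])
      items[[i]] <- merged; cents[i, ] <- newc
      items <- items[-j]; cents <- cents[-j, , drop = FALSE]
    }
    merges
  }
  set.seed(77)
  for (rep in 1:5) {
    m <- matrix(runif(8), 4, 2)
    rownames(m) <- letters[1:4]
    h <- hierarchical_cluster(m, "euclidean")
    want <- oracle(m, function(x, y) sqrt(sum((x - y)^2)))
    leaves <- function(node) {
      if (node < 0) return(-node)
      sort(c(leaves(h$merge[node, 1]), leaves(h$merge[node, 2])))
    }
    got <- lapply(seq_len(nrow(h$merge)), function(s) sort(leaves(s)))
    expect_equal(got, want)
  }
})

test_that("pairwise tests: exact cases and agreement with stats::t.test", {
  d <- design9()
  m <- matrix(0, 2, 9, dimnames = list(c("flat", "diff"), d$channel))
  set.seed(3)
  # every subset sees (1, 2, 3) across its three donors -> identical groups
  m["flat", ] <- as.integer(factor(d$donor))
  m["diff", ] <- ifelse(d$subset == "classical", 1, 0.4) + rnorm(9, 0, 1e-3)
  tt <- pairwise_tests(m, d)
  # identical group values -> t = 0, p = 1
  expect_equal(tt["flat" == tt$accession, "p_classical_vs_intermediate"], 1)
  expect_equal(tt["flat" == tt$accession, "t_classical_vs_intermediate"], 0)
  # cross-check a row against stats::t.test
  a <- m["diff", d$subset == "classical"]
  b <- m["diff", d$subset == "nonclassical"]
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(tt[tt$accession == "diff", "p_classical_vs_nonclassical"],
               ref$p.value, tolerance = 1e-12)
  refw <- t.test(a, b)
  ttw <- pairwise_tests(m, d, var_equal = FALSE)
  expect_equal(ttw[ttw$accession == "diff", "p_classical_vs_nonclassical"],
               refw$p.value, tolerance = 1e-12)
})

test_that("degenerate zero-variance comparisons resolve as specified", {
  d <- design9()
  m <- rbind(same = ifelse(d$subset == "classical", 1, 1),
             apart = ifelse(d$subset == "classical", 1, 0.4))
  colnames(m) <- d$channel
  tt <- pairwise_tests(m, d)
  expect_equal(tt$p_classical_vs_intermediate[1], 1)
  expect_equal(tt$p_classical_vs_intermediate[2], 0)
})

test_that("BH adjustment matches the hand example and q >= p", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  set.seed(5)
  pv <- runif(200)
  q <- p.adjust(pv, "BH")
  expect_true(all(q >= pv - 1e-15))
})

test_that("marker calls respect clusters, significance and direction", {
  d <- design9()
  set.seed(44)
  n <- 60
  cls <- rep(1:3, each = n / 3)
  templates <- rbind(c(1, 0.3, 0.3), c(0.5, 0.5, 0.5), c(0.3, 0.3, 1))
  mu <- templates[cls, match(d$subset, c("classical", "intermediate",
                                         "nonclassical"))]
  m <- mu + matrix(rnorm(n * 9, 0, 0.03), n, 9)
  rownames(m) <- paste0("P", seq_len(n))
  colnames(m) <- d$channel
  cl <- kmeans_cluster(m, 3L, d, restarts = 10L, seed = 1L)
  tt <- pairwise_tests(m, d)
  mk <- rank_markers(cl, tt, m, d, q_cutoff = 0.05)
  enr <- mk[mk$direction == "enriched", ]
  # flat proteins are never called
  expect_false(any(paste0("P", 21:40) %in% mk$accession))
  # the strong classical block is called classical
  called_cl <- enr$accession[enr$subset == "classical"]
  expect_gte(length(intersect(called_cl, paste0("P", 1:20))), 18)
  # every call is significant in both of its comparisons
  expect_true(all(mk$worst_q < 0.05))
  # ranking is by worst-case q
  expect_true(!is.unsorted(mk$worst_q))
})

test_that("cross-platform co-clustering pairs identical platforms first", {
  d <- design9()
  set.seed(9)
  m <- matrix(runif(30 * 9, 0.1, 1), 30, 9,
              dimnames = list(paste0("G", 1:30), d$channel))
  res <- co_cluster_platforms(m, m, d, d)
  h <- res$tree
  # first three merges join x_<subset> with y_<subset>
  for (s in 1:3) {
    pair <- h$labels[-h$merge[s, ]]
    expect_equal(sub("^[xy]_", "", pair[1]), sub("^[xy]_", "", pair[2]))
  }
  # row order of the external matrix does not matter
  res2 <- co_cluster_platforms(m, m[sample(30), ], d, d)
  expect_equal(res$tree$merge, res2$tree$merge)
  expect_error(co_cluster_platforms(m[1:2, ], m, d, d), ">= 3 shared")
})

test_that("noisy transcript profiles still co-cluster by subset", {
  d <- design9()
  cfg <- sim_config(seed = 13L)
  pro <- generate_proteome(cfg)
  m <- simulate_profile_matrix(cfg, pro, d)
  rna <- pmax(m + matrix(rnorm(length(m), 0, 0.05), nrow(m)), 0.01)
  res <- co_cluster_platforms(m, rna, d, d)
  h <- res$tree
  # the first merges join same-subset columns across platforms
  pair1 <- sub("^[xy]_", "", h$labels[-h$merge[1, ]])
  expect_equal(pair1[1], pair1[2])
})
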