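#' Fractional-signal profile matrix
#'
#' @param pq Protein table with `frac_<channel>` columns (see
#'   [fractional_signal()]).
#' @param design Sample design.
#' @return Numeric matrix proteins x channels (rownames = accessions), each
#'   row with maximum exactly 1.
#' @export
profile_matrix <- function(pq, design = attr(pq, "design")) {
  design <- as_study_design(design)
  m <- as.matrix(pq[paste0("frac_", design$channel)])
  dimnames(m) <- list(pq$accession, design$channel)
  m
}

#' Normalize to a maximum of one, then average within subsets
#'
#' The validation-figure transform: each profile is divided by its maximum
#' and the replicate channels of each subset are then averaged (normalise
#' first, average second — the reverse order gives measurably different
#' values).
#'
#' @param x Numeric vector (one protein across samples) or matrix
#'   (proteins x samples).
#' @param subsets Character vector of subset labels, one per sample.
#' @return Per-subset means (vector), or a proteins x subsets matrix.
#' @export
normalize_max1 <- function(x, subsets) {
  if (is.matrix(x)) {
    mx <- apply(x, 1L, max)
    if (any(mx <= 0)) stop("row(s) with no positive value")
    norm <- x / mx
    groups <- unique(subsets)
    out <- sapply(groups, function(g) {
      rowMeans(norm[, subsets == g, drop = FALSE])
    })
    return(matrix(out, nrow = nrow(x), dimnames = list(rownames(x), groups)))
  }
  if (max(x) <= 0) stop("no positive value to normalize by")
  v <- x / max(x)
  means <- tapply(v, subsets, mean)[unique(subsets)]
  stats::setNames(as.numeric(means), names(means))
}

#' PCA of samples over protein profiles
#'
#' Samples (TMT channels) are the observations and proteins the variables;
#' variables are centered, not scaled (fractional signals already lie in
#' [0,1]).
#'
#' @param m Profile matrix, proteins x samples.
#' @return List with `scores` (samples x components), `explained` (variance
#'   fractions, summing to <= 1) and the `prcomp` fit.
#' @export
pca_samples <- function(m) {
  stopifnot(ncol(m) >= 3L, nrow(m) >= 2L)
  fit <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  keep <- ev > max(ev) * 1e-12
  if (sum(keep) < 2L) warning("profile matrix is (near) rank deficient; ",
                              sum(keep), " informative component(s)")
  list(scores = fit$x, explained = ev / sum(ev), fit = fit)
}

# k-means++ seeding over rows of m
kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  centers <- matrix(NA_real_, k, ncol(m))
  i <- sample.int(n, 1L)
  centers[1L, ] <- m[i, ]
  if (k > 1L) {
    d2 <- rowSums((m - matrix(centers[1L, ], n, ncol(m), byrow = TRUE))^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      i <- sample.int(n, 1L, prob = p)
      centers[j, ] <- m[i, ]
      d2 <- pmin(d2, rowSums((m - matrix(m[i, ], n, ncol(m), byrow = TRUE))^2))
    }
  }
  centers
}

kmeans_best <- function(m, k, restarts, extra_centers = NULL) {
  best <- NULL
  inits <- replicate(restarts, kmeanspp_centers(m, k), simplify = FALSE)
  if (!is.null(extra_centers)) inits <- c(inits, list(extra_centers))
  for (centers in inits) {
    centers <- centers[!duplicated(round(centers, 12L)), , drop = FALSE]
    fit <- suppressWarnings(
      stats::kmeans(m, centers = centers, iter.max = 50L, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Within-class variance scan over k = 1..kmax
#'
#' For each class count k the best of `restarts` k-means fits (k-means++
#' seeding; plus a warm start that augments the previous k's centroids with
#' the worst-fit point, which makes the curve non-increasing in k) is
#' recorded as the summed squared distance of each protein to its cluster
#' centroid.
#'
#' @param m Profile matrix (proteins x samples).
#' @param kmax Largest k (must be < number of proteins).
#' @param restarts Restarts per k.
#' @param seed Seed for the initialization stream.
#' @return Data frame `k`, `wcv` with attribute `"fits"` (per-k kmeans
#'   fits).
#' @export
kmeans_scan <- function(m, kmax = 20L, restarts = 50L, seed = 1L) {
  if (kmax >= nrow(m)) stop("kmax must be smaller than the number of proteins")
  set.seed(seed)
  wcv <- numeric(kmax)
  fits <- vector("list", kmax)
  prev <- NULL
  for (k in seq_len(kmax)) {
    extra <- NULL
    if (!is.null(prev)) {
      d2 <- rowSums((m - prev$centers[prev$cluster, , drop = FALSE])^2)
      extra <- rbind(prev$centers, m[which.max(d2), ])
    }
    fit <- kmeans_best(m, k, restarts, extra_centers = extra)
    wcv[k] <- fit$tot.withinss
    fits[[k]] <- fit
    prev <- fit
  }
  out <- data.frame(k = seq_len(kmax), wcv = wcv)
  attr(out, "fits") <- fits
  out
}

#' Detect the elbow of a within-class variance curve
#'
#' Fits a straight line to the last `tail_len` points of the curve — the
#' steady overfitting decline — and returns the smallest k whose variance
#' already lies within `tol_sd` tail-residual standard deviations of that
#' line; clusters added beyond this point only track the tail. The fit is
#' performed on log-log axes: the overfitting tail of a k-means variance
#' curve declines as a power of k (roughly k^(-2/d) for d features), so it
#' is straight in log-log coordinates, whereas a line fit on raw axes
#' under-predicts just left of the tail and systematically overshoots the
#' elbow. The choice is advisory — every downstream analysis takes k as a
#' parameter.
#'
#' @param curve Data frame `k`, `wcv` from [kmeans_scan()].
#' @param tail_len Number of trailing points defining the overfitting line.
#' @param tol_sd Tolerance in tail-residual standard deviations.
#' @return Chosen k (integer).
#' @export
detect_elbow <- function(curve, tail_len = 8L, tol_sd = 1) {
  kmax <- max(curve$k)
  if (tail_len >= kmax) stop("tail_len must be smaller than kmax")
  tail_idx <- curve$k > kmax - tail_len
  eps <- max(curve$wcv[1], 1) * 1e-12
  if (all(curve$wcv[tail_idx] <= eps)) {
    # degenerate: the tail is an exact fit; first k reaching it is the elbow
    return(min(curve$k[curve$wcv <= eps]))
  }
  tail_dat <- data.frame(lk = log(curve$k[tail_idx]),
                         lw = log(pmax(curve$wcv[tail_idx], eps)))
  fit <- stats::lm(lw ~ lk, data = tail_dat)
  sd_tail <- sqrt(sum(stats::residuals(fit)^2) / max(1L, sum(tail_idx) - 2L))
  pred <- stats::predict(fit, newdata = data.frame(lk = log(curve$k)))
  lw_all <- log(pmax(curve$wcv, eps))
  within <- lw_all <= pred + tol_sd * sd_tail + sqrt(.Machine$double.eps)
  min(curve$k[within])
}

#' K-means clustering with subset-enrichment labels
#'
#' @param m Profile matrix (proteins x samples).
#' @param k Number of clusters (2 <= k < n proteins).
#' @param design Sample design aligned with the columns of `m`.
#' @param restarts,seed As in [kmeans_scan()].
#' @return List with `cluster` (named assignment vector), `summary` (per
#'   cluster: size, mean fractional signal per subset, `enriched_subset` =
#'   subset with the highest mean) and the kmeans `fit`.
#' @export
kmeans_cluster <- function(m, k, design, restarts = 50L, seed = 1L) {
  stopifnot(k >= 2L)
  if (k >= nrow(m)) stop("k must be smaller than the number of proteins")
  design <- as_study_design(design)
  set.seed(seed)
  fit <- kmeans_best(m, k, restarts)
  cl <- stats::setNames(fit$cluster, rownames(m))
  subsets <- unique(design$subset)
  means <- t(sapply(seq_len(k), function(ci) {
    rows <- m[cl == ci, , drop = FALSE]
    vapply(subsets, function(s) {
      mean(rows[, design$subset == s, drop = FALSE])
    }, 0)
  }))
  colnames(means) <- subsets
  summary <- data.frame(cluster = seq_len(k),
                        size = as.integer(table(factor(cl, levels = seq_len(k)))),
                        means,
                        enriched_subset = subsets[max.col(means)],
                        check.names = FALSE)
  list(cluster = cl, summary = summary, fit = fit)
}

#' Uncentered correlation distance
#'
#' d(x, y) = 1 - sum(x*y) / sqrt(sum(x^2) * sum(y^2)); zero for a vector
#' with itself, up to 2 for anti-correlated vectors. Undefined (error) for
#' all-zero vectors.
#'
#' @param x,y Numeric vectors.
#' @export
uncentered_correlation_dist <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("uncentered correlation undefined for a zero vector")
  1 - sum(x * y) / (nx * ny)
}

row_metric_fun <- function(metric) {
  switch(metric,
         euclidean = function(x, y) sqrt(sum((x - y)^2)),
         uncentered_correlation = uncentered_correlation_dist,
         stop("unknown metric: ", metric))
}

#' Agglomerative centroid-linkage hierarchical clustering
#'
#' Clusters the rows of `m` by repeatedly merging the pair of clusters
#' whose centroids (member means) are closest under the chosen metric, in
#' the style of Cluster 3.0's centroid linkage. Note that centroid linkage
#' is not monotone: merge heights can occasionally invert.
#'
#' @param m Numeric matrix (items x features), rownames used as labels.
#' @param metric `"euclidean"` or `"uncentered_correlation"`.
#' @return An object of class `hclust` (merge, height, order, labels).
#' @export
hierarchical_cluster <- function(m, metric = c("euclidean", "uncentered_correlation")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  dfun <- row_metric_fun(metric)
  n <- nrow(m)
  if (metric == "uncentered_correlation") {
    zero <- rowSums(m^2) == 0
    if (any(zero)) stop("zero vector(s) under correlation metric: ",
                        paste(rownames(m)[zero], collapse = ", "))
  }
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  centroids <- m
  sizes <- rep(1L, n)
  id <- -seq_len(n)          # hclust convention: negatives are singletons
  active <- rep(TRUE, n)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) D[i, j] <- dfun(m[i, ], m[j, ])
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  slot <- seq_len(n)  # row index of each active cluster's data
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    w <- arrayInd(which.min(sub), dim(sub))
    a <- act[min(w)]; b <- act[max(w)]
    merge[step, ] <- sort(c(id[a], id[b]))
    height[step] <- D[min(a, b), max(a, b)]
    newc <- (centroids[a, ] * sizes[a] + centroids[b, ] * sizes[b]) /
      (sizes[a] + sizes[b])
    centroids[a, ] <- newc
    sizes[a] <- sizes[a] + sizes[b]
    id[a] <- step
    active[b] <- FALSE
    for (o in which(active)) {
      if (o == a) next
      D[min(o, a), max(o, a)] <- dfun(newc, centroids[o, ])
    }
  }
  structure(list(merge = merge, height = height,
                 order = hclust_leaf_order(merge),
                 labels = labels, method = "centroid",
                 dist.method = metric, call = match.call()),
            class = "hclust")
}

hclust_leaf_order <- function(merge) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(nrow(merge))
}

#' Serialize a clustering tree to Newick
#'
#' @param h An `hclust` object.
#' @return Single Newick string.
#' @export
tree_newick <- function(h) {
  ape::write.tree(ape::as.phylo(h))
}

# vectorized two-sample t-tests over matrix rows
row_t_test <- function(a, b, var_equal = TRUE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se == 0
  # zero variance in both groups: equal means -> p = 1; unequal -> p -> 0
  t[degenerate & ma == mb] <- 0
  p[degenerate & ma == mb] <- 1
  t[degenerate & ma != mb] <- sign(ma - mb)[degenerate & ma != mb] * Inf
  p[degenerate & ma != mb] <- 0
  list(t = t, p = p, diff = ma - mb, degenerate = degenerate & ma != mb)
}

#' Pairwise subset differential tests with BH correction
#'
#' Two-tailed two-sample t-tests (pooled variance by default, Welch by
#' flag) per protein for each subset pair, with Benjamini-Hochberg
#' adjustment applied separately within each comparison family (all
#' proteins of one subset pair).
#'
#' @param m Profile matrix (proteins x samples).
#' @param design Sample design aligned with columns.
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @return Data frame with, per subset pair `<A>_vs_<B>`, columns
#'   `t_`, `p_`, `q_` and `diff_` (mean A minus mean B), plus `accession`.
#' @export
pairwise_tests <- function(m, design, var_equal = TRUE) {
  design <- as_study_design(design)
  subsets <- unique(design$subset)
  if (length(subsets) < 2L) stop("need at least two subsets")
  counts <- table(design$subset)
  if (any(counts < 2L)) stop("need >= 2 samples per subset")
  out <- data.frame(accession = rownames(m), stringsAsFactors = FALSE)
  pairs <- utils::combn(subsets, 2L, simplify = FALSE)
  for (pr in pairs) {
    a <- m[, design$subset == pr[1], drop = FALSE]
    b <- m[, design$subset == pr[2], drop = FALSE]
    tt <- row_t_test(a, b, var_equal = var_equal)
    q <- stats::p.adjust(tt$p, method = "BH")
    nm <- paste0(pr[1], "_vs_", pr[2])
    out[[paste0("t_", nm)]] <- tt$t
    out[[paste0("p_", nm)]] <- tt$p
    out[[paste0("q_", nm)]] <- q
    out[[paste0("diff_", nm)]] <- tt$diff
  }
  attr(out, "pairs") <- vapply(pairs, paste, "", collapse = "_vs_")
  out
}

#' Call and rank subset markers
#'
#' A protein is called an enriched marker of a subset when (a) it belongs
#' to a cluster whose enriched subset matches, and (b) both pairwise
#' comparisons against the other two subsets are significant (q below
#' `q_cutoff`) with the subset's mean on top. Depleted markers require the
#' subset's mean to be lowest with both comparisons significant (no cluster
#' gate, since clusters are labelled by their enriched subset). Ranked by
#' worst-case q, then by the smallest absolute mean difference (effect
#' size).
#'
#' @param clusters Result of [kmeans_cluster()].
#' @param tests Result of [pairwise_tests()] on the same matrix.
#' @param m Profile matrix.
#' @param design Sample design.
#' @param q_cutoff Significance cutoff on BH-adjusted q (default 0.05).
#' @return Data frame: `accession`, `subset`, `direction`, `cluster`,
#'   `worst_q`, `effect`.
#' @export
rank_markers <- function(clusters, tests, m, design, q_cutoff = 0.05) {
  design <- as_study_design(design)
  subsets <- unique(design$subset)
  stopifnot(length(subsets) == 3L)
  subset_means <- sapply(subsets, function(s) {
    rowMeans(m[, design$subset == s, drop = FALSE])
  })
  cl <- clusters$cluster[rownames(m)]
  cl_label <- clusters$summary$enriched_subset[cl]
  get <- function(prefix, a, b) {
    # comparisons are stored in design order; signed value of (a - b)
    nm_ab <- paste0(prefix, a, "_vs_", b); nm_ba <- paste0(prefix, b, "_vs_", a)
    if (nm_ab %in% names(tests)) list(v = tests[[nm_ab]], sign = 1)
    else list(v = tests[[nm_ba]], sign = -1)
  }
  calls <- list()
  for (s in subsets) {
    others <- setdiff(subsets, s)
    q1 <- get("q_", s, others[1]); d1 <- get("diff_", s, others[1])
    q2 <- get("q_", s, others[2]); d2 <- get("diff_", s, others[2])
    diff1 <- d1$sign * d1$v; diff2 <- d2$sign * d2$v
    sig <- q1$v < q_cutoff & q2$v < q_cutoff
    top <- subset_means[, s] == apply(subset_means, 1L, max)
    bottom <- subset_means[, s] == apply(subset_means, 1L, min)
    enriched <- sig & diff1 > 0 & diff2 > 0 & top & cl_label == s
    depleted <- sig & diff1 < 0 & diff2 < 0 & bottom
    worst_q <- pmax(q1$v, q2$v)
    effect <- pmin(abs(diff1), abs(diff2))
    for (dir in c("enriched", "depleted")) {
      hit <- if (dir == "enriched") enriched else depleted
      if (!any(hit)) next
      calls[[length(calls) + 1L]] <- data.frame(
        accession = rownames(m)[hit], subset = s, direction = dir,
        cluster = as.integer(cl[hit]), worst_q = worst_q[hit],
        effect = effect[hit], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(accession = character(0), subset = character(0),
               direction = character(0), cluster = integer(0),
               worst_q = numeric(0), effect = numeric(0))
  out <- out[order(out$worst_q, -out$effect), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-cluster proteomic and external (e.g. transcriptomic) profiles
#'
#' Both matrices are reduced to shared identifiers, averaged across donors
#' within each subset, normalised row-wise to a maximum of one per
#' platform, then the combined platform-subset columns are clustered
#' hierarchically.
#'
#' @param x,y Numeric matrices (identifiers x samples) with rownames.
#' @param x_design,y_design Sample designs for the columns of `x` and `y`.
#' @param metric Distance metric (default uncentered correlation, the
#'   cross-platform choice).
#' @return List with `tree` (hclust over the combined columns), `newick`
#'   and `combined` (the matrix clustered).
#' @export
co_cluster_platforms <- function(x, y, x_design, y_design,
                                 metric = c("uncentered_correlation", "euclidean")) {
  metric <- match.arg(metric)
  shared <- intersect(rownames(x), rownames(y))
  if (length(shared) < 3L) stop("need >= 3 shared identifiers; found ",
                                length(shared))
  x_design <- as_study_design(x_design); y_design <- as_study_design(y_design)
  avg <- function(m, design) {
    sapply(unique(design$subset), function(s) {
      rowMeans(m[, design$subset == s, drop = FALSE])
    })
  }
  xm <- avg(x[shared, , drop = FALSE], x_design)
  ym <- avg(y[shared, , drop = FALSE], y_design)
  xm <- xm / apply(xm, 1L, max)
  ym <- ym / apply(ym, 1L, max)
  colnames(xm) <- paste0("x_", colnames(xm))
  colnames(ym) <- paste0("y_", colnames(ym))
  combined <- cbind(xm, ym)
  tree <- hierarchical_cluster(t(combined), metric = metric)
  list(tree = tree, newick = tree_newick(tree), combined = combined)
}
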