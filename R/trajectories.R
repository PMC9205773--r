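# Maximum-curvature elbow on the log within-SS curve: the interior k where
# the second difference of log(WSS) is largest, i.e. where the relative
# decrease flattens most sharply. Working on the log scale makes the rule
# invariant to the overall SS magnitude, so a huge first drop (k far below
# the truth) cannot mask the true elbow.
elbow_point <- function(k_values, wss) {
  stopifnot(length(k_values) == length(wss), length(k_values) >= 3)
  y <- log(pmax(wss, .Machine$double.eps))
  curv <- y[-c(1, 2)] - 2 * y[-c(1, length(y))] + y[-c(length(y) - 1,
                                                       length(y))]
  k_values[which.max(curv) + 1]
}

#' Cluster developmental expression trajectories
#'
#' Standardises each gene's trajectory across timepoints (per-gene Z-score),
#' runs k-means (squared Euclidean, multiple restarts) over a range of k,
#' picks k at the elbow of the within-cluster sum-of-squares curve (maximum
#' curvature of log WSS; see `elbow_point`), and reports per-cluster
#' centroids plus a representative gene — the member closest to its
#' centroid, ties broken by gene id. A single-element `k_range` forces that
#' k and skips the elbow rule. Constant trajectories cannot be standardised
#' and are dropped with a warning.
#'
#' @param dev gene-by-timepoint expression matrix (gene ids as row names).
#' @param genes subset of genes to cluster (default all rows).
#' @param k_range candidate cluster counts.
#' @param nstart k-means restarts per k.
#' @param normalise per-gene Z-scoring (default); `FALSE` clusters raw
#'   trajectories.
#' @param seed integer seed.
#' @return list of class `dev_cluster_result`: `k` (chosen), `cluster`
#'   (named vector gene -> cluster id), `centroids` (k x timepoint),
#'   `representatives` (one gene per cluster), `wss_by_k`, `k_range`,
#'   `normalise`.
#' @export
cluster_trajectories <- function(dev, genes = rownames(dev), k_range = 2:8,
                                 nstart = 10, normalise = TRUE, seed = 1L) {
  stopifnot(ncol(dev) >= 3, length(k_range) >= 1)
  m <- dev[intersect(genes, rownames(dev)), , drop = FALSE]
  if (nrow(m) < max(k_range)) stop("need at least max(k_range) genes")
  if (normalise) {
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " constant trajectorie(s) dropped")
      m <- m[sds > 0, , drop = FALSE]
    }
    m <- t(scale(t(m)))
  }
  set.seed(seed)
  fits <- lapply(k_range, function(k)
    stats::kmeans(m, centers = k, nstart = nstart, iter.max = 100))
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  k <- if (length(k_range) == 1) k_range else elbow_point(k_range, wss)
  fit <- fits[[match(k, k_range)]]
  reps <- vapply(seq_len(k), function(cl) {
    members <- sort(names(fit$cluster)[fit$cluster == cl])
    dist2 <- rowSums((m[members, , drop = FALSE] -
                        matrix(fit$centers[cl, ], length(members),
                               ncol(m), byrow = TRUE))^2)
    members[which.min(dist2)]
  }, character(1))
  structure(list(k = k, cluster = fit$cluster, centroids = fit$centers,
                 representatives = reps,
                 wss_by_k = stats::setNames(wss, k_range),
                 k_range = k_range, normalise = normalise),
            class = "dev_cluster_result")
}
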