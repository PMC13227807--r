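#' Pairwise Spearman correlation matrix
#'
#' Each entry is the Spearman rank correlation over the samples where both
#' features are observed (pairwise complete observations); entries supported
#' by fewer than `min_pairs` complete pairs are set missing.
#'
#' @param expr features x samples matrix.
#' @param min_pairs minimum complete pairs per reported entry (default 10).
#' @return list: `rho` (symmetric matrix, unit diagonal), `n_obs`
#'   (pairwise complete counts).
#' @export
spearman_matrix <- function(expr, min_pairs = 10) {
  check_expr(expr)
  rho <- suppressWarnings(
    stats::cor(t(expr), method = "spearman",
               use = "pairwise.complete.obs"))
  obs <- !is.na(expr)
  n_obs <- tcrossprod(obs * 1)
  rho[n_obs < min_pairs] <- NA_real_
  diag(rho) <- 1
  list(rho = rho, n_obs = n_obs)
}

#' Connected-component clusters of the |rho|-threshold network
#'
#' An undirected edge joins two features iff `|rho| >= threshold` (missing
#' correlations count as below threshold); clusters are the connected
#' components, singletons retained as size-1 clusters. Cluster IDs are
#' deterministic: each cluster is named after its lexicographically smallest
#' member.
#'
#' @param corr output of [spearman_matrix()] (or a bare correlation matrix).
#' @param threshold absolute-correlation cutoff in `(0, 1]`.
#' @return list of class `cluster_map`: `threshold`, `assignments` (named
#'   character vector feature -> cluster ID), `summary` (n_clusters of
#'   size 2 or more, max_cluster_size, n_singletons).
#' @export
cluster_components <- function(corr, threshold) {
  rho <- if (is.list(corr)) corr$rho else corr
  stopifnot(threshold > 0, threshold <= 1)
  adj <- abs(rho) >= threshold
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  feats <- rownames(rho)
  assignments <- vapply(seq_len(comp$no), function(i) {
    min(feats[comp$membership == i])
  }, character(1))[comp$membership]
  names(assignments) <- feats
  sizes <- table(assignments)
  structure(list(
    threshold = threshold,
    assignments = assignments,
    summary = list(n_clusters = sum(sizes >= 2),
                   max_cluster_size = max(sizes),
                   n_singletons = sum(sizes == 1))
  ), class = "cluster_map")
}

#' Scan cluster structure across |rho| thresholds
#'
#' @param corr output of [spearman_matrix()].
#' @param thresholds numeric cutoffs, sorted descending (default
#'   0.90, 0.85, 0.80, 0.75, 0.70).
#' @return data.frame: threshold, n_clusters (size >= 2), max_cluster_size,
#'   n_singletons.
#' @export
scan_thresholds <- function(corr, thresholds = c(0.90, 0.85, 0.80,
                                                 0.75, 0.70)) {
  if (is.unsorted(rev(thresholds))) stop("thresholds must be descending")
  rows <- lapply(thresholds, function(thr) {
    s <- cluster_components(corr, thr)$summary
    data.frame(threshold = thr, n_clusters = s$n_clusters,
               max_cluster_size = s$max_cluster_size,
               n_singletons = s$n_singletons)
  })
  do.call(rbind, rows)
}

#' Module eigengene of a feature cluster
#'
#' Member features are median-imputed, z-scored across samples, and
#' summarized by the first principal component; eigengene scores are scaled
#' to unit variance and the sign is oriented so the mean member loading is
#' positive.
#'
#' @param expr features x samples matrix.
#' @param members cluster member feature IDs (>= 2 with nonzero SD).
#' @return list: `eigengene` (named per-sample vector, unit variance),
#'   `variance_explained` (first eigenvalue fraction), `loadings`.
#' @export
module_eigengene <- function(expr, members) {
  check_expr(expr)
  members <- intersect(members, rownames(expr))
  if (length(members) < 2) stop("need >= 2 member features")
  m <- expr[members, , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    mi <- is.na(m[i, ])
    if (any(mi)) m[i, mi] <- stats::median(m[i, ], na.rm = TRUE)
  }
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    m <- m[sds > 0, , drop = FALSE]
    if (nrow(m) < 2) stop("fewer than 2 members with nonzero SD")
  }
  z <- (m - rowMeans(m)) / apply(m, 1, stats::sd)
  pc <- tryCatch(stats::prcomp(t(z), center = FALSE, scale. = FALSE),
                 error = function(e) stop("degenerate covariance: ",
                                          conditionMessage(e)))
  ev <- pc$sdev^2
  if (!is.finite(ev[1]) || ev[1] <= 0) stop("degenerate covariance")
  loadings <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  if (mean(loadings) < 0) {
    loadings <- -loadings
    scores <- -scores
  }
  scores <- scores / stats::sd(scores)
  list(eigengene = stats::setNames(scores, colnames(expr)),
       variance_explained = ev[1] / sum(ev),
       loadings = loadings)
}
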