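#' Pairwise Canberra distances
#'
#' `sum_i |x_i - y_i| / (|x_i| + |y_i|)` per pair, skipping coordinates where
#' both entries are zero. This is the definition UMAP uses; it differs from
#' `stats::dist(method = "canberra")`, whose denominator is `|x_i + y_i|` and
#' misbehaves on signed data such as PCA scores.
#'
#' @param X numeric matrix, rows = observations.
#' @return A `dist` object.
#' @export
canberra_dist <- function(X) {
  X <- as.matrix(X)
  m <- nrow(X)
  D <- matrix(0, m, m)
  aX <- abs(X)
  for (a in seq_len(m - 1)) {
    idx <- (a + 1):m
    num <- abs(sweep(X[idx, , drop = FALSE], 2, X[a, ]))
    den <- sweep(aX[idx, , drop = FALSE], 2, aX[a, ], `+`)
    frac <- num / den
    frac[den == 0] <- 0
    D[idx, a] <- rowSums(frac)
  }
  stats::as.dist(D + t(D))
}

#' PCA reduction of the cell-by-cell similarity matrix
#'
#' Standard principal component scores on the mean-centered input. The
#' similarity matrix has one row per cell, so the scores are a
#' `cells x n_components` matrix.
#'
#' @param S numeric matrix (typically the symmetrized estimated-Jaccard
#'   similarity matrix from [knn_graph()]).
#' @param n_components number of components kept; must be < nrow(S).
#' @return score matrix `m x n_components`.
#' @export
reduce_pca <- function(S, n_components) {
  S <- as.matrix(S)
  if (n_components >= nrow(S))
    stop("n_components must be < number of cells")
  p <- stats::prcomp(S, center = TRUE, scale. = FALSE, rank. = n_components)
  p$x[, seq_len(n_components), drop = FALSE]
}

#' UMAP embedding
#'
#' Runs the published UMAP algorithm (via uwot) under the configured metric.
#' Canberra distances are computed by [canberra_dist()] and passed to UMAP as
#' precomputed distances. Deterministic given `seed` (single-threaded layout
#' optimization). Euclidean is the default: when the cluster signal is a
#' contact-decay gradient, it is carried by the magnitude of a few leading
#' principal components, which the per-coordinate scale-free Canberra metric
#' discards; `"canberra"` reproduces the published configuration and can help
#' on real populations whose structure spans many components.
#'
#' @param X numeric matrix, rows = cells (e.g. PCA scores).
#' @param n_components embedding dimensionality (default 5).
#' @param metric `"euclidean"` (default) or `"canberra"`.
#' @param n_neighbors UMAP neighborhood size (clamped to m - 1).
#' @param seed integer seed.
#' @return `m x n_components` embedding matrix.
#' @export
embed_umap <- function(X, n_components = 5, metric = "euclidean",
                       n_neighbors = 30, seed = 42) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (!metric %in% c("canberra", "euclidean"))
    stop("unknown metric '", metric, "'")
  nn <- max(2L, min(n_neighbors, m - 1L))
  input <- if (metric == "canberra") canberra_dist(X) else X
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  emb <- uwot::umap(input, n_components = n_components, n_neighbors = nn,
                    n_threads = 1, n_sgd_threads = 0, batch = FALSE)
  rownames(emb) <- rownames(X)
  emb
}

# Ng-Jordan-Weiss spectral clustering: RBF affinity with median-distance
# bandwidth, symmetric normalized Laplacian, k-means on the row-normalized
# top eigenvectors
spectral_labels <- function(X, n_clusters) {
  m <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  sigma2 <- stats::median(D2[upper.tri(D2)])
  if (sigma2 <= 0) sigma2 <- 1
  W <- exp(-D2 / (2 * sigma2))
  diag(W) <- 0
  d <- rowSums(W)
  d[d <= 0] <- 1e-12
  L <- sweep(sweep(W, 1, sqrt(d), `/`), 2, sqrt(d), `/`)
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, seq_len(n_clusters), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  U <- U / nrm
  stats::kmeans(U, centers = n_clusters, nstart = 25, iter.max = 100)$cluster
}

# flat single-level CF tree: points are absorbed into the nearest subcluster
# when the merged radius stays under threshold, else open a new subcluster
birch_subclusters <- function(X, threshold) {
  m <- nrow(X); p <- ncol(X)
  ns <- 0L
  N <- integer(0); LS <- matrix(0, 0, p); SS <- numeric(0)
  assign_sc <- integer(m)
  for (i in seq_len(m)) {
    x <- X[i, ]
    if (ns > 0L) {
      cent <- LS[seq_len(ns), , drop = FALSE] / N[seq_len(ns)]
      d2 <- rowSums(sweep(cent, 2, x)^2)
      best <- which.min(d2)
      nN <- N[best] + 1
      nLS <- LS[best, ] + x
      nSS <- SS[best] + sum(x^2)
      rad2 <- max(0, nSS / nN - sum((nLS / nN)^2))
      if (sqrt(rad2) <= threshold) {
        N[best] <- nN; LS[best, ] <- nLS; SS[best] <- nSS
        assign_sc[i] <- best
        next
      }
    }
    ns <- ns + 1L
    N <- c(N, 1L); LS <- rbind(LS, x); SS <- c(SS, sum(x^2))
    assign_sc[i] <- ns
  }
  list(centroids = LS / N, n = N, assign = assign_sc)
}

#' Cluster cells on an embedding
#'
#' Four algorithms with a user-specified fixed number of clusters: k-means,
#' spectral clustering (Ng-Jordan-Weiss: RBF affinity with median-distance
#' bandwidth, normalized Laplacian, k-means on the row-normalized leading
#' eigenvectors), BIRCH (a compact CF-tree implementation: threshold-bounded
#' subclusters, then Ward agglomeration of the subcluster centroids) and
#' agglomerative clustering (Ward linkage).
#'
#' @param embedding numeric matrix, rows = cells, finite-valued.
#' @param method one of `"spectral"` (default), `"kmeans"`, `"birch"`,
#'   `"agglomerative"`.
#' @param n_clusters fixed number of clusters, in `[1, m]`.
#' @param seed integer seed for the seeded algorithms.
#' @param birch_threshold CF-subcluster radius bound for BIRCH.
#' @return list of class `ClusterResult`: `labels` (0-based integers in
#'   `[0, n_clusters)`), `method`, `n_clusters`, `seed`.
#' @export
cluster_cells <- function(embedding, method = c("spectral", "kmeans", "birch",
                                                "agglomerative"),
                          n_clusters, seed = 42, birch_threshold = 0.5) {
  method <- match.arg(method)
  X <- as.matrix(embedding)
  m <- nrow(X)
  if (!all(is.finite(X))) stop("embedding must be finite-valued")
  if (n_clusters < 1 || n_clusters > m)
    stop("n_clusters must be in [1, ", m, "]")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  labels <-
    if (n_clusters == 1L) rep(0L, m)
    else if (n_clusters == m) seq_len(m) - 1L
    else switch(method,
      kmeans = stats::kmeans(X, centers = n_clusters, nstart = 10,
                             iter.max = 100)$cluster - 1L,
      spectral = as.integer(spectral_labels(X, n_clusters)) - 1L,
      agglomerative = stats::cutree(stats::hclust(stats::dist(X), method = "ward.D2"),
                                    k = n_clusters) - 1L,
      birch = {
        thr <- birch_threshold
        repeat {
          sc <- birch_subclusters(X, thr)
          if (nrow(sc$centroids) >= n_clusters || thr < 1e-8) break
          thr <- thr / 2
        }
        if (nrow(sc$centroids) < n_clusters)
          stop("BIRCH produced fewer subclusters than n_clusters")
        glob <- stats::cutree(stats::hclust(stats::dist(sc$centroids),
                                            method = "ward.D2"), k = n_clusters)
        as.integer(glob[sc$assign]) - 1L
      })
  structure(list(labels = as.integer(labels), method = method,
                 n_clusters = as.integer(n_clusters), seed = seed),
            class = "ClusterResult")
}

#' Run the full clustering pipeline
#'
#' flatten -> (optional intra-chromosomal restriction) -> MinHash approximate
#' k-NN similarity -> (optional PCA) -> (optional UMAP, Canberra) ->
#' clustering. Every intermediate is returned and full provenance recorded.
#'
#' @param pop a [cell_population()].
#' @param n_clusters fixed number of clusters.
#' @param h number of hash functions (default 800).
#' @param master_seed seed of the hash family.
#' @param k neighbors kept (`NULL` = full graph, k = m - 1).
#' @param mode k-NN mode, see [knn_graph()].
#' @param intra_only use only intra-chromosomal contacts (default TRUE).
#' @param use_pca,use_umap stage toggles; with both off, clustering consumes
#'   the raw symmetrized similarity matrix.
#' @param pca_components number of principal components (default
#'   `min(m - 1, 20)`).
#' @param umap_components UMAP dimensionality (default 5).
#' @param umap_neighbors UMAP neighborhood size (default 30).
#' @param umap_metric `"euclidean"` (default) or `"canberra"` (the published configuration).
#' @param cluster_method clustering algorithm (default `"spectral"`).
#' @param seed seed for embedding and clustering stages.
#' @param batch_share share of cells per index-fitting batch (low-memory
#'   mode); does not change results.
#' @return list of class `PipelineResult`: `labels` (0-based), `cell_ids`,
#'   `graph`, `embedding`, `provenance`.
#' @export
run_pipeline <- function(pop, n_clusters,
                         h = 800, master_seed = 1, k = NULL,
                         mode = "approximate", intra_only = TRUE,
                         use_pca = TRUE, use_umap = TRUE,
                         pca_components = NULL, umap_components = 5,
                         umap_neighbors = 30, umap_metric = "euclidean",
                         cluster_method = "spectral", seed = 42,
                         batch_share = 1) {
  stopifnot(inherits(pop, "CellPopulation"))
  flat <- compile_population(pop)
  m <- flat$m
  family <- hash_family(h = h, master_seed = master_seed)
  graph <- knn_graph(flat, family = family, k = k, mode = mode,
                     intra_only = intra_only, batch_share = batch_share)
  X <- graph$sim
  if (is.null(pca_components)) pca_components <- min(m - 1L, 20L)
  if (use_pca && use_umap && pca_components <= umap_components)
    stop("pca_components must exceed umap_components when both stages run")
  if (use_pca) X <- reduce_pca(X, pca_components)
  if (use_umap) X <- embed_umap(X, n_components = umap_components,
                                metric = umap_metric,
                                n_neighbors = umap_neighbors, seed = seed)
  cl <- cluster_cells(X, method = cluster_method, n_clusters = n_clusters,
                      seed = seed)
  structure(list(labels = cl$labels, cell_ids = flat$cell_ids, graph = graph,
                 embedding = X,
                 provenance = list(m = m, n_bins = flat$n_bins, h = h,
                                   master_seed = master_seed,
                                   k = graph$k, mode = mode,
                                   intra_only = intra_only, use_pca = use_pca,
                                   use_umap = use_umap,
                                   pca_components = pca_components,
                                   umap_components = umap_components,
                                   umap_neighbors = umap_neighbors,
                                   umap_metric = umap_metric,
                                   cluster_method = cluster_method,
                                   n_clusters = n_clusters, seed = seed,
                                   batch_share = batch_share)),
            class = "PipelineResult")
}

#' @method print PipelineResult
#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult:", length(x$labels), "cells in",
      x$provenance$n_clusters, "clusters (", x$provenance$cluster_method, ")\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Export an embedding with a provenance header
#'
#' @param result a [run_pipeline()] result.
#' @param path output TSV path; provenance is echoed as `# key=value` lines.
#' @export
write_embedding <- function(result, path) {
  stopifnot(inherits(result, "PipelineResult"))
  con <- file(path, "w")
  on.exit(close(con))
  prov <- result$provenance
  writeLines(paste0("# ", names(prov), "=", vapply(prov, paste, character(1))), con)
  emb <- as.matrix(result$embedding)
  df <- data.frame(cell_id = result$cell_ids, emb, check.names = FALSE)
  colnames(df) <- c("cell_id", paste0("dim", seq_len(ncol(emb))))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
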