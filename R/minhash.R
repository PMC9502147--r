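MODULUS_32 <- 4294967291  # largest 32-bit prime

#' Seeded family of 32-bit hash functions
#'
#' `h` hash functions share one mixing core (Thomas Wang's 32-bit mix) and
#' differ only by seed. Per-function seeds are a deterministic counter-based
#' expansion of `master_seed`: `seed_j = mix32(mix32(master_seed) + j)`. The
#' mix is a bijection on 32-bit integers, so seeds within a family are
#' pairwise distinct, and the inner mix scatters master seeds so that
#' differently seeded families are unrelated.
#'
#' @param h number of hash functions (default 800).
#' @param master_seed non-negative integer master seed.
#' @return list of class `HashFamily`: `h`, `master_seed`, `seeds`, `modulus`.
#' @export
hash_family <- function(h = 800, master_seed = 1) {
  stopifnot(h >= 1, master_seed >= 0)
  structure(list(h = as.integer(h),
                 master_seed = as.numeric(master_seed),
                 seeds = cpp_expand_seeds(master_seed, as.integer(h)),
                 modulus = MODULUS_32),
            class = "HashFamily")
}

#' Reduce a feature id into the 32-bit range
#'
#' Feature ids of fine-resolution matrices exceed 32 bits (n^2 grows to tens
#' of billions); they are reduced by modulo before hashing. The modulus is the
#' largest 32-bit prime, which avoids structured collisions from the row-major
#' feature layout.
#'
#' @param feature_id non-negative feature id(s), possibly > 2^32.
#' @param modulus reduction constant.
#' @return `feature_id %% modulus`, stable across runs.
#' @export
reduce_feature_id <- function(feature_id, modulus = MODULUS_32) {
  stopifnot(all(feature_id >= 0))
  feature_id %% modulus
}

#' Hash a reduced feature id under one seed
#'
#' `mix32(reduced_id XOR seed)`: deterministic, output in `[0, 2^32)`,
#' approximately uniform over random ids.
#'
#' @param seed per-function seed (from [hash_family()]).
#' @param reduced_id id(s) already reduced to the 32-bit range.
#' @return numeric hash value(s) in `[0, 2^32)`.
#' @export
hash_feature <- function(seed, reduced_id) {
  cpp_mix32(reduced_id, seed)
}

#' MinHash signature of one nonzero feature-id set
#'
#' Entry j is the argmin over `a` in `A` of `hash_feature(seed_j,
#' reduce_feature_id(a))` — the feature id attaining the minimum hash value,
#' with hash ties broken by the smallest feature id. An empty set yields the
#' sentinel -1 in every entry.
#'
#' @param A ascending numeric vector of nonzero feature ids (may be empty).
#' @param family a [hash_family()].
#' @return numeric signature vector of length `family$h`.
#' @export
minhash_signature <- function(A, family) {
  stopifnot(inherits(family, "HashFamily"))
  drop(cpp_signatures(list(sort(as.numeric(A))), family$seeds, family$modulus))
}

#' MinHash signatures of a whole flattened population
#'
#' @param flat a [compile_population()] result.
#' @param family a [hash_family()].
#' @return numeric `m x h` matrix of class `SignatureMatrix`; row c holds cell
#'   c's signature (sentinel -1 rows for cells with empty nonzero sets).
#' @export
signature_matrix <- function(flat, family) {
  stopifnot(inherits(flat, "FlattenedPopulation"), inherits(family, "HashFamily"))
  sig <- cpp_signatures(flat$sets, family$seeds, family$modulus)
  rownames(sig) <- flat$cell_ids
  structure(sig, class = c("SignatureMatrix", "matrix"),
            family = family[c("h", "master_seed", "modulus")])
}

merge_buckets <- function(keys1, cells1, keys2, cells2) {
  keys <- sort(unique(c(keys1, keys2)))
  i1 <- match(keys, keys1)
  i2 <- match(keys, keys2)
  cells <- vector("list", length(keys))
  for (t in seq_along(keys)) {
    cells[[t]] <- c(if (!is.na(i1[t])) cells1[[i1[t]]],
                    if (!is.na(i2[t])) cells2[[i2[t]]])
  }
  list(keys = keys, cells = cells)
}

fit_batch <- function(sig, cell_ids) {
  h <- ncol(sig)
  lapply(seq_len(h), function(j) {
    v <- sig[, j]
    ok <- v >= 0
    v <- v[ok]
    ids <- cell_ids[ok]
    keys <- sort(unique(v))
    list(keys = keys,
         cells = unname(split(ids, factor(v, levels = keys))))
  })
}

#' Fit the inverse index from a signature matrix
#'
#' Per hash function, the index maps each observed signature value to the
#' ascending list of cells holding it; querying a signature then costs one map
#' lookup per hash function, independent of the number of cells. Sentinel
#' (empty-set) rows are skipped. With `batch_share < 1` the signature rows are
#' inserted in consecutive batches covering that share of the cells each
#' (the low-memory fitting mode); the resulting index is bit-identical to
#' single-pass fitting.
#'
#' @param sig a [signature_matrix()] (any numeric m x h matrix is accepted,
#'   e.g. a hand-built example).
#' @param batch_share share of cells inserted per batch, in (0, 1].
#' @return list of class `InverseIndex`: `h`, `m`, `maps` (per function:
#'   `keys` sorted, `cells` list of ascending 1-based cell indices), `family`.
#' @export
fit_inverse_index <- function(sig, batch_share = 1) {
  sig <- as.matrix(sig)
  stopifnot(batch_share > 0, batch_share <= 1)
  m <- nrow(sig)
  h <- ncol(sig)
  if (m == 0) {
    maps <- replicate(h, list(keys = numeric(0), cells = list()),
                      simplify = FALSE)
  } else {
    bs <- max(1L, as.integer(ceiling(m * batch_share)))
    starts <- seq(1L, m, by = bs)
    maps <- NULL
    for (s in starts) {
      idx <- s:min(s + bs - 1L, m)
      part <- fit_batch(sig[idx, , drop = FALSE], idx)
      maps <- if (is.null(maps)) part else
        lapply(seq_len(h), function(j)
          merge_buckets(maps[[j]]$keys, maps[[j]]$cells,
                        part[[j]]$keys, part[[j]]$cells))
    }
  }
  structure(list(h = h, m = m, maps = maps,
                 family = attr(sig, "family")),
            class = "InverseIndex")
}

#' Count hash collisions of one signature against the index
#'
#' For each hash function the querying cell performs one index lookup under
#' its signature value and collects the cells stored there; occurrences are
#' counted per candidate and the querying cell itself is excluded. Exactly
#' `h` lookups are performed (attribute `lookups`), independent of m.
#'
#' @param sig_row numeric signature vector of length `index$h`.
#' @param index a [fit_inverse_index()] result.
#' @param self_id 1-based index of the querying cell (0 if not in the index).
#' @return integer vector of collision counts per cell (length `index$m`),
#'   with attribute `lookups`.
#' @export
query_collisions <- function(sig_row, index, self_id = 0) {
  stopifnot(inherits(index, "InverseIndex"), length(sig_row) == index$h)
  res <- cpp_query_all(matrix(as.numeric(sig_row), nrow = 1), index$maps,
                       index$m, as.integer(self_id))
  structure(drop(res$counts), lookups = res$lookups[1])
}

#' Estimated Jaccard similarity from a collision count
#'
#' The per-function collision probability of MinHash equals the Jaccard index,
#' so `collision_count / h` is an unbiased estimator of it.
#'
#' @param collision_count collisions observed over `h` functions.
#' @param h number of hash functions.
#' @return similarity in `[0, 1]`.
#' @export
estimate_jaccard <- function(collision_count, h) {
  if (h == 0) stop("h must be >= 1")
  stopifnot(all(collision_count >= 0), all(collision_count <= h))
  collision_count / h
}

#' Exact Jaccard index of two feature-id sets
#'
#' `|A n B| / |A u B|`; two empty sets are defined to have similarity 0.
#'
#' @param A,B finite numeric id sets.
#' @return similarity in `[0, 1]`.
#' @export
exact_jaccard <- function(A, B) {
  A <- unique(as.numeric(A)); B <- unique(as.numeric(B))
  u <- length(A) + length(B) - sum(A %in% B)
  if (u == 0) return(0)
  sum(A %in% B) / u
}

order_neighbors <- function(score, self, decreasing = TRUE) {
  ids <- seq_along(score)[-self]
  s <- score[-self]
  o <- if (decreasing) order(-s, ids) else order(s, ids)
  ids[o]
}

#' Approximate k-nearest-neighbor graph of a flattened population
#'
#' In `approximate` mode, MinHash signatures are computed and inserted into an
#' inverse index (fit), each cell then queries the index for hash collisions
#' (h lookups per cell), candidates are ranked by collision count (ties by
#' ascending cell index) and the top k kept, with edge weight
#' `collisions / h` (the estimated Jaccard). `exact_jaccard` mode ranks by the
#' exact Jaccard index over all pairs (the quadratic oracle path).
#' `euclidean_rerank` mode pre-selects candidates by collisions and re-ranks
#' them by Euclidean distance on the raw flattened rows.
#'
#' @param flat a [compile_population()] result.
#' @param family a [hash_family()] (ignored in `exact_jaccard` mode).
#' @param k neighbors kept per cell; `NULL` (default) keeps the full graph,
#'   k = m - 1.
#' @param mode one of `"approximate"`, `"exact_jaccard"`, `"euclidean_rerank"`.
#' @param intra_only drop inter-chromosomal features first (default TRUE).
#' @param batch_share share of cells per fitting batch, in (0, 1]; the
#'   low-memory mode. Result is identical for any value.
#' @return list of class `KnnGraph`: `neighbors` (per cell, a data.frame with
#'   `neighbor`, `collisions`, `est_jaccard` and, in rerank mode,
#'   `euclidean`), `sim` (symmetrized m x m similarity matrix for the
#'   embedding stage), `k`, `h`, `mode`, `cell_ids`, `lookups` per query.
#' @export
knn_graph <- function(flat, family = NULL, k = NULL,
                      mode = c("approximate", "exact_jaccard", "euclidean_rerank"),
                      intra_only = TRUE, batch_share = 1) {
  stopifnot(inherits(flat, "FlattenedPopulation"))
  mode <- match.arg(mode)
  m <- flat$m
  if (m < 2) stop("need at least 2 cells")
  if (is.null(k)) k <- m - 1L
  if (k < 1 || k > m - 1) stop("k must be in [1, m-1]")
  if (intra_only) flat <- restrict_intra_chromosomal(flat)
  empty <- lengths(flat$sets) == 0
  if (any(empty))
    warning(sum(empty), " cell(s) have empty nonzero sets and get empty neighbor lists")

  lookups <- NULL
  h <- NA_integer_
  if (mode == "exact_jaccard") {
    S <- cpp_jaccard_matrix(flat$sets)
    diag(S) <- 0
    counts <- NULL
  } else {
    stopifnot(inherits(family, "HashFamily"))
    h <- family$h
    sig <- signature_matrix(flat, family)
    index <- fit_inverse_index(sig, batch_share = batch_share)
    res <- cpp_query_all(unclass(sig)[, , drop = FALSE], index$maps,
                         m, seq_len(m))
    counts <- res$counts
    lookups <- res$lookups
    S <- counts / h
  }

  neighbors <- vector("list", m)
  for (c in seq_len(m)) {
    if (empty[c]) {
      neighbors[[c]] <- data.frame(neighbor = integer(0), collisions = integer(0),
                                   est_jaccard = numeric(0))
      next
    }
    nb <- order_neighbors(S[c, ], c)[seq_len(k)]
    df <- data.frame(neighbor = nb,
                     collisions = if (is.null(counts)) NA_integer_ else counts[c, nb],
                     est_jaccard = S[c, nb])
    if (mode == "euclidean_rerank") {
      d2 <- vapply(nb, function(b)
        cpp_sparse_euclidean2(flat$sets[[c]], flat$values[[c]],
                              flat$sets[[b]], flat$values[[b]]), numeric(1))
      o <- order(d2, nb)
      df <- df[o, , drop = FALSE]
      df$euclidean <- sqrt(d2[o])
      rownames(df) <- NULL
    }
    neighbors[[c]] <- df
  }

  # symmetrized similarity matrix for the embedding stage
  if (k == m - 1L) {
    sym <- (S + t(S)) / 2
  } else {
    kept <- matrix(0, m, m)
    for (c in seq_len(m)) {
      nb <- neighbors[[c]]$neighbor
      kept[c, nb] <- S[c, nb]
    }
    sym <- pmax(kept, t(kept))
  }
  dimnames(sym) <- list(flat$cell_ids, flat$cell_ids)

  structure(list(neighbors = neighbors, sim = sym, k = as.integer(k), h = h,
                 mode = mode, cell_ids = flat$cell_ids, lookups = lookups),
            class = "KnnGraph")
}

#' @method print KnnGraph
#' @export
print.KnnGraph <- function(x, ...) {
  cat("KnnGraph:", length(x$neighbors), "cells, k =", x$k,
      ", mode =", x$mode, if (!is.na(x$h)) paste(", h =", x$h), "\n")
  invisible(x)
}

#' Re-rank pre-selected candidates by Euclidean distance
#'
#' Distances are computed on the raw flattened rows between the query and each
#' candidate only (never all pairs); candidates are returned in ascending
#' distance order, ties by ascending cell index.
#'
#' @param candidates cell indices pre-selected (e.g. by hash collisions).
#' @param flat a `FlattenedPopulation`.
#' @param query_id 1-based index of the querying cell.
#' @return data.frame `candidate`, `euclidean`, sorted.
#' @export
euclidean_rerank <- function(candidates, flat, query_id) {
  stopifnot(inherits(flat, "FlattenedPopulation"), length(candidates) >= 1)
  d2 <- vapply(candidates, function(b)
    cpp_sparse_euclidean2(flat$sets[[query_id]], flat$values[[query_id]],
                          flat$sets[[b]], flat$values[[b]]), numeric(1))
  o <- order(d2, candidates)
  data.frame(candidate = candidates[o], euclidean = sqrt(d2[o]))
}

#' Export a k-NN graph
#'
#' Writes the symmetrized similarity matrix as Matrix Market and the neighbor
#' lists as TSV (`query_id`, `neighbor_id`, `collisions`, `est_jaccard`).
#'
#' @param graph a [knn_graph()] result.
#' @param mtx_path,tsv_path output paths (`NULL` to skip either).
#' @export
write_knn_graph <- function(graph, mtx_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(graph, "KnnGraph"))
  if (!is.null(mtx_path))
    Matrix::writeMM(methods::as(Matrix::Matrix(graph$sim, sparse = TRUE), "generalMatrix"),
                    mtx_path)
  if (!is.null(tsv_path)) {
    rows <- do.call(rbind, lapply(seq_along(graph$neighbors), function(c) {
      df <- graph$neighbors[[c]]
      if (!nrow(df)) return(NULL)
      data.frame(query_id = graph$cell_ids[c],
                 neighbor_id = graph$cell_ids[df$neighbor],
                 collisions = df$collisions,
                 est_jaccard = df$est_jaccard)
    }))
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
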