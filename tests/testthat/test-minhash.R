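test_that("hash family seeds are deterministic and pairwise distinct", {
  f1 <- hash_family(1000, 42)
  f2 <- hash_family(1000, 42)
  expect_identical(f1, f2)
  expect_equal(anyDuplicated(f1$seeds), 0)
  expect_false(any(hash_family(100, 1)$seeds %in% hash_family(100, 2)$seeds[1:5]))
})

test_that("feature-id reduction is a plain modulo into 32 bits", {
  mod <- 4294967291
  expect_equal(reduce_feature_id(123), 123)
  expect_equal(reduce_feature_id(mod), 0)
  set.seed(1)
  ids <- floor(runif(1e4, 0, 76e9))  # fine-resolution feature-id regime
  red <- reduce_feature_id(ids)
  expect_true(all(red >= 0 & red < mod))
  expect_equal(length(unique(red)), length(unique(ids %% mod)))
})

test_that("the compiled hash matches an independent R implementation", {
  set.seed(4)
  ids <- floor(runif(200, 0, 2^32))
  for (seed in c(0, 1, 77, 2^31)) {
    expect_equal(hash_feature(seed, ids), r_mix32(ids, seed))
  }
  # determinism and near-uniformity
  expect_identical(hash_feature(9, ids), hash_feature(9, ids))
  hv <- hash_feature(5, floor(runif(1e5, 0, 2^32)))
  se <- 2^32 / sqrt(12 * 1e5)
  expect_lt(abs(mean(hv) - 2^31), 5 * se)
  # distinct seeds rarely agree on one id
  outs <- vapply(1:1000, function(s) hash_feature(s, 42), numeric(1))
  expect_gte(length(unique(outs)), 999)
})

test_that("signatures are the argmin feature id under each hash function", {
  fam <- hash_family(16, 3)
  set.seed(11)
  A <- sort(sample.int(1e6, 40))
  sig <- minhash_signature(A, fam)
  oracle <- vapply(fam$seeds, function(s) {
    hv <- r_mix32(A %% fam$modulus, s)
    A[which.min(hv)]  # which.min takes the first = smallest feature id on ties
  }, numeric(1))
  expect_equal(sig, oracle)
  expect_true(all(sig %in% A))
  # singleton and empty sets
  expect_equal(unique(minhash_signature(77, fam)), 77)
  expect_equal(unique(minhash_signature(numeric(0), fam)), -1)
  # identical sets, identical signatures
  expect_identical(minhash_signature(A, fam), minhash_signature(rev(A), fam))
})

test_that("the inverse index groups cells by signature value per function", {
  # four cells, three hash functions; function 1 values 2, 4, 4, 5
  sig <- rbind(c(2, 9, 6), c(4, 7, 2), c(4, 8, 2), c(5, 7, 3))
  idx <- fit_inverse_index(sig)
  expect_equal(idx$maps[[1]]$keys, c(2, 4, 5))
  expect_equal(idx$maps[[1]]$cells, list(1L, c(2L, 3L), 4L))
  # querying cell 2 surfaces cell 3 via their shared function-1 value
  hits <- query_collisions(sig[2, ], idx, self_id = 2)
  expect_gte(hits[3], 1)
  expect_equal(hits[2], 0)
  # stored pairs = h x (cells with non-sentinel rows)
  total <- sum(vapply(idx$maps, function(mp) sum(lengths(mp$cells)), numeric(1)))
  expect_equal(total, 3 * 4)
  # sentinel rows are skipped
  sig2 <- rbind(sig, c(-1, -1, -1))
  idx2 <- fit_inverse_index(sig2)
  total2 <- sum(vapply(idx2$maps, function(mp) sum(lengths(mp$cells)), numeric(1)))
  expect_equal(total2, 3 * 4)
  # empty input
  idx0 <- fit_inverse_index(matrix(numeric(0), 0, 3))
  expect_equal(idx0$m, 0)
})

test_that("stored pair count scales as h x m on a random fixture", {
  pop <- make_population(m = 20, n = 15, seed = 5)
  flat <- compile_population(pop)
  fam <- hash_family(8, 1)
  idx <- fit_inverse_index(signature_matrix(flat, fam))
  total <- sum(vapply(idx$maps, function(mp) sum(lengths(mp$cells)), numeric(1)))
  expect_equal(total, 8 * 20)
})

test_that("collision counts equal coordinate-wise signature agreement", {
  pop <- make_population(m = 12, n = 15, n_contacts = 25, seed = 8)
  flat <- compile_population(pop)
  fam <- hash_family(64, 2)
  sig <- signature_matrix(flat, fam)
  idx <- fit_inverse_index(sig)
  for (a in c(1, 5, 12)) {
    hits <- query_collisions(sig[a, ], idx, self_id = a)
    oracle <- vapply(seq_len(12), function(b)
      if (b == a) 0L else sum(sig[a, ] == sig[b, ]), integer(1))
    expect_equal(hits, oracle, ignore_attr = TRUE)
    expect_equal(attr(hits, "lookups", exact = TRUE), 64L)
  }
  # symmetry over all pairs
  g <- knn_graph(flat, fam, intra_only = FALSE)
  C <- vapply(seq_len(12), function(a) {
    v <- numeric(12)
    df <- g$neighbors[[a]]
    v[df$neighbor] <- df$collisions
    v
  }, numeric(12))
  expect_equal(C, t(C))
})

test_that("estimate_jaccard is collisions over h with guarded bounds", {
  expect_equal(estimate_jaccard(0, 10), 0)
  expect_equal(estimate_jaccard(10, 10), 1)
  expect_error(estimate_jaccard(1, 0), "h")
  expect_error(estimate_jaccard(11, 10))
})

test_that("exact Jaccard handles the arithmetic and degenerate cases", {
  expect_equal(exact_jaccard(1:3, 2:4), 0.5)
  expect_equal(exact_jaccard(5:9, 5:9), 1)
  expect_equal(exact_jaccard(1:3, 4:6), 0)
  expect_equal(exact_jaccard(numeric(0), numeric(0)), 0)
  expect_equal(exact_jaccard(numeric(0), 1:3), 0)
})

test_that("MinHash is an unbiased Jaccard estimator across seeded families", {
  # one fixed pair with J = 8/12, >= 50 independently seeded families
  set.seed(21)
  pr <- make_set_pair(8 / 12, 12)
  J <- exact_jaccard(pr$A, pr$B)
  expect_equal(J, 8 / 12)
  h <- 200
  fams <- 50
  coll <- vapply(seq_len(fams), function(ms) {
    fam <- hash_family(h, ms)
    sum(minhash_signature(pr$A, fam) == minhash_signature(pr$B, fam))
  }, numeric(1))
  p_hat <- sum(coll) / (h * fams)
  se <- sqrt(J * (1 - J) / (h * fams))
  expect_lt(abs(p_hat - J), 4 * se)
})

test_that("exact-mode k-NN equals a naive double-loop oracle", {
  pop <- make_population(m = 30, n = 18, n_contacts = 30, seed = 13)
  flat <- compile_population(pop)
  g <- knn_graph(flat, mode = "exact_jaccard", intra_only = FALSE)
  for (a in seq_len(30)) {
    J <- vapply(seq_len(30), function(b) {
      if (b == a) return(-1)
      A <- flat$sets[[a]]; B <- flat$sets[[b]]
      length(intersect(A, B)) / length(union(A, B))
    }, numeric(1))
    ids <- setdiff(seq_len(30), a)
    oracle <- ids[order(-J[ids], ids)]
    expect_equal(g$neighbors[[a]]$neighbor, oracle)
    expect_equal(g$neighbors[[a]]$est_jaccard, J[oracle])
  }
})

test_that("approximate mode recovers oracle neighbors on structured data", {
  flat <- window_flat(m = 25, n_features = 400, width = 80, step = 10)
  oracle <- knn_graph(flat, mode = "exact_jaccard", intra_only = FALSE, k = 5)
  approx <- knn_graph(flat, hash_family(3000, 7), intra_only = FALSE, k = 5)
  recall <- mean(vapply(seq_len(25), function(c)
    length(intersect(approx$neighbors[[c]]$neighbor,
                     oracle$neighbors[[c]]$neighbor)) / 5, numeric(1)))
  expect_gte(recall, 0.9)
})

test_that("two-cell populations neighbor each other", {
  pop <- make_population(m = 2, n = 10, seed = 1)
  g <- knn_graph(compile_population(pop), hash_family(50, 1))
  expect_equal(g$neighbors[[1]]$neighbor, 2)
  expect_equal(g$neighbors[[2]]$neighbor, 1)
})

test_that("cells with empty nonzero sets get empty neighbor lists and a warning", {
  bins <- bin_table(c("chr1", "chr1", "chr2"), c(0, 1, 0) * 1e6,
                    c(1, 2, 1) * 1e6)
  cells <- list(cell_contact_matrix("a", 0, 1, 2),
                cell_contact_matrix("b", c(0, 1), c(1, 1), c(1, 1)),
                cell_contact_matrix("inter_only", 0, 2, 3))
  flat <- compile_population(cell_population(bins, cells))
  expect_warning(g <- knn_graph(flat, hash_family(20, 1), intra_only = TRUE),
                 "empty")
  expect_equal(nrow(g$neighbors[[3]]), 0)
})

test_that("euclidean re-ranking orders candidates by raw-row distance", {
  pop <- make_population(m = 12, n = 14, n_contacts = 20, seed = 17)
  flat <- compile_population(pop)
  cand <- 2:11
  rr <- euclidean_rerank(cand, flat, query_id = 1)
  dense <- t(vapply(seq_len(12), function(c) dense_row_from_flat(flat, c),
                    numeric(flat$n_features)))
  d <- sqrt(colSums((t(dense[cand, ]) - dense[1, ])^2))
  expect_equal(rr$candidate, cand[order(d, cand)])
  expect_equal(rr$euclidean, sort(d))
  # identical candidate ranks first with distance 0
  expect_equal(euclidean_rerank(c(5, 1), flat, 1)$candidate[1], 1)
  expect_equal(euclidean_rerank(c(5, 1), flat, 1)$euclidean[1], 0)
  # single candidate unchanged
  expect_equal(euclidean_rerank(7, flat, 1)$candidate, 7)
  # rerank mode sorts neighbor lists by distance
  g <- knn_graph(flat, hash_family(200, 1), mode = "euclidean_rerank",
                 intra_only = FALSE, k = 5)
  expect_false(is.unsorted(g$neighbors[[1]]$euclidean))
})

test_that("graphs are deterministic and identical under batched fitting", {
  pop <- make_population(m = 23, n = 16, n_contacts = 25, seed = 19)
  flat <- compile_population(pop)
  fam <- hash_family(120, 5)
  g1 <- knn_graph(flat, fam, batch_share = 1)
  g2 <- knn_graph(flat, fam, batch_share = 0.3)
  g3 <- knn_graph(flat, fam, batch_share = 0.07)
  expect_identical(g1, g2)
  expect_identical(g1, g3)
  sig <- signature_matrix(flat, fam)
  expect_identical(fit_inverse_index(sig, 1), fit_inverse_index(sig, 0.25))
  # same inputs, same graph
  expect_identical(g1, knn_graph(flat, hash_family(120, 5)))
})

test_that("each query performs exactly h index lookups regardless of m", {
  for (m in c(10, 100)) {
    sets <- lapply(seq_len(m), function(c) sort(sample.int(1e5, 30)))
    flat <- window_flat(m, 1, 1, 1)  # shell; replace sets
    flat$sets <- sets
    flat$values <- lapply(sets, function(s) rep(1, length(s)))
    flat$m <- m
    flat$cell_ids <- sprintf("c%04d", seq_len(m))
    fam <- hash_family(48, 9)
    sig <- signature_matrix(flat, fam)
    idx <- fit_inverse_index(sig)
    for (c in sample.int(m, 5)) {
      hits <- query_collisions(sig[c, ], idx, self_id = c)
      expect_equal(attr(hits, "lookups", exact = TRUE), 48L)
    }
    g <- knn_graph(flat, fam, intra_only = FALSE)
    expect_true(all(g$lookups == 48L))
  }
})
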