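# Independent R re-implementation of the Wang 32-bit mix (oracle for the
# compiled hash path). All arithmetic on doubles, 32-bit wrap via %% 2^32.
r_xor32 <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  hi * 65536 + lo
}
r_mix32 <- function(key, seed = 0) {
  two32 <- 2^32
  k <- r_xor32(key %% two32, seed %% two32)
  k <- (two32 - 1 - k + (k * 2^15)) %% two32
  k <- r_xor32(k, k %/% 2^12)
  k <- (k + k * 2^2) %% two32
  k <- r_xor32(k, k %/% 2^4)
  k <- (k * 2057) %% two32
  r_xor32(k, k %/% 2^16)
}

# small random population: n bins on one or two chromosomes, random
# upper-triangle contacts
make_population <- function(m = 10, n = 20, n_contacts = 15, seed = 1,
                            two_chroms = FALSE) {
  set.seed(seed)
  bins <- if (two_chroms)
    bin_table(rep(c("chr1", "chr2"), each = n / 2),
              rep(seq(0, n / 2 - 1) * 1e6, 2),
              rep(seq_len(n / 2) * 1e6, 2))
  else
    bin_table(rep("chr1", n), seq(0, n - 1) * 1e6, seq_len(n) * 1e6)
  cells <- lapply(seq_len(m), function(c) {
    pairs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE) - 1L
    pick <- sample(nrow(pairs), n_contacts)
    cell_contact_matrix(sprintf("cell_%02d", c),
                        pairs[pick, 1], pairs[pick, 2],
                        sample(1:5, n_contacts, replace = TRUE))
  })
  cell_population(bins, cells)
}

# dense mirror of one cell, the brute-force reference for flattening
dense_cell <- function(cell, n) {
  M <- matrix(0, n, n)
  ct <- cell$contacts
  for (t in seq_len(nrow(ct))) {
    M[ct$bin1[t] + 1, ct$bin2[t] + 1] <- ct$count[t]
    M[ct$bin2[t] + 1, ct$bin1[t] + 1] <- ct$count[t]
  }
  M
}

dense_row_from_flat <- function(flat, c) {
  v <- numeric(flat$n_features)
  v[flat$sets[[c]] + 1] <- flat$values[[c]]
  v
}

# hand-built flattened population whose cells carry sliding-window feature
# sets: Jaccard decays smoothly with cell-index distance, so neighbor ranks
# are unambiguous
window_flat <- function(m, n_features, width, step) {
  sets <- lapply(seq_len(m), function(c) {
    start <- (c - 1) * step
    as.numeric(seq(start, start + width - 1) %% n_features)
  })
  sets <- lapply(sets, sort)
  structure(list(m = m, n_bins = NA_integer_, n_features = n_features,
                 cell_ids = sprintf("w%03d", seq_len(m)),
                 sets = sets,
                 values = lapply(sets, function(s) rep(1, length(s))),
                 bins = NULL),
            class = "FlattenedPopulation")
}

# random id-set pair with a prescribed Jaccard index
make_set_pair <- function(target_j, union_size, id_max = 1e7) {
  inter <- min(union_size - 1L, max(1L, round(target_j * union_size)))
  a_only <- (union_size - inter) %/% 2
  ids <- sample.int(id_max, union_size)
  b_idx <- c(seq_len(inter),
             setdiff(seq_len(union_size), seq_len(inter + a_only)))
  list(A = sort(ids[seq_len(inter + a_only)]),
       B = sort(ids[b_idx]))
}

make_blobs <- function(per = 20, centers = rbind(c(0, 0), c(10, 0), c(5, 9)),
                       sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(g)
    cbind(stats::rnorm(per, centers[g, 1], sd),
          stats::rnorm(per, centers[g, 2], sd))))
  list(X = X, truth = rep(seq_len(nrow(centers)), each = per))
}
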