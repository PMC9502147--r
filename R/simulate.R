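#' Specification of a synthetic single-cell Hi-C population
#'
#' Defines the study conditions the generator emulates: cluster structure is
#' carried by the contact-decay constant alpha (contacts at bin distance d are
#' sampled with weight `exp(-alpha * d)`), the sparsity regime by the target
#' per-cell density (nonzero fraction of the symmetrized n x n grid). Defaults
#' describe a 300-cell population on one 300 Mb chromosome binned at 1 Mb with
#' three equally sized clusters whose decay constants form a 2x ladder, at a
#' density of 5e-3.
#'
#' @param m number of cells.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bin width (bp).
#' @param proportions cluster mixing proportions (sum to 1).
#' @param alphas per-cluster decay constants (per bin, > 0).
#' @param density target per-cell nonzero fraction of the n x n grid, (0, 1].
#' @param lambda rate of the shifted Poisson for contact counts (counts are
#'   `1 + Poisson(lambda)`).
#' @param tad_boundaries optional 0-based bin ids at which TAD blocks start;
#'   pairs within one block get their weight multiplied by `tad_enrichment`.
#' @param tad_enrichment multiplicative weight boost inside TAD blocks.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return list of class `PopulationSpec`.
#' @export
population_spec <- function(m = 300,
                            chrom_lengths = c(chr1 = 300e6),
                            bin_size = 1e6,
                            proportions = c(1, 1, 1) / 3,
                            alphas = c(0.04, 0.08, 0.16),
                            density = 5e-3,
                            lambda = 0.3,
                            tad_boundaries = NULL,
                            tad_enrichment = 3,
                            seed = 1) {
  stopifnot(m >= 1, bin_size > 0, all(alphas > 0),
            length(proportions) == length(alphas),
            density > 0, density <= 1, lambda >= 0)
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("cluster proportions must sum to 1")
  structure(list(m = as.integer(m), chrom_lengths = chrom_lengths,
                 bin_size = bin_size, proportions = proportions,
                 alphas = alphas, density = density, lambda = lambda,
                 tad_boundaries = tad_boundaries,
                 tad_enrichment = tad_enrichment, seed = as.integer(seed)),
            class = "PopulationSpec")
}

#' Generate a synthetic population with known cluster labels
#'
#' For each cell of cluster g, candidate intra-chromosomal bin pairs (i, j),
#' i <= j, are sampled without replacement with probability proportional to
#' `exp(-alpha_g * |i - j|)` (optionally boosted within TAD blocks) until the
#' target nonzero count of the symmetrized matrix is reached; counts are drawn
#' from a shifted Poisson (>= 1).
#'
#' @param spec a [population_spec()].
#' @return list with `population` (a [cell_population()]) and `truth`
#'   (integer cluster label per cell, 1-based, aligned with cell order).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "PopulationSpec"))
  bins <- bin_table_from_lengths(spec$chrom_lengths, spec$bin_size)
  n <- n_bins(bins)

  # candidate intra-chromosomal upper-triangle pairs, 0-based global bin ids
  chrom_of <- bins$chrom
  offs <- c(0, cumsum(rle(chrom_of)$lengths))
  cand_i <- integer(0); cand_j <- integer(0)
  for (t in seq_along(rle(chrom_of)$values)) {
    nb <- offs[t + 1] - offs[t]
    local <- which(upper.tri(matrix(0, nb, nb), diag = TRUE), arr.ind = TRUE)
    cand_i <- c(cand_i, offs[t] + local[, 1] - 1L)
    cand_j <- c(cand_j, offs[t] + local[, 2] - 1L)
  }
  dist_bins <- cand_j - cand_i
  n_cand <- length(cand_i)

  # pairs needed so the symmetrized nonzero count hits density * n^2
  target_sym <- spec$density * n * n
  u <- max(1L, as.integer(round(target_sym / 2)))
  if (u > n_cand)
    stop("density ", spec$density, " infeasible: needs ", u,
         " intra-chromosomal pairs but only ", n_cand, " exist")

  tad_boost <- rep(1, n_cand)
  if (!is.null(spec$tad_boundaries)) {
    block <- findInterval(cand_i, sort(spec$tad_boundaries))
    same <- block == findInterval(cand_j, sort(spec$tad_boundaries))
    tad_boost[same] <- spec$tad_enrichment
  }

  G <- length(spec$proportions)
  weights <- lapply(seq_len(G), function(g)
    exp(-spec$alphas[g] * dist_bins) * tad_boost)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  sizes <- diff(round(cumsum(c(0, spec$proportions)) * spec$m))
  sizes[G] <- spec$m - sum(sizes[-G])
  truth <- sample(rep(seq_len(G), times = sizes))

  cells <- vector("list", spec$m)
  width <- nchar(as.character(spec$m))
  for (c in seq_len(spec$m)) {
    g <- truth[c]
    picked <- sample.int(n_cand, u, replace = FALSE, prob = weights[[g]])
    counts <- 1 + stats::rpois(u, spec$lambda)
    cells[[c]] <- cell_contact_matrix(
      sprintf("cell_%0*d", width, c),
      cand_i[picked], cand_j[picked], counts)
  }
  list(population = cell_population(bins, cells), truth = truth)
}
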