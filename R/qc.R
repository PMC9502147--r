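bin_width <- function(bins) {
  w <- bins$end - bins$start
  as.numeric(stats::median(w))
}

#' Contact-decay profile of a clustered population
#'
#' Per cell, intra-chromosomal contacts are accumulated by bin distance
#' `|i - j|` and normalized to the cell's total (cells without contacts give a
#' zero column, with a warning). Columns are ordered by cluster, and within
#' each cluster by descending short/long contact ratio (contacts at genomic
#' distance <= `d_short_bp` over contacts beyond it), so cells with similar
#' decay behaviour sit next to each other.
#'
#' @param pop a [cell_population()].
#' @param labels cluster label per cell (any atomic type, length m).
#' @param d_short_bp short/long boundary in bp (default 2 Mb).
#' @return list of class `ContactDecayProfile`: `profile` (distances x cells,
#'   rows = 0 .. max intra distance, columns reordered), `order` (data.frame
#'   `cell_id`, `cluster`, `ratio` in column order).
#' @export
contact_decay_profile <- function(pop, labels, d_short_bp = 2e6) {
  stopifnot(inherits(pop, "CellPopulation"))
  m <- n_cells(pop)
  if (length(labels) != m) stop("labels must have one entry per cell")
  bins <- pop$bins
  chrom_sizes <- rle(bins$chrom)$lengths
  maxd <- max(chrom_sizes) - 1L
  chroms <- bins$chrom
  prof <- matrix(0, maxd + 1L, m,
                 dimnames = list(0:maxd, names(pop$cells)))
  for (c in seq_len(m)) {
    ct <- pop$cells[[c]]$contacts
    if (!nrow(ct)) next
    intra <- chroms[ct$bin1 + 1] == chroms[ct$bin2 + 1]
    ct <- ct[intra, , drop = FALSE]
    if (!nrow(ct)) next
    d <- ct$bin2 - ct$bin1
    acc <- rowsum(ct$count, d)
    prof[as.integer(rownames(acc)) + 1L, c] <- acc[, 1]
  }
  tot <- colSums(prof)
  zero <- tot == 0
  if (any(zero))
    warning(sum(zero), " cell(s) without intra-chromosomal contacts give zero columns")
  prof[, !zero] <- sweep(prof[, !zero, drop = FALSE], 2, tot[!zero], `/`)

  d_short <- floor(d_short_bp / bin_width(bins))
  short <- colSums(prof[0:maxd <= d_short, , drop = FALSE])
  long <- colSums(prof) - short
  ratio <- ifelse(long > 0, short / long, Inf)
  ord <- order(labels, -ratio, seq_len(m))
  structure(list(profile = prof[, ord, drop = FALSE],
                 order = data.frame(cell_id = names(pop$cells)[ord],
                                    cluster = labels[ord],
                                    ratio = ratio[ord])),
            class = "ContactDecayProfile")
}

#' Consensus (bulk mean) matrix of one cluster
#'
#' Entry-wise mean of the symmetrized contact matrices of the cluster's
#' cells. With `chrom` given, only that chromosome's block is computed, which
#' bounds memory at fine resolutions.
#'
#' @param pop a [cell_population()].
#' @param labels cluster label per cell.
#' @param cluster_id the cluster to aggregate.
#' @param chrom optional chromosome name restricting the block.
#' @return dense symmetric matrix (n x n, or block-sized).
#' @export
consensus_matrix <- function(pop, labels, cluster_id, chrom = NULL) {
  stopifnot(inherits(pop, "CellPopulation"))
  members <- which(labels == cluster_id)
  if (!length(members)) stop("unknown or empty cluster '", cluster_id, "'")
  bins <- pop$bins
  if (is.null(chrom)) {
    sel <- seq_len(n_bins(bins)) - 1L
  } else {
    sel <- which(bins$chrom == chrom) - 1L
    if (!length(sel)) stop("unknown chromosome '", chrom, "'")
  }
  nb <- length(sel)
  off <- min(sel)
  M <- matrix(0, nb, nb)
  for (c in members) {
    ct <- pop$cells[[c]]$contacts
    keep <- ct$bin1 %in% sel & ct$bin2 %in% sel
    ct <- ct[keep, , drop = FALSE]
    if (!nrow(ct)) next
    i <- ct$bin1 - off + 1L
    j <- ct$bin2 - off + 1L
    for (t in seq_len(nrow(ct))) {
      M[i[t], j[t]] <- M[i[t], j[t]] + ct$count[t]
      if (i[t] != j[t]) M[j[t], i[t]] <- M[j[t], i[t]] + ct$count[t]
    }
  }
  M / length(members)
}

#' Detection rate at a uniqueness threshold
#'
#' A cluster is assigned to true class c iff the fraction of its cells with
#' class c is at least `threshold`; a threshold above 0.5 makes the
#' assignment unique. The detection rate of class c is the share of its cells
#' that fall inside clusters assigned to c, in percent.
#'
#' @param labels predicted cluster per cell.
#' @param truth true class per cell.
#' @param threshold uniqueness threshold in (0.5, 1].
#' @return list of class `DetectionReport`: `rates` (percent per class),
#'   `composition` (cluster x class fraction matrix, rows sum to 1),
#'   `assignment` (class per cluster or NA), `threshold`.
#' @export
uniqueness_detection_rate <- function(labels, truth, threshold = 0.7) {
  if (length(labels) != length(truth)) stop("labels and truth must align")
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must be in (0.5, 1] so the assignment is unique")
  tab <- table(cluster = labels, class = truth)
  comp <- tab / rowSums(tab)
  assigned <- apply(comp, 1, function(r) {
    hit <- which(r >= threshold)
    if (length(hit) == 1) colnames(comp)[hit] else NA_character_
  })
  classes <- colnames(comp)
  rates <- vapply(classes, function(cl) {
    in_cl <- truth == cl
    captured <- labels %in% names(assigned)[!is.na(assigned) & assigned == cl]
    100 * sum(in_cl & captured) / sum(in_cl)
  }, numeric(1))
  structure(list(rates = rates, composition = unclass(comp),
                 assignment = assigned, threshold = threshold),
            class = "DetectionReport")
}

#' @method print DetectionReport
#' @export
print.DetectionReport <- function(x, ...) {
  cat("DetectionReport (uniqueness threshold", x$threshold, ")\n")
  print(round(x$rates, 1))
  invisible(x)
}

#' Adjusted Rand index and cluster purity
#'
#' @param labels predicted cluster per cell.
#' @param truth true class per cell.
#' @return list: `ari`, `purity` (overall), `per_cluster_purity`.
#' @export
cluster_agreement <- function(labels, truth) {
  if (length(labels) != length(truth)) stop("labels and truth must align")
  tab <- table(labels, truth)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  ari <- if (max_index == expected) 1 else (sum_ij - expected) / (max_index - expected)
  per_cluster <- apply(tab, 1, max) / rowSums(tab)
  list(ari = ari,
       purity = sum(apply(tab, 1, max)) / n,
       per_cluster_purity = per_cluster)
}
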