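#' Construct a bin table
#'
#' A bin table describes the fixed-width genomic intervals (bins) that index
#' the rows and columns of every contact matrix in a population. Coordinates
#' are 0-based, half-open (BED convention); bin ids are global, 0-based and
#' ordered by (chrom, start).
#'
#' @param chrom character vector, chromosome name per bin.
#' @param start,end integer-valued genomic coordinates in bp.
#' @return A `data.frame` of class `BinTable` with columns `chrom`, `start`,
#'   `end`. `n_bins(bins)` gives the total bin count.
#' @examples
#' bins <- bin_table(rep("chr1", 4), seq(0, 3e6, 1e6), seq(1e6, 4e6, 1e6))
#' n_bins(bins)
#' @export
bin_table <- function(chrom, start, end) {
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start and end must have equal length")
  bins <- data.frame(chrom = as.character(chrom),
                     start = as.numeric(start),
                     end = as.numeric(end),
                     stringsAsFactors = FALSE)
  if (any(bins$end <= bins$start))
    stop("every bin must satisfy start < end")
  # bins must arrive sorted by (chrom, start) with chromosomes contiguous
  chr_rle <- rle(bins$chrom)
  if (anyDuplicated(chr_rle$values))
    stop("bins of one chromosome must be contiguous")
  for (cname in chr_rle$values) {
    s <- bins$start[bins$chrom == cname]
    if (is.unsorted(s, strictly = TRUE))
      stop("bins must be sorted by start within chromosome ", cname)
  }
  class(bins) <- c("BinTable", "data.frame")
  bins
}

#' @rdname bin_table
#' @param bins a `BinTable`.
#' @export
n_bins <- function(bins) nrow(bins)

#' Uniform bin table from chromosome lengths
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp.
#' @return A [bin_table()].
#' @export
bin_table_from_lengths <- function(chrom_lengths, bin_size) {
  stopifnot(length(chrom_lengths) >= 1, bin_size > 0)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  pieces <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    start <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = cn, start = start,
               end = pmin(start + bin_size, len),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  bin_table(all$chrom, all$start, all$end)
}

#' Construct a single-cell contact matrix
#'
#' Sparse triplet storage of one binned Hi-C interaction matrix. Entries are
#' canonicalized to the upper triangle (`bin1 <= bin2`); duplicate mirrored
#' pairs are summed. Bin ids are 0-based.
#'
#' @param cell_id stable cell identifier.
#' @param bin1,bin2 0-based bin ids of each contact.
#' @param count contact count per entry, strictly positive (non-negative
#'   reals are accepted so normalized matrices can be carried).
#' @return A list of class `CellContactMatrix` with fields `cell_id` and
#'   `contacts` (data.frame `bin1`, `bin2`, `count`, sorted, upper triangle).
#' @export
cell_contact_matrix <- function(cell_id, bin1 = numeric(0), bin2 = numeric(0),
                                count = numeric(0)) {
  if (length(bin1) != length(bin2) || length(bin1) != length(count))
    stop("bin1, bin2 and count must have equal length")
  if (any(count <= 0)) stop("contact counts must be > 0 in cell '", cell_id, "'")
  if (any(bin1 < 0) || any(bin2 < 0))
    stop("negative bin id in cell '", cell_id, "'")
  i <- pmin(bin1, bin2)
  j <- pmax(bin1, bin2)
  if (length(i)) {
    key <- paste(i, j)
    if (anyDuplicated(key)) {
      agg <- rowsum(count, key, reorder = FALSE)
      keep <- !duplicated(key)
      i <- i[keep]; j <- j[keep]
      count <- agg[match(key[keep], rownames(agg)), 1]
    }
    o <- order(i, j)
    i <- i[o]; j <- j[o]; count <- count[o]
  }
  structure(list(cell_id = as.character(cell_id),
                 contacts = data.frame(bin1 = i, bin2 = j, count = count)),
            class = "CellContactMatrix")
}

#' Construct a cell population
#'
#' @param bins shared [bin_table()].
#' @param cells list of [cell_contact_matrix()] objects with unique ids.
#' @return A list of class `CellPopulation` with fields `bins`, `cells`.
#' @export
cell_population <- function(bins, cells) {
  stopifnot(inherits(bins, "BinTable"), length(cells) >= 1)
  n <- n_bins(bins)
  ids <- vapply(cells, function(x) x$cell_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate cell ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (cell in cells) {
    ct <- cell$contacts
    if (nrow(ct) && max(ct$bin2) >= n)
      stop("bin index out of range in cell '", cell$cell_id,
           "' (n_bins = ", n, ")")
  }
  names(cells) <- ids
  structure(list(bins = bins, cells = cells), class = "CellPopulation")
}

#' @method print CellPopulation
#' @export
print.CellPopulation <- function(x, ...) {
  cat("CellPopulation:", length(x$cells), "cells,", n_bins(x$bins), "bins (",
      length(unique(x$bins$chrom)), "chromosome(s) )\n")
  invisible(x)
}

#' Number of cells in a population
#' @param pop a `CellPopulation`.
#' @export
n_cells <- function(pop) length(pop$cells)

#' Flatten one contact matrix into a sparse feature row
#'
#' The n x n matrix is symmetrized (the upper triangle mirrored; the diagonal
#' kept once) and unrolled row-major into n^2 features, so the contact between
#' bins i and j occupies features `i*n + j` and `j*n + i` (0-based).
#'
#' @param cell a [cell_contact_matrix()].
#' @param bins the population's [bin_table()].
#' @return list with `ids` (ascending 0-based feature ids) and `values`
#'   (matching contact counts), plus `n_features = n_bins^2`.
#' @examples
#' bins <- bin_table(rep("chr1", 3), c(0, 1, 2) * 1e6, c(1, 2, 3) * 1e6)
#' cell <- cell_contact_matrix("c1", c(0, 0, 1), c(0, 1, 2), c(1, 2, 6))
#' flatten_cell(cell, bins)$ids
#' @export
flatten_cell <- function(cell, bins) {
  n <- n_bins(bins)
  ct <- cell$contacts
  if (nrow(ct) && max(ct$bin2) >= n)
    stop("bin index out of range in cell '", cell$cell_id, "'")
  up <- ct$bin1 * n + ct$bin2
  lo <- ct$bin2 * n + ct$bin1
  off <- ct$bin1 != ct$bin2
  ids <- c(up, lo[off])
  vals <- c(ct$count, ct$count[off])
  o <- order(ids)
  list(ids = ids[o], values = vals[o], n_features = n * n)
}

#' Flatten a dense n x n matrix row-major
#'
#' The elementary flattening step: an n x n grid becomes a 1 x n^2 feature
#' vector with the contact of bins (i, j) at feature `i*n + j` (0-based).
#' [flatten_cell()] applies this to the symmetrized sparse cell matrix;
#' this variant takes any dense square matrix.
#'
#' @param M dense square matrix.
#' @return list: `vector` (the full 1 x n^2 row), `ids` (0-based feature ids
#'   of nonzero entries, ascending), `values`, `n_features`.
#' @examples
#' flatten_dense(matrix(1:9, 3, byrow = TRUE))$vector
#' @export
flatten_dense <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (ncol(M) != n) stop("matrix must be square")
  v <- as.numeric(t(M))
  nz <- which(v != 0)
  list(vector = v, ids = nz - 1, values = v[nz], n_features = n * n)
}

#' Compile a population into one flattened cells-by-features matrix
#'
#' Stacks the flattened rows of all cells into one conceptual m x n^2 sparse
#' matrix, kept as per-cell ascending nonzero feature-id sets (the sets the
#' Jaccard index and MinHash consume) with aligned values.
#'
#' @param pop a [cell_population()].
#' @return A list of class `FlattenedPopulation`: `m`, `n_bins`, `n_features`,
#'   `cell_ids`, `sets` (list of ascending feature-id vectors), `values`
#'   (aligned contact counts), `bins`.
#' @export
compile_population <- function(pop) {
  stopifnot(inherits(pop, "CellPopulation"))
  n <- n_bins(pop$bins)
  rows <- lapply(pop$cells, flatten_cell, bins = pop$bins)
  structure(list(m = length(rows),
                 n_bins = n,
                 n_features = n * n,
                 cell_ids = names(pop$cells),
                 sets = lapply(rows, `[[`, "ids"),
                 values = lapply(rows, `[[`, "values"),
                 bins = pop$bins),
            class = "FlattenedPopulation")
}

#' @method print FlattenedPopulation
#' @export
print.FlattenedPopulation <- function(x, ...) {
  f <- lengths(x$sets)
  cat("FlattenedPopulation:", x$m, "cells x", format(x$n_features, big.mark = ","),
      "features; nonzero per cell:", min(f), "-", max(f), "\n")
  invisible(x)
}

#' Nonzero feature-id set of one cell
#'
#' @param flat a [compile_population()] result.
#' @param cell_index 1-based cell index.
#' @return Ascending 0-based feature ids with positive value.
#' @export
nonzero_feature_set <- function(flat, cell_index) {
  stopifnot(inherits(flat, "FlattenedPopulation"))
  if (cell_index < 1 || cell_index > flat$m)
    stop("cell_index out of range [1, ", flat$m, "]")
  flat$sets[[cell_index]]
}

#' Drop inter-chromosomal features from a flattened population
#'
#' Removes every feature whose two bins lie on different chromosomes from all
#' rows and nonzero sets. Feature-id numbering is unchanged, so the operation
#' is idempotent.
#'
#' @param flat a `FlattenedPopulation`.
#' @return A `FlattenedPopulation` restricted to intra-chromosomal contacts.
#' @export
restrict_intra_chromosomal <- function(flat) {
  stopifnot(inherits(flat, "FlattenedPopulation"))
  n <- flat$n_bins
  chroms <- flat$bins$chrom
  for (c in seq_len(flat$m)) {
    ids <- flat$sets[[c]]
    if (!length(ids)) next
    i <- ids %/% n
    j <- ids %% n
    keep <- chroms[i + 1] == chroms[j + 1]
    flat$sets[[c]] <- ids[keep]
    flat$values[[c]] <- flat$values[[c]][keep]
  }
  flat
}

#' Per-cell density of the symmetrized contact matrix
#'
#' Nonzero entries of the symmetrized n x n matrix divided by n^2 — the
#' sparsity regime that governs how many MinHash collisions a population can
#' produce.
#'
#' @param pop a `CellPopulation`.
#' @return Named numeric vector, one nonzero fraction per cell.
#' @export
measure_density <- function(pop) {
  stopifnot(inherits(pop, "CellPopulation"))
  n <- n_bins(pop$bins)
  vapply(pop$cells, function(cell) {
    ct <- cell$contacts
    diag_n <- sum(ct$bin1 == ct$bin2)
    (2 * (nrow(ct) - diag_n) + diag_n) / (n * n)
  }, numeric(1))
}
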