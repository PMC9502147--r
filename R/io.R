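#' Read a single-cell Hi-C population
#'
#' Two layouts are supported: `scool` — one HDF5 container holding a shared
#' bin table under `/bins` (`chrom`, `start`, `end`) and one pixel table per
#' cell under `/cells/<name>/pixels` (`bin1_id`, `bin2_id`, `count`) — and
#' `mtx_dir` — a directory with `bins.tsv` (chrom, start, end; BED-style
#' 0-based half-open coordinates) plus one Matrix Market file per cell.
#' Matrix Market coordinates are 1-based on disk and converted to 0-based bin
#' ids internally. Cells are read in lexicographic name order.
#'
#' @param path scool file or mtx directory.
#' @param format `"scool"` or `"mtx_dir"`.
#' @return A [cell_population()].
#' @export
read_population <- function(path, format = c("scool", "mtx_dir")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input path '", path, "' does not exist")
  if (format == "scool") read_scool(path) else read_mtx_dir(path)
}

#' Write a single-cell Hi-C population
#'
#' Inverse of [read_population()]; writing then reading reproduces the bin
#' table and every sparse entry exactly.
#'
#' @param pop a [cell_population()].
#' @param path output scool file or mtx directory.
#' @param format `"scool"` or `"mtx_dir"`.
#' @export
write_population <- function(pop, path, format = c("scool", "mtx_dir")) {
  stopifnot(inherits(pop, "CellPopulation"))
  format <- match.arg(format)
  if (format == "scool") write_scool(pop, path) else write_mtx_dir(pop, path)
  invisible(path)
}

read_scool <- function(path) {
  ls <- rhdf5::h5ls(path)
  if (!any(ls$group == "/bins" | (ls$group == "/" & ls$name == "bins")))
    stop("scool file '", path, "' is missing the /bins table")
  bins <- bin_table(as.character(rhdf5::h5read(path, "bins/chrom")),
                    as.numeric(rhdf5::h5read(path, "bins/start")),
                    as.numeric(rhdf5::h5read(path, "bins/end")))
  cell_names <- sort(ls$name[ls$group == "/cells" & ls$otype == "H5I_GROUP"])
  if (!length(cell_names)) stop("scool file '", path, "' holds no cells")
  cells <- lapply(cell_names, function(cn) {
    px <- paste0("cells/", cn, "/pixels")
    cell_contact_matrix(cn,
                        as.numeric(rhdf5::h5read(path, paste0(px, "/bin1_id"))),
                        as.numeric(rhdf5::h5read(path, paste0(px, "/bin2_id"))),
                        as.numeric(rhdf5::h5read(path, paste0(px, "/count"))))
  })
  cell_population(bins, cells)
}

write_scool <- function(pop, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "bins")
  rhdf5::h5write(pop$bins$chrom, path, "bins/chrom")
  rhdf5::h5write(pop$bins$start, path, "bins/start")
  rhdf5::h5write(pop$bins$end, path, "bins/end")
  rhdf5::h5createGroup(path, "cells")
  for (cell in pop$cells) {
    grp <- paste0("cells/", cell$cell_id)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5createGroup(path, paste0(grp, "/pixels"))
    rhdf5::h5write(cell$contacts$bin1, path, paste0(grp, "/pixels/bin1_id"))
    rhdf5::h5write(cell$contacts$bin2, path, paste0(grp, "/pixels/bin2_id"))
    rhdf5::h5write(cell$contacts$count, path, paste0(grp, "/pixels/count"))
  }
  rhdf5::h5closeAll()
}

read_mtx_dir <- function(path) {
  bins_path <- file.path(path, "bins.tsv")
  if (!file.exists(bins_path))
    stop("mtx directory '", path, "' is missing bins.tsv")
  bt <- utils::read.table(bins_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(bt)))
    stop("bins.tsv must have columns chrom, start, end")
  bins <- bin_table(bt$chrom, bt$start, bt$end)
  files <- sort(list.files(path, pattern = "\\.mtx$", full.names = TRUE))
  if (!length(files)) stop("mtx directory '", path, "' holds no .mtx files")
  ids <- sub("\\.mtx$", "", basename(files))
  if (anyDuplicated(ids)) stop("duplicate cell names in '", path, "'")
  cells <- lapply(seq_along(files), function(t) {
    M <- tryCatch(Matrix::readMM(files[t]),
                  error = function(e) stop("malformed Matrix Market file '",
                                           files[t], "': ", conditionMessage(e)))
    trip <- Matrix::summary(methods::as(M, "TsparseMatrix"))
    if (any(trip$x <= 0))
      stop("non-positive count at record ", which(trip$x <= 0)[1],
           " of '", files[t], "'")
    # 1-based Matrix Market coordinates -> 0-based bin ids
    cell_contact_matrix(ids[t], trip$i - 1, trip$j - 1, trip$x)
  })
  cell_population(bins, cells)
}

write_mtx_dir <- function(pop, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(pop$bins), file.path(path, "bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  n <- n_bins(pop$bins)
  for (cell in pop$cells) {
    ct <- cell$contacts
    M <- Matrix::sparseMatrix(i = ct$bin1 + 1, j = ct$bin2 + 1, x = ct$count,
                              dims = c(n, n))
    Matrix::writeMM(M, file.path(path, paste0(cell$cell_id, ".mtx")))
  }
}

#' Write / read a cluster assignment file
#'
#' Plain text, one `cell_id<TAB>cluster_id` row per cell, no header.
#'
#' @param labels cluster id per cell.
#' @param cell_ids cell identifier per cell.
#' @param path output path.
#' @export
write_cluster_file <- function(labels, cell_ids, path) {
  if (length(labels) != length(cell_ids))
    stop("labels and cell_ids must align")
  utils::write.table(data.frame(cell_ids, labels), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_file
#' @return `read_cluster_file` returns a data.frame with columns `cell_id`,
#'   `cluster_id`.
#' @export
read_cluster_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("cell_id", "cluster_id"))
  df
}
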