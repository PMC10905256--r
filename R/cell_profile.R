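#' Construct a single-cell spatial expression profile
#'
#' A cell profile holds the sparse cell-by-gene count matrix produced by
#' binning molecules into segmented cells, plus per-cell metadata.
#'
#' @param matrix A cell-by-gene matrix (coerced to `dgCMatrix`); row
#'   names are cell labels, column names gene ids.
#' @param cell_meta Data frame with one row per cell: `label`,
#'   `area_px`, `centroid_y`, `centroid_x` (`n_genes` and
#'   `total_counts` are recomputed from the matrix).
#' @return Object of class `cell_profile`: list with elements `matrix`,
#'   `cell_meta`, `gene_ids`.
#' @export
cell_profile <- function(matrix, cell_meta = NULL) {
  m <- methods::as(methods::as(methods::as(Matrix::Matrix(matrix, sparse = TRUE),
                                           "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(m@x < 0)) stop("profile counts must be nonnegative")
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- if (ncol(m)) paste0("g", seq_len(ncol(m))) else character(0)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(label = as.integer(rownames(m)),
                            area_px = rep(NA_integer_, nrow(m)),
                            centroid_y = rep(NA_real_, nrow(m)),
                            centroid_x = rep(NA_real_, nrow(m)))
  }
  cell_meta <- cell_meta[match(as.integer(rownames(m)), cell_meta$label), , drop = FALSE]
  cell_meta$n_genes <- Matrix::rowSums(m > 0)
  cell_meta$total_counts <- Matrix::rowSums(m)
  rownames(cell_meta) <- NULL
  structure(list(matrix = m, cell_meta = cell_meta, gene_ids = colnames(m)),
            class = "cell_profile")
}

#' @export
print.cell_profile <- function(x, ...) {
  cat(sprintf("cell_profile: %d cells x %d genes, %d nonzeros, %d total counts\n",
              nrow(x$matrix), ncol(x$matrix), length(x$matrix@x),
              as.integer(sum(x$matrix))))
  invisible(x)
}

#' @export
summary.cell_profile <- function(object, ...) {
  cm <- object$cell_meta
  cat(sprintf("cells: %d  genes: %d\n", nrow(object$matrix), ncol(object$matrix)))
  if (nrow(cm)) {
    cat(sprintf("median genes per cell: %.0f  median counts per cell: %.0f\n",
                median(cm$n_genes), median(cm$total_counts)))
    if (!all(is.na(cm$area_px)))
      cat(sprintf("median cell area: %.0f px\n", median(cm$area_px)))
  }
  invisible(object)
}

#' Write a cell profile to a directory
#'
#' Writes `matrix.mtx` (MatrixMarket triplet, 1-based, cells as rows),
#' `genes.tsv` and `cells.tsv` (index files), `cell_meta.tsv`
#' (label, area_px, centroid_y, centroid_x, n_genes, total_counts) and,
#' when a labelled molecule table is given, `labeled.gem.tsv` — the
#' input GEM with an appended integer `label` column (0 = unassigned).
#'
#' @param profile A [cell_profile()].
#' @param path Output directory (created if missing).
#' @param molecules,labels Optional [molecule_table()] and matching
#'   per-record label vector for the labelled GEM.
#' @return Invisibly, `path`.
#' @export
write_cell_profile <- function(profile, path, molecules = NULL, labels = NULL) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  Matrix::writeMM(profile$matrix, file.path(path, "matrix.mtx"))
  writeLines(as.character(profile$gene_ids), file.path(path, "genes.tsv"))
  writeLines(as.character(rownames(profile$matrix)), file.path(path, "cells.tsv"))
  utils::write.table(profile$cell_meta, file.path(path, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(molecules)) write_gem(molecules, file.path(path, "labeled.gem.tsv"), labels)
  invisible(path)
}

#' Read a cell profile written by [write_cell_profile()]
#'
#' @param path Directory containing `matrix.mtx`, `genes.tsv`,
#'   `cells.tsv`, `cell_meta.tsv`.
#' @return A [cell_profile()].
#' @export
read_cell_profile <- function(path) {
  m <- Matrix::readMM(file.path(path, "matrix.mtx"))
  rownames(m) <- readLines(file.path(path, "cells.tsv"))
  colnames(m) <- readLines(file.path(path, "genes.tsv"))
  meta <- utils::read.table(file.path(path, "cell_meta.tsv"),
                            sep = "\t", header = TRUE)
  cell_profile(m, meta)
}
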