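# Reading and writing count matrices and fitted objects.
#
# Counts travel as MatrixMarket sparse triplets plus row (cell barcode) and
# column (gene feature) label files, following the 10x convention but with
# cells as rows, or as a dense TSV.  Fitted objects and simulation bundles
# are serialized as RDS.

#' Write a count matrix as MatrixMarket + label TSVs
#'
#' @param X Cells x genes count matrix (dense or sparse).
#' @param dir Output directory (created if missing).
#' @param cell_names,gene_names Optional label vectors; defaults are
#'   positional labels.
#' @return The directory, invisibly.
#' @export
write_counts_mtx <- function(X, dir, cell_names = NULL, gene_names = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Xs <- methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(Xs, file.path(dir, "counts.mtx"))
  if (is.null(cell_names)) cell_names <- rownames(X)
  if (is.null(cell_names)) cell_names <- paste0("cell", seq_len(nrow(X)))
  if (is.null(gene_names)) gene_names <- colnames(X)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(X)))
  writeLines(cell_names, file.path(dir, "barcodes.tsv"))
  writeLines(gene_names, file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir Directory containing `counts.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @return A dense cells x genes matrix with dimnames.
#' @export
read_counts_mtx <- function(dir) {
  X <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  rownames(X) <- readLines(file.path(dir, "barcodes.tsv"))
  colnames(X) <- readLines(file.path(dir, "features.tsv"))
  X
}

#' Read a dense counts TSV (cells in rows, genes in columns, with headers)
#'
#' @param path Path to the TSV; first column holds cell identifiers.
#' @return A dense matrix with dimnames.
#' @export
read_counts_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                    check.names = FALSE)
  as.matrix(tab)
}

#' Serialize a fitted pipeline (or simulation bundle) to RDS + TSV exports
#'
#' Writes `fit.rds` plus per-matrix TSVs (`L.tsv`, `F.tsv`, `lfc_*.tsv`)
#' for interoperability.
#'
#' @param fit A `gbcd_fit` object.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_gbcd_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(fit, file.path(dir, "fit.rds"))
  wt <- function(M, f) write.table(as.data.frame(M), file.path(dir, f),
                                   sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(fit$cov_fit$L, "L.tsv")
  wt(fit$sig_fit$F, "F.tsv")
  wt(fit$lfc$post_mean, "lfc_post_mean.tsv")
  wt(fit$lfc$lfsr, "lfc_lfsr.tsv")
  invisible(dir)
}
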