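#' Construct a spatial transcriptomics dataset
#'
#' The canonical container for a spot/cell-by-gene UMI count matrix with 2-D
#' spatial coordinates. Rows of `counts` and `coords` align one-to-one.
#'
#' @param counts Non-negative integer matrix, spots in rows, genes in columns.
#' @param coords Numeric matrix with one row per spot and two columns (x, y),
#'   in platform units.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   column names of `counts`).
#' @param spot_ids Character vector of unique spot identifiers (defaults to
#'   row names of `counts`).
#'
#' @return An object of class `st_dataset`: a list with elements `counts`
#'   (base matrix), `coords`, `gene_ids`, `spot_ids`.
#' @export
st_dataset <- function(counts, coords, gene_ids = colnames(counts),
                       spot_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  coords <- as.matrix(coords)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(counts)))
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(nrow(counts)))
  if (any(counts < 0)) stop("invalid-counts: negative entries in count matrix",
                            call. = FALSE)
  if (nrow(coords) != nrow(counts))
    stop("alignment-error: coords rows (", nrow(coords),
         ") do not match counts rows (", nrow(counts), ")", call. = FALSE)
  if (ncol(coords) != 2)
    stop("alignment-error: coords must have exactly 2 columns", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique", call. = FALSE)
  if (anyDuplicated(spot_ids)) stop("spot_ids must be unique", call. = FALSE)
  if (length(gene_ids) != ncol(counts) || length(spot_ids) != nrow(counts))
    stop("alignment-error: identifier lengths do not match matrix dimensions",
         call. = FALSE)
  dimnames(counts) <- list(spot_ids, gene_ids)
  rownames(coords) <- spot_ids
  colnames(coords) <- c("x", "y")
  structure(list(counts = counts, coords = coords,
                 gene_ids = gene_ids, spot_ids = spot_ids),
            class = "st_dataset")
}

#' @export
print.st_dataset <- function(x, ...) {
  cat("st_dataset:", nrow(x$counts), "spots x", ncol(x$counts), "genes\n")
  cat("  total counts:", sum(x$counts),
      " sparsity:", round(mean(x$counts == 0), 3), "\n")
  invisible(x)
}

#' @export
dim.st_dataset <- function(x) dim(x$counts)

#' Load a spatial dataset from disk
#'
#' Readers for the three supported on-disk layouts:
#' \describe{
#'   \item{`mtx_dir`}{a 10x-style directory with `matrix.mtx` (genes x spots),
#'     `features.tsv`, `barcodes.tsv` and a `tissue_positions.csv` table whose
#'     first column is the barcode and whose last two columns are coordinates.}
#'   \item{`delimited`}{`counts.tsv` (spots x genes, row and column names) and
#'     `coords.tsv` (`spot_id`, `x`, `y`).}
#'   \item{`h5ad`}{an AnnData container; converted through the `anndata`
#'     Python package (`X` counts, `obsm['spatial']` coordinates).}
#' }
#'
#' @param path Directory (`mtx_dir`, `delimited`) or file (`h5ad`).
#' @param format One of `"mtx_dir"`, `"h5ad"`, `"delimited"`.
#' @return An [st_dataset()].
#' @export
load_dataset <- function(path, format = c("mtx_dir", "h5ad", "delimited")) {
  format <- match.arg(format)
  switch(format,
         mtx_dir   = load_mtx_dir(path),
         delimited = load_delimited(path),
         h5ad      = load_h5ad(path))
}

load_mtx_dir <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx)) stop("matrix.mtx not found in ", path, call. = FALSE)
  m <- as.matrix(Matrix::readMM(mtx))           # genes x spots (10x layout)
  feats <- utils::read.delim(file.path(path, "features.tsv"),
                             header = FALSE, stringsAsFactors = FALSE)
  bars <- utils::read.delim(file.path(path, "barcodes.tsv"),
                            header = FALSE, stringsAsFactors = FALSE)
  pos_file <- file.path(path, "tissue_positions.csv")
  if (!file.exists(pos_file))
    stop("coords-missing: no tissue_positions.csv in ", path, call. = FALSE)
  pos <- utils::read.csv(pos_file, stringsAsFactors = FALSE)
  if (nrow(pos) != ncol(m))
    stop("alignment-error: positions table has ", nrow(pos),
         " rows but matrix has ", ncol(m), " spots", call. = FALSE)
  idx <- match(bars[[1]], pos[[1]])
  if (anyNA(idx))
    stop("alignment-error: barcodes missing from positions table", call. = FALSE)
  nc <- ncol(pos)
  coords <- as.matrix(pos[idx, c(nc - 1L, nc)])
  st_dataset(t(m), coords, gene_ids = feats[[1]], spot_ids = bars[[1]])
}

load_delimited <- function(path) {
  cf <- file.path(path, "counts.tsv")
  xf <- file.path(path, "coords.tsv")
  if (!file.exists(cf)) stop("counts.tsv not found in ", path, call. = FALSE)
  if (!file.exists(xf)) stop("coords-missing: no coords.tsv in ", path,
                             call. = FALSE)
  counts <- as.matrix(utils::read.delim(cf, row.names = 1, check.names = FALSE))
  pos <- utils::read.delim(xf, stringsAsFactors = FALSE)
  if (nrow(pos) != nrow(counts))
    stop("alignment-error: coords.tsv has ", nrow(pos),
         " rows but counts.tsv has ", nrow(counts), " spots", call. = FALSE)
  idx <- match(rownames(counts), pos[[1]])
  if (anyNA(idx))
    stop("alignment-error: spot ids missing from coords.tsv", call. = FALSE)
  st_dataset(counts, as.matrix(pos[idx, 2:3]),
             gene_ids = colnames(counts), spot_ids = rownames(counts))
}

#' Write a spatial dataset to disk
#'
#' Inverse of [load_dataset()]; writes the layout matching `format` so that a
#' round trip reproduces the counts, coordinates and identifiers.
#'
#' @inheritParams load_dataset
#' @param ds An [st_dataset()].
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("mtx_dir", "h5ad", "delimited")) {
  format <- match.arg(format)
  switch(format,
         mtx_dir = {
           dir.create(path, showWarnings = FALSE, recursive = TRUE)
           Matrix::writeMM(methods::as(Matrix::Matrix(t(ds$counts), sparse = TRUE),
                                       "generalMatrix"),
                           file.path(path, "matrix.mtx"))
           utils::write.table(data.frame(ds$gene_ids, ds$gene_ids, "Gene Expression"),
                              file.path(path, "features.tsv"), sep = "\t",
                              quote = FALSE, row.names = FALSE, col.names = FALSE)
           utils::write.table(data.frame(ds$spot_ids),
                              file.path(path, "barcodes.tsv"), sep = "\t",
                              quote = FALSE, row.names = FALSE, col.names = FALSE)
           utils::write.csv(data.frame(barcode = ds$spot_ids,
                                       x = ds$coords[, 1], y = ds$coords[, 2]),
                            file.path(path, "tissue_positions.csv"),
                            row.names = FALSE, quote = FALSE)
         },
         delimited = {
           dir.create(path, showWarnings = FALSE, recursive = TRUE)
           utils::write.table(ds$counts, file.path(path, "counts.tsv"),
                              sep = "\t", quote = FALSE, col.names = NA)
           utils::write.table(data.frame(spot_id = ds$spot_ids,
                                         x = ds$coords[, 1], y = ds$coords[, 2]),
                              file.path(path, "coords.tsv"), sep = "\t",
                              quote = FALSE, row.names = FALSE)
         },
         h5ad = write_h5ad(ds, path))
  invisible(path)
}
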