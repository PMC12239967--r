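#' Gene x cell count matrices
#'
#' Counts are stored as a sparse `Matrix::dgCMatrix` with gene rownames
#' and cell colnames, plus a `negctrl_genes` attribute flagging
#' negative-control probes (panel probes targeting no transcript, whose
#' mean count estimates nonspecific background).
#'
#' @param counts genes x cells matrix (dense or sparse), non-negative
#'   integers.
#' @param genes,cells optional dimension names (defaults: existing
#'   dimnames).
#' @param negctrl_genes character vector, subset of `genes`.
#' @return a `count_matrix` (sparse matrix subclass by attribute).
#' @export
count_matrix <- function(counts, genes = rownames(counts),
                         cells = colnames(counts),
                         negctrl_genes = character(0)) {
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (any(m@x < 0)) stop("counts must be non-negative")
  if (any(m@x != round(m@x))) stop("counts must be integers")
  if (is.null(genes) || is.null(cells))
    stop("gene and cell identifiers are required")
  dimnames(m) <- list(as.character(genes), as.character(cells))
  if (!all(negctrl_genes %in% rownames(m)))
    stop("negctrl_genes must be a subset of genes")
  attr(m, "negctrl_genes") <- as.character(negctrl_genes)
  m
}

#' Negative-control probe ids of a count matrix
#' @param counts a [count_matrix()].
#' @export
negctrl_genes <- function(counts) attr(counts, "negctrl_genes") %||% character(0)

#' Read a count matrix from MatrixMarket MTX plus side files
#'
#' `<stem>.mtx` holds the sparse genes x cells counts; `<stem>.genes.txt`
#' and `<stem>.cells.txt` hold one id per line; `<stem>.negctrl.txt`
#' (optional) lists negative-control probe ids.
#'
#' @param stem path stem (no extension).
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(stem) {
  m <- Matrix::readMM(paste0(stem, ".mtx"))
  genes <- readLines(paste0(stem, ".genes.txt"))
  cells <- readLines(paste0(stem, ".cells.txt"))
  ncf <- paste0(stem, ".negctrl.txt")
  neg <- if (file.exists(ncf)) readLines(ncf) else character(0)
  count_matrix(m, genes = genes, cells = cells, negctrl_genes = neg)
}

#' Write a count matrix as MTX plus side files
#' @param counts a [count_matrix()].
#' @param stem path stem (no extension).
#' @export
write_count_matrix <- function(counts, stem) {
  Matrix::writeMM(methods::as(counts, "TsparseMatrix"), paste0(stem, ".mtx"))
  writeLines(rownames(counts), paste0(stem, ".genes.txt"))
  writeLines(colnames(counts), paste0(stem, ".cells.txt"))
  writeLines(negctrl_genes(counts), paste0(stem, ".negctrl.txt"))
  invisible(stem)
}
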