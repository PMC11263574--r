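#' Construct a cell-by-gene count matrix with metadata
#'
#' The central container of the pipeline: a sparse cell x gene matrix of
#' raw UMI counts together with per-cell metadata (sample of origin and
#' striatal region, caudate nucleus `"CN"` or putamen `"Pu"`).
#'
#' @param counts A cell x gene matrix of non-negative integer counts
#'   (dense or any [Matrix::Matrix] type); coerced to `dgCMatrix`.
#' @param cell_ids Character vector of unique cell identifiers (rows).
#' @param gene_names Character vector of gene names (columns).
#' @param cell_meta A `data.frame` with one row per cell holding at least
#'   `sample_id` and `region`.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `cell_ids`, `gene_names`, `cell_meta`.
#' @export
count_matrix <- function(counts, cell_ids, gene_names, cell_meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (length(cell_ids) != nrow(counts))
    stop("cell_ids length does not match number of rows of counts")
  if (length(gene_names) != ncol(counts))
    stop("gene_names length does not match number of columns of counts")
  if (!is.data.frame(cell_meta) || nrow(cell_meta) != nrow(counts))
    stop("cell_meta must be a data.frame with one row per cell")
  if (!all(c("sample_id", "region") %in% names(cell_meta)))
    stop("cell_meta must contain sample_id and region columns")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  dimnames(counts) <- list(cell_ids, gene_names)
  cell_meta <- as.data.frame(cell_meta)
  rownames(cell_meta) <- cell_ids
  structure(list(counts = counts, cell_ids = cell_ids,
                 gene_names = gene_names, cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes, %d sample(s), regions: %s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample_id)),
              paste(sort(unique(x$cell_meta$region)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Per-cell QC metrics
#'
#' Computes the three per-cell metrics the QC cascade filters on: total
#' UMI count, number of detected genes, and the fraction of counts on
#' mitochondrially encoded genes (names starting `MT-`).
#'
#' @param cm A [count_matrix()].
#' @return A `data.frame` with columns `cell_id`, `n_umis`, `n_genes`,
#'   `mito_fraction`.
#' @export
cell_metrics <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  n_umis <- Matrix::rowSums(cm$counts)
  n_genes <- Matrix::rowSums(cm$counts > 0)
  mito <- startsWith(cm$gene_names, "MT-")
  mito_counts <- if (any(mito)) Matrix::rowSums(cm$counts[, mito, drop = FALSE]) else 0
  data.frame(cell_id = cm$cell_ids, n_umis = as.numeric(n_umis),
             n_genes = as.integer(n_genes),
             mito_fraction = ifelse(n_umis > 0, mito_counts / n_umis, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Subset a count matrix by cells
#'
#' @param cm A [count_matrix()].
#' @param cell_ids Character vector of cell ids to keep (order preserved).
#' @return A [count_matrix()] restricted to those cells.
#' @export
subset_cells <- function(cm, cell_ids) {
  stopifnot(inherits(cm, "count_matrix"))
  idx <- match(cell_ids, cm$cell_ids)
  if (anyNA(idx)) stop("unknown cell ids: ",
                       paste(utils::head(cell_ids[is.na(idx)], 5), collapse = ", "))
  count_matrix(cm$counts[idx, , drop = FALSE], cm$cell_ids[idx],
               cm$gene_names, cm$cell_meta[idx, , drop = FALSE])
}

#' Write / read a count matrix as MTX plus TSV sidecars
#'
#' `write_count_matrix()` writes `matrix.mtx` (cells as rows),
#' `cells.tsv` (cell_id, sample_id, region) and `genes.tsv`;
#' `read_count_matrix()` reads them back.
#'
#' @param cm A [count_matrix()].
#' @param dir Directory to write to / read from (created if missing).
#' @return `write_count_matrix()` returns `dir` invisibly;
#'   `read_count_matrix()` returns a [count_matrix()].
#' @export
write_count_matrix <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tm <- methods::as(cm$counts, "TsparseMatrix")
  path <- file.path(dir, "matrix.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(tm), ncol(tm), length(tm@x))), path)
  data.table::fwrite(data.table::data.table(i = tm@i + 1L, j = tm@j + 1L,
                                            x = as.integer(tm@x)),
                     path, sep = " ", col.names = FALSE, append = TRUE)
  utils::write.table(
    data.frame(cell_id = cm$cell_ids,
               sample_id = cm$cell_meta$sample_id,
               region = cm$cell_meta$region),
    file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = cm$gene_names),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  count_matrix(m, cells$cell_id, genes$gene,
               cells[, c("sample_id", "region"), drop = FALSE])
}

#' Flag gene categories excluded from feature selection
#'
#' Flags mitochondrial (`MT-` prefix), ribosomal-protein (`RPL`/`RPS`
#' prefixes) and sex-linked genes by name, the three categories removed
#' before highly-variable-gene selection and factor analysis.
#'
#' @param gene_names Character vector of gene names.
#' @return Logical matrix with columns `mito`, `ribo`, `sex`.
#' @export
gene_category_flags <- function(gene_names) {
  sex_genes <- c("XIST", "TSIX", "UTY", "USP9Y", "DDX3Y", "RPS4Y1",
                 "NLGN4Y", "KDM5D", "EIF1AY", "ZFY", "TTTY14")
  cbind(mito = startsWith(gene_names, "MT-"),
        ribo = startsWith(gene_names, "RPL") | startsWith(gene_names, "RPS"),
        sex = gene_names %in% sex_genes)
}
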