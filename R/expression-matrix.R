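#' Single-cell expression matrix container
#'
#' Wraps a sparse genes x cells count matrix together with per-gene QC
#' flags (mitochondrial / ERCC spike-in), per-cell metadata (sample, grade,
#' assigned cell type), and the derived layers the pipeline fills in:
#' the log-normalized matrix, the highly-variable-gene list and the PCA
#' cell embedding.
#'
#' @param counts genes x cells matrix of non-negative integer counts
#'   (coerced to `dgCMatrix`); must carry row and column names.
#' @param cell_meta data.frame with one row per cell: columns `cell_id`,
#'   `sample_id`, `grade` (one of "III", "IV", "other") and optionally
#'   `assigned_type`. Defaults to a single-sample skeleton.
#' @param mito_regex,ercc_regex gene-name patterns flagging mitochondrial
#'   and spike-in genes.
#' @return An object of class `expr_matrix` with elements `counts`,
#'   `gene_ids`, `cell_ids`, `gene_flags`, `cell_meta`, `normalized`,
#'   `hvg`, `pcs`, `log`.
#' @export
expr_matrix <- function(counts, cell_meta = NULL,
                        mito_regex = "^MT-", ercc_regex = "^ERCC-") {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have gene (row) and cell (column) names")
  if (anyDuplicated(rownames(counts))) stopf("gene ids must be unique")
  if (anyDuplicated(colnames(counts))) stopf("cell ids must be unique")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != floor(v))))
    stopf("counts must be non-negative integers")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = colnames(counts), sample_id = "S1",
                            grade = "other", stringsAsFactors = FALSE)
  }
  cell_meta <- as.data.frame(cell_meta)
  if (!all(c("cell_id", "sample_id", "grade") %in% names(cell_meta)))
    stopf("cell_meta needs columns cell_id, sample_id, grade")
  if (!identical(as.character(cell_meta$cell_id), colnames(counts)))
    stopf("cell_meta$cell_id must match counts column names in order")
  if (is.null(cell_meta$assigned_type)) cell_meta$assigned_type <- NA_character_
  gene_flags <- data.frame(
    gene_id = rownames(counts),
    is_mito = grepl(mito_regex, rownames(counts)),
    is_ercc = grepl(ercc_regex, rownames(counts)),
    stringsAsFactors = FALSE)
  structure(list(counts = counts, gene_ids = rownames(counts),
                 cell_ids = colnames(counts), gene_flags = gene_flags,
                 cell_meta = cell_meta, normalized = NULL, hvg = NULL,
                 pcs = NULL, log = character()),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  mito genes: %d, ERCC genes: %d\n",
              sum(x$gene_flags$is_mito), sum(x$gene_flags$is_ercc)))
  cat(sprintf("  grades: %s\n",
              paste(sprintf("%s=%d", names(table(x$cell_meta$grade)),
                            table(x$cell_meta$grade)), collapse = ", ")))
  cat(sprintf("  layers: normalized=%s, hvg=%s, pcs=%s\n",
              !is.null(x$normalized),
              if (is.null(x$hvg)) "no" else length(x$hvg),
              if (is.null(x$pcs)) "no" else ncol(x$pcs)))
  if (length(x$log)) cat("  log:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}

#' Subset an expression matrix by genes and/or cells
#'
#' Keeps the original ordering of the survivors; derived layers are
#' subset consistently (the PCA embedding is dropped when genes change,
#' since it is no longer the PCA of the stored matrix).
#'
#' @param x an [expr_matrix].
#' @param genes,cells character vectors (or logical/integer indices) of
#'   genes / cells to keep; `NULL` keeps all.
#' @return A new [expr_matrix].
#' @export
subset_expr <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else {
    if (is.character(genes)) which(x$gene_ids %in% genes) else which(
      seq_len(nrow(x$counts)) %in% seq_len(nrow(x$counts))[genes])
  }
  ci <- if (is.null(cells)) seq_len(ncol(x$counts)) else {
    if (is.character(cells)) which(x$cell_ids %in% cells) else which(
      seq_len(ncol(x$counts)) %in% seq_len(ncol(x$counts))[cells])
  }
  out <- x
  out$counts <- x$counts[gi, ci, drop = FALSE]
  out$gene_ids <- x$gene_ids[gi]
  out$cell_ids <- x$cell_ids[ci]
  out$gene_flags <- x$gene_flags[gi, , drop = FALSE]
  out$cell_meta <- x$cell_meta[ci, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  if (!is.null(x$normalized)) out$normalized <- x$normalized[gi, ci, drop = FALSE]
  if (!is.null(x$hvg)) out$hvg <- intersect(x$hvg, out$gene_ids)
  if (!is.null(x$pcs)) {
    out$pcs <- if (length(gi) == nrow(x$counts))
      x$pcs[ci, , drop = FALSE] else NULL
  }
  out
}

#' Write / read an expression matrix in Matrix Market form
#'
#' Writes `matrix.mtx` (sparse triplet counts), `genes.tsv`,
#' `barcodes.tsv` and `cell_meta.tsv` under `dir`; `read_expr_mtx`
#' restores the object (raw counts and metadata; derived layers are not
#' persisted).
#'
#' @param x an [expr_matrix].
#' @param dir output directory.
#' @return `write_expr_mtx` returns `dir` invisibly; `read_expr_mtx`
#'   returns an [expr_matrix].
#' @export
write_expr_mtx <- function(x, dir) {
  stopifnot(inherits(x, "expr_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  write.table(x$cell_meta, file.path(dir, "cell_meta.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_expr_mtx
#' @export
read_expr_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  meta_file <- file.path(dir, "cell_meta.tsv")
  meta <- if (file.exists(meta_file))
    read.delim(meta_file, stringsAsFactors = FALSE) else NULL
  expr_matrix(m, cell_meta = meta)
}
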