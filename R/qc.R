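#' Quality-control thresholds
#'
#' Bundles the cell/gene filtering and downstream processing defaults:
#' genes detected in fewer than 3 cells and cells detecting fewer than 50
#' genes are dropped, as are cells whose mitochondrial + spike-in count
#' fraction exceeds 25 percent; normalization uses a scale factor of
#' 10,000, and downstream steps keep 2,000 highly variable genes and 20
#' principal components.
#'
#' @param min_cells_per_gene,min_genes_per_cell,max_mito_ercc_fraction,scale_factor,n_hvg,n_pcs
#'   see description.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_cells_per_gene = 3, min_genes_per_cell = 50,
                          max_mito_ercc_fraction = 0.25,
                          scale_factor = 10000, n_hvg = 2000, n_pcs = 20) {
  stopifnot(min_cells_per_gene > 0, min_genes_per_cell > 0,
            max_mito_ercc_fraction > 0, max_mito_ercc_fraction <= 1,
            scale_factor > 0, n_hvg > 0, n_pcs > 0)
  structure(list(min_cells_per_gene = min_cells_per_gene,
                 min_genes_per_cell = min_genes_per_cell,
                 max_mito_ercc_fraction = max_mito_ercc_fraction,
                 scale_factor = scale_factor, n_hvg = n_hvg, n_pcs = n_pcs),
            class = "qc_thresholds")
}

#' Per-cell QC metrics
#'
#' @param expr an [expr_matrix].
#' @return data.frame with per-cell total counts, detected genes and
#'   mitochondrial/ERCC count fraction (the quantities usually inspected
#'   before filtering).
#' @export
qc_metrics <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  tot <- Matrix::colSums(expr$counts)
  det <- Matrix::colSums(expr$counts > 0)
  flagged <- expr$gene_flags$is_mito | expr$gene_flags$is_ercc
  mito <- Matrix::colSums(expr$counts[flagged, , drop = FALSE])
  data.frame(cell_id = expr$cell_ids, total_counts = tot,
             detected_genes = det,
             mito_ercc_fraction = ifelse(tot > 0, mito / tot, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply cell and gene quality filters
#'
#' Filtering order is fixed and recorded in the object log: (1) cells with
#' mito+ERCC count fraction above `max_mito_ercc_fraction`, (2) cells
#' detecting fewer than `min_genes_per_cell` genes, (3) genes detected
#' ("detected" = count > 0) in fewer than `min_cells_per_gene` of the
#' surviving cells. Survivors keep their original order; the input object
#' is untouched.
#'
#' @param expr an [expr_matrix] with raw counts.
#' @param thresholds a [qc_thresholds].
#' @return A filtered [expr_matrix].
#' @export
apply_qc <- function(expr, thresholds = qc_thresholds()) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(thresholds, "qc_thresholds"))
  m <- qc_metrics(expr)
  keep_mito <- m$mito_ercc_fraction <= thresholds$max_mito_ercc_fraction
  keep_genes_per_cell <- m$detected_genes >= thresholds$min_genes_per_cell
  keep_cell <- keep_mito & keep_genes_per_cell
  if (!any(keep_cell)) stopf("all cells removed by QC filtering")
  sub <- expr$counts[, keep_cell, drop = FALSE]
  gene_prev <- Matrix::rowSums(sub > 0)
  keep_gene <- gene_prev >= thresholds$min_cells_per_gene
  out <- subset_expr(expr, genes = which(keep_gene), cells = which(keep_cell))
  out$normalized <- NULL; out$hvg <- NULL; out$pcs <- NULL
  out$log <- c(expr$log, sprintf(
    "qc: removed %d cells by mito/ERCC > %g, %d cells by < %d detected genes, %d genes in < %d cells",
    sum(!keep_mito), thresholds$max_mito_ercc_fraction,
    sum(keep_mito & !keep_genes_per_cell), thresholds$min_genes_per_cell,
    sum(!keep_gene), thresholds$min_cells_per_gene))
  out
}

#' Depth-normalize and log-transform counts
#'
#' `normalized[g, c] = log(1 + scale_factor * counts[g, c] / total[c])`
#' (natural logarithm). Raw counts are kept alongside.
#'
#' @param expr an [expr_matrix] (after QC).
#' @param scale_factor library-size scale factor (default 10,000).
#' @return The [expr_matrix] with a `normalized` layer.
#' @export
normalize_cells <- function(expr, scale_factor = 10000) {
  stopifnot(inherits(expr, "expr_matrix"), scale_factor > 0)
  tot <- Matrix::colSums(expr$counts)
  if (any(tot == 0))
    stopf("cells with zero total count: %s",
          paste(head(expr$cell_ids[tot == 0], 5), collapse = ", "))
  norm <- expr$counts %*% Matrix::Diagonal(x = scale_factor / tot)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(expr$counts)
  expr$normalized <- norm
  expr$log <- c(expr$log, sprintf("normalize: scale_factor=%g", scale_factor))
  expr
}

#' Highly-variable genes, scaling and PCA
#'
#' Ranks genes by a variance-stabilized dispersion statistic (variance of
#' the log-normalized values divided by a loess mean-variance trend),
#' keeps the top `n_hvg`, z-scores each kept gene across cells with values
#' clipped at +/-10, and computes the first `n_pcs` principal components
#' of the scaled matrix.
#'
#' @param expr an [expr_matrix] with a `normalized` layer.
#' @param n_hvg number of highly variable genes (reduced with a warning if
#'   it exceeds the gene count).
#' @param n_pcs number of principal components (reduced with a warning if
#'   too large for the matrix).
#' @return The [expr_matrix] with `hvg` (ordered gene subset) and `pcs`
#'   (cells x n_pcs orthogonal-column embedding).
#' @export
select_hvg_scale_pca <- function(expr, n_hvg = 2000, n_pcs = 20) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.null(expr$normalized)) stopf("normalized layer required; run normalize_cells()")
  norm <- expr$normalized
  mu <- Matrix::rowMeans(norm)
  v <- Matrix::rowMeans(norm^2) - mu^2
  v <- v * ncol(norm) / max(1, ncol(norm) - 1)
  disp <- rep(0, length(v))
  pos <- which(v > 0 & mu > 0)
  trend_ok <- FALSE
  if (length(pos) >= 30) {
    fit <- tryCatch(suppressWarnings({
      tr <- loess(log10(v[pos]) ~ log10(mu[pos]), span = 0.5, degree = 2)
      v[pos] / 10^predict(tr)
    }), error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit))) {
      disp[pos] <- fit; trend_ok <- TRUE
    }
  }
  if (!trend_ok) disp[pos] <- v[pos]  # raw variance when no stable trend
  if (n_hvg > nrow(norm)) {
    warnf("n_hvg (%d) exceeds gene count (%d); using all genes", n_hvg, nrow(norm))
    n_hvg <- nrow(norm)
  }
  if (!any(disp > 0)) stopf("no gene has positive variance")
  ord <- order(disp, decreasing = TRUE)   # zero-variance genes sort last
  hvg <- expr$gene_ids[ord[seq_len(n_hvg)]]

  scaled <- as.matrix(norm[hvg, , drop = FALSE])
  sds <- apply(scaled, 1, sd)
  scaled <- (scaled - rowMeans(scaled)) / ifelse(sds > 0, sds, 1)
  scaled[scaled > 10] <- 10
  scaled[scaled < -10] <- -10

  max_pcs <- min(ncol(scaled) - 1L, nrow(scaled))
  if (n_pcs > max_pcs) {
    warnf("n_pcs (%d) too large; reduced to %d", n_pcs, max_pcs)
    n_pcs <- max_pcs
  }
  pc <- prcomp(t(scaled), center = FALSE, scale. = FALSE, rank. = n_pcs)
  pcs <- pc$x[, seq_len(n_pcs), drop = FALSE]
  rownames(pcs) <- expr$cell_ids
  expr$hvg <- hvg
  expr$pcs <- pcs
  expr$log <- c(expr$log, sprintf("hvg/pca: %d hvg, %d pcs", length(hvg), n_pcs))
  expr
}
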