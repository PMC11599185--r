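#' Shared-nearest-neighbour graph clustering of cells
#'
#' Builds a k-nearest-neighbour graph on the PCA embedding, weights edges
#' by the Jaccard similarity of the two cells' neighbour sets (shared
#' nearest neighbours), prunes weak links, and optimizes modularity with
#' the Louvain algorithm at the given resolution. Clusters are renumbered
#' 0-based by decreasing size.
#'
#' @param expr an [expr_matrix] with a `pcs` embedding.
#' @param k_neighbors neighbourhood size (default 20).
#' @param resolution modularity resolution (default 0.5).
#' @param seed integer seed (the modularity optimizer is stochastic).
#' @param prune SNN edges with Jaccard weight below this are dropped
#'   (default 1/15, the usual SNN pruning cutoff).
#' @return List of class `cell_clustering`: `labels` (named 0-based
#'   integer vector), `k_neighbors`, `resolution`, `modularity`.
#' @export
cluster_cells <- function(expr, k_neighbors = 20, resolution = 0.5,
                          seed = 1, prune = 1 / 15) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.null(expr$pcs)) stopf("pcs required; run select_hvg_scale_pca()")
  n <- nrow(expr$pcs)
  if (n <= k_neighbors)
    stopf("only %d cells but k_neighbors = %d; choose a smaller k", n, k_neighbors)
  nb <- knn_index(expr$pcs, k_neighbors)
  # SNN: Jaccard overlap of neighbour sets (self included, Seurat-style)
  sets <- cbind(seq_len(n), nb)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(sets)),
                              j = as.vector(sets), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  k1 <- ncol(sets)
  snn <- methods::as(shared, "TsparseMatrix")
  keep <- snn@i < snn@j
  i <- snn@i[keep] + 1L; j <- snn@j[keep] + 1L
  w <- snn@x[keep] / (2 * k1 - snn@x[keep])   # Jaccard
  ok <- w >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = i[ok], to = j[ok], weight = w[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  set.seed(derive_seed(seed, "louvain"))
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)[as.character(seq_len(n))]
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- setNames(as.integer(relabel[as.character(memb)]), expr$cell_ids)
  structure(list(labels = labels, k_neighbors = k_neighbors,
                 resolution = resolution,
                 modularity = igraph::modularity(cl)),
            class = "cell_clustering")
}

# exact k nearest neighbours (Euclidean) by blocked distance computation
knn_index <- function(x, k) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  out <- matrix(0L, n, k)
  block <- max(1L, min(n, floor(2e7 / n)))
  for (s in seq(1L, n, by = block)) {
    idx <- s:min(n, s + block - 1L)
    d2 <- outer(sq[idx], sq, "+") - 2 * x[idx, , drop = FALSE] %*% t(x)
    for (r in seq_along(idx)) {
      d2[r, idx[r]] <- Inf
      out[idx[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  out
}

#' @export
print.cell_clustering <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("SNN clustering: %d clusters over %d cells (resolution %g, k = %d)\n",
              length(tab), length(x$labels), x$resolution, x$k_neighbors))
  cat("  sizes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# One-vs-rest Wilcoxon rank-sum, one gene per row. Exact null distribution
# on small tie-free samples, otherwise the normal approximation with tie
# and continuity corrections -- the same dispatch as stats::wilcox.test.
rank_sum_rows <- function(mat, in_group, alternative = "greater") {
  n <- ncol(mat); n1 <- sum(in_group); n2 <- n - n1
  p <- numeric(nrow(mat))
  for (g in seq_len(nrow(mat))) {
    r <- rank(mat[g, ])
    W <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- table(r)
    has_ties <- any(ties > 1)
    if (!has_ties && n1 < 50 && n2 < 50) {
      p[g] <- switch(alternative,
        greater = stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE),
        less = stats::pwilcox(W, n1, n2),
        two.sided = {
          pl <- stats::pwilcox(W, n1, n2)
          pg <- stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE)
          min(2 * min(pl, pg), 1)
        })
      next
    }
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) { p[g] <- 1; next }
    z <- W - n1 * n2 / 2
    cc <- switch(alternative, greater = 0.5, less = -0.5,
                 two.sided = sign(z) * 0.5)
    z <- (z - cc) / sqrt(sigma2)
    p[g] <- switch(alternative,
                   greater = pnorm(z, lower.tail = FALSE),
                   less = pnorm(z),
                   two.sided = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
  }
  pmin(p, 1)
}

#' One-vs-rest marker detection per cluster
#'
#' Wilcoxon rank-sum test of each gene in each cluster against all other
#' cells, on the log-normalized layer; log fold-change is the difference
#' of mean log-normalized expression. Only positively enriched genes
#' (lfc > 0) are reported; p-values are Benjamini-Hochberg adjusted per
#' cluster across all tested genes.
#'
#' @param expr an [expr_matrix] with a `normalized` layer.
#' @param clustering a [cluster_cells()] result.
#' @param min_lfc minimum log fold-change to report (default 0,
#'   i.e. any positive enrichment).
#' @return data.frame (`gene_id`, `cluster`, `lfc`, `p`, `p_adj`), sorted
#'   by cluster then adjusted p.
#' @export
find_markers <- function(expr, clustering, min_lfc = 0) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(clustering, "cell_clustering"))
  if (is.null(expr$normalized)) stopf("normalized layer required")
  labels <- clustering$labels[expr$cell_ids]
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) {
    warnf("single cluster: no markers to find")
    return(data.frame(gene_id = character(), cluster = integer(),
                      lfc = numeric(), p = numeric(), p_adj = numeric()))
  }
  norm <- as.matrix(expr$normalized)
  res <- lapply(clusters, function(cl) {
    ing <- labels == cl
    lfc <- rowMeans(norm[, ing, drop = FALSE]) -
      rowMeans(norm[, !ing, drop = FALSE])
    p <- rank_sum_rows(norm, ing, alternative = "greater")
    d <- data.frame(gene_id = expr$gene_ids, cluster = cl, lfc = lfc,
                    p = p, p_adj = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
    d[d$lfc > min_lfc, ]
  })
  out <- do.call(rbind, res)
  out <- out[order(out$cluster, out$p_adj, out$p), ]
  rownames(out) <- NULL
  out
}

#' Assign cell types to clusters from reference markers
#'
#' Scores each (cluster, type) pair by the mean log-normalized expression
#' of that type's reference marker genes over the cluster's cells and
#' assigns each cluster the argmax type. A cluster whose scores are all
#' zero gets the sentinel `"unknown"`; ties are broken by lexicographic
#' type name with a warning. The assignment is written into
#' `cell_meta$assigned_type`.
#'
#' @param expr an [expr_matrix] with a `normalized` layer.
#' @param clustering a [cluster_cells()] result.
#' @param reference_markers data.frame (`gene`, `cell_type`); markers
#'   absent from the matrix are dropped with a warning.
#' @return List: `expr` (annotated), `assignment` (named cluster -> type),
#'   `scores` (cluster x type matrix).
#' @export
annotate_clusters <- function(expr, clustering, reference_markers) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(clustering, "cell_clustering"))
  if (is.null(expr$normalized)) stopf("normalized layer required")
  rm_tab <- as.data.frame(reference_markers)
  names(rm_tab)[1:2] <- c("gene", "cell_type")
  present <- rm_tab$gene %in% expr$gene_ids
  if (!any(present)) stopf("no reference marker gene present in the matrix")
  if (any(!present))
    warnf("%d reference markers absent from the matrix; dropped", sum(!present))
  rm_tab <- rm_tab[present, ]
  labels <- clustering$labels[expr$cell_ids]
  clusters <- sort(unique(labels))
  types <- sort(unique(rm_tab$cell_type))
  scores <- matrix(0, length(clusters), length(types),
                   dimnames = list(as.character(clusters), types))
  norm <- expr$normalized
  for (ty in types) {
    gs <- rm_tab$gene[rm_tab$cell_type == ty]
    mg <- Matrix::colMeans(norm[gs, , drop = FALSE])
    for (cl in clusters)
      scores[as.character(cl), ty] <- mean(mg[labels == cl])
  }
  assignment <- apply(scores, 1, function(s) {
    if (all(s == 0)) return("unknown")
    best <- names(s)[s == max(s)]
    if (length(best) > 1)
      warnf("tie between types %s; lexicographic tie-break",
            paste(best, collapse = ", "))
    sort(best)[1]
  })
  expr$cell_meta$assigned_type <- unname(assignment[as.character(labels)])
  expr$log <- c(expr$log, sprintf("annotate: %s",
    paste(sprintf("%s->%s", names(assignment), assignment), collapse = ", ")))
  list(expr = expr, assignment = assignment, scores = scores)
}
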