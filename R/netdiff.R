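#' Differential network between two conditions
#'
#' Set differences on typed edges and on node ids. The "only in b" edge
#' set induces the rewired (grade-IV-specific) differential network.
#'
#' @param net_a,net_b `mlnet` objects with the same layer schema.
#' @return List `edges_only_a`, `edges_only_b`, `nodes_only_a`,
#'   `nodes_only_b`.
#' @export
differential_network <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "mlnet"), inherits(net_b, "mlnet"))
  ek <- function(n) paste(n$edges$src, n$edges$dst, n$edges$edge_type)
  ka <- ek(net_a); kb <- ek(net_b)
  na <- unlist(net_a$layers, use.names = FALSE)
  nb <- unlist(net_b$layers, use.names = FALSE)
  list(edges_only_a = net_a$edges[!(ka %in% kb), , drop = FALSE],
       edges_only_b = net_b$edges[!(kb %in% ka), , drop = FALSE],
       nodes_only_a = setdiff(na, nb),
       nodes_only_b = setdiff(nb, na))
}

#' Node centralities of a multilayer network
#'
#' Computed on the directed four-layer graph: total/in/out degree; Katz
#' centrality `x = (I - alpha * t(A))^{-1} 1` (attenuated count of all
#' incoming walks plus the unit bias, requiring `alpha` below the inverse
#' spectral radius -- a layered DAG is nilpotent, so any alpha works);
#' PageRank with uniform teleportation; betweenness over directed
#' shortest paths, pairwise-normalized by `(n-1)(n-2)`.
#'
#' @param net an `mlnet` (or a directed igraph graph).
#' @param katz_alpha attenuation; default `min(0.1, 0.85 / spectral
#'   radius)`.
#' @param pagerank_damping damping factor (default 0.85).
#' @param normalized_betweenness divide by `(n-1)(n-2)` (default TRUE).
#' @return data.frame, one row per node: `node`, `layer`, `degree`,
#'   `in_degree`, `out_degree`, `betweenness`, `katz`, `pagerank`.
#' @export
centralities <- function(net, katz_alpha = NULL, pagerank_damping = 0.85,
                         normalized_betweenness = TRUE) {
  g <- if (inherits(net, "mlnet")) as_igraph(net) else net
  n <- igraph::vcount(g)
  if (n == 0)
    return(data.frame(node = character(), layer = character(),
                      degree = numeric(), in_degree = numeric(),
                      out_degree = numeric(), betweenness = numeric(),
                      katz = numeric(), pagerank = numeric()))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  sr <- if (n > 1) max(Mod(eigen(A, only.values = TRUE)$values)) else 0
  if (is.null(katz_alpha))
    katz_alpha <- if (sr > 0) min(0.1, 0.85 / sr) else 0.1
  if (sr > 0 && katz_alpha >= 1 / sr)
    stopf("katz_alpha (%g) at/above 1/spectral radius (%g): series diverges",
          katz_alpha, 1 / sr)
  katz <- solve(diag(n) - katz_alpha * t(A), rep(1, n))
  btw <- igraph::betweenness(g, directed = TRUE,
                             normalized = normalized_betweenness && n > 2)
  pr <- igraph::page_rank(g, damping = pagerank_damping)$vector
  data.frame(node = igraph::V(g)$name,
             layer = igraph::V(g)$layer %||% NA_character_,
             degree = igraph::degree(g, mode = "all"),
             in_degree = igraph::degree(g, mode = "in"),
             out_degree = igraph::degree(g, mode = "out"),
             betweenness = unname(btw), katz = unname(katz),
             pagerank = unname(pr), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Welch comparison of a centrality metric between two networks
#'
#' Two-sample Welch t-test on the per-node values of the chosen metric.
#' With zero variance in both samples the statistic is undefined and is
#' reported as such (`defined = FALSE`, p = NA).
#'
#' @param tab_a,tab_b [centralities()] tables.
#' @param metric one of `"katz"`, `"pagerank"`, `"betweenness"`,
#'   `"degree"`.
#' @return List `t`, `p`, `defined`.
#' @export
compare_centralities <- function(tab_a, tab_b, metric = "katz") {
  a <- tab_a[[metric]]; b <- tab_b[[metric]]
  if (length(a) < 2 || length(b) < 2)
    stopf("need >= 2 nodes per network")
  if (var(a) == 0 && var(b) == 0)
    return(list(t = NA_real_, p = NA_real_, defined = FALSE))
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value, defined = TRUE)
}

#' Compare the three headline centralities with multiplicity adjustment
#'
#' Katz, PageRank and betweenness are each Welch-tested between the two
#' networks; p-values are adjusted across the three tests
#' (Benjamini-Hochberg by default).
#'
#' @param net_a,net_b `mlnet` objects (or precomputed tables via
#'   `tab_a`/`tab_b`).
#' @param adjust p-adjustment rule (default `"BH"`).
#' @param ... passed to [centralities()].
#' @return data.frame (`metric`, `t`, `p`, `p_adj`, `defined`).
#' @export
compare_all_centralities <- function(net_a, net_b, adjust = "BH", ...) {
  tab_a <- if (inherits(net_a, "mlnet")) centralities(net_a, ...) else net_a
  tab_b <- if (inherits(net_b, "mlnet")) centralities(net_b, ...) else net_b
  metrics <- c("katz", "pagerank", "betweenness")
  res <- lapply(metrics, function(m) {
    r <- compare_centralities(tab_a, tab_b, m)
    data.frame(metric = m, t = r$t, p = r$p, defined = r$defined)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, adjust)
  out[, c("metric", "t", "p", "p_adj", "defined")]
}

#' Total-degree distribution of a network
#'
#' @param net an `mlnet`.
#' @return data.frame (`degree`, `n_nodes`); counts sum to the node count.
#' @export
degree_distribution <- function(net) {
  stopifnot(inherits(net, "mlnet"))
  nodes <- unlist(net$layers, use.names = FALSE)
  if (!length(nodes))
    return(data.frame(degree = integer(), n_nodes = integer()))
  deg <- table(factor(c(net$edges$src, net$edges$dst), levels = nodes))
  tab <- table(as.integer(deg))
  data.frame(degree = as.integer(names(tab)), n_nodes = as.integer(tab))
}
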