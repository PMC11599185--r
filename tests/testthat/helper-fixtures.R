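# Shared fixtures (memoized across test files) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# default-condition synthetic study, processed through the full upstream
# pipeline (QC -> normalize -> HVG/PCA -> cluster -> annotate) per grade
pipeline_fixture <- function() memo("pipeline", function() {
  sim <- simulate_study(seed = 1)
  proc <- function(ex) {
    ex <- apply_qc(ex)
    ex <- normalize_cells(ex)
    ex <- suppressWarnings(select_hvg_scale_pca(ex))
    cl <- cluster_cells(ex, seed = 1)
    ann <- annotate_clusters(ex, cl, sim$truth$reference_markers)
    list(expr = ann$expr, clustering = cl, assignment = ann$assignment)
  }
  g3 <- proc(sim$grade_III); g4 <- proc(sim$grade_IV)
  list(sim = sim, g3 = g3, g4 = g4)
})

# the fitted multilayer networks for both grades
network_fixture <- function() memo("networks", function() {
  fx <- pipeline_fixture()
  list(
    net3 = mlnet(fx$g3$expr, fx$sim$prior, grade = "III", seed = 1),
    net4 = mlnet(fx$g4$expr, fx$sim$prior, grade = "IV", seed = 1))
})

quad_key_of <- function(q) paste(q$ligand, q$receptor, q$tf, q$target,
                                 sep = "|")

# small deterministic count matrix wrapped as expr_matrix
toy_expr <- function(counts, grade = "other") {
  m <- Matrix::Matrix(counts, sparse = TRUE)
  expr_matrix(m, cell_meta = data.frame(
    cell_id = colnames(counts), sample_id = "S1", grade = grade,
    stringsAsFactors = FALSE))
}

# ---- independent oracles -------------------------------------------------

# brute-force 4-path enumeration by nested loops over raw edge tables
oracle_quadruples <- function(lr, rt, tt) {
  out <- list()
  for (i in seq_len(nrow(lr))) for (j in seq_len(nrow(rt)))
    for (k in seq_len(nrow(tt))) {
      if (lr[i, 2] == rt[j, 1] && rt[j, 2] == tt[k, 1])
        out[[length(out) + 1L]] <- data.frame(
          ligand = lr[i, 1], receptor = lr[i, 2], tf = rt[j, 2],
          target = tt[k, 2], stringsAsFactors = FALSE)
    }
  if (!length(out))
    return(data.frame(ligand = character(), receptor = character(),
                      tf = character(), target = character()))
  q <- unique(do.call(rbind, out))
  q[order(q$ligand, q$receptor, q$tf, q$target), , drop = FALSE]
}

# Katz by explicit series summation x = 1 + sum_k alpha^k (A^T)^k 1
oracle_katz <- function(A, alpha, n_terms = 200) {
  x <- rep(1, nrow(A)); term <- rep(1, nrow(A))
  for (k in seq_len(n_terms)) {
    term <- alpha * t(A) %*% term
    x <- x + as.numeric(term)
    if (max(abs(term)) < 1e-14) break
  }
  x
}

# PageRank by power iteration with uniform teleport; dangling mass
# redistributed uniformly (the igraph/standard convention)
oracle_pagerank <- function(A, d = 0.85, tol = 1e-12) {
  n <- nrow(A)
  out_deg <- rowSums(A)
  P <- A / ifelse(out_deg > 0, out_deg, 1)
  x <- rep(1 / n, n)
  repeat {
    dangling <- sum(x[out_deg == 0])
    x_new <- (1 - d) / n + d * (as.numeric(t(P) %*% x) + dangling / n)
    if (max(abs(x_new - x)) < tol) break
    x <- x_new
  }
  x_new / sum(x_new)
}

# betweenness by exhaustive shortest-path counting (unweighted digraph)
oracle_betweenness <- function(A, normalized = FALSE) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); S <- matrix(0, n, n)  # distance, #shortest paths
  diag(D) <- 0; diag(S) <- 1
  D[A > 0] <- 1; S[A > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || k == i || k == j) next
    via <- D[i, k] + D[k, j]
    if (via < D[i, j]) { D[i, j] <- via; S[i, j] <- S[i, k] * S[k, j] }
    else if (via == D[i, j] && is.finite(via))
      S[i, j] <- S[i, j] + S[i, k] * S[k, j]
  }
  # recompute path counts cleanly by DP over increasing distance
  S <- matrix(0, n, n); diag(S) <- 1
  ord <- order(as.vector(D))
  for (idx in ord) {
    i <- (idx - 1) %% n + 1; j <- (idx - 1) %/% n + 1
    if (i == j || !is.finite(D[i, j])) next
    if (D[i, j] == 1) { S[i, j] <- 1; next }
    preds <- which(A[, j] > 0)
    S[i, j] <- sum(S[i, preds] * (D[i, preds] == D[i, j] - 1))
  }
  btw <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (length(unique(c(s, t, v))) < 3) next
    if (!is.finite(D[s, t]) || S[s, t] == 0) next
    if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
        D[s, v] + D[v, t] == D[s, t])
      btw[v] <- btw[v] + S[s, v] * S[v, t] / S[s, t]
  }
  if (normalized && n > 2) btw <- btw / ((n - 1) * (n - 2))
  btw
}

# one-sided Fisher/hypergeometric tail by explicit enumeration of the
# 2x2 tables at least as extreme
oracle_fisher_tail <- function(overlap, K, N, n_he) {
  xs <- overlap:min(K, n_he)
  sum(choose(K, xs) * choose(N - K, n_he - xs)) / choose(N, n_he)
}

# random layered DAG over <= `max_per_layer` nodes per layer
random_layered_edges <- function(max_per_layer = 5, p = 0.4) {
  sizes <- sample(1:max_per_layer, 4, replace = TRUE)
  lg <- paste0("l", seq_len(sizes[1])); rc <- paste0("r", seq_len(sizes[2]))
  tf <- paste0("f", seq_len(sizes[3])); tg <- paste0("t", seq_len(sizes[4]))
  rel <- function(a, b) {
    g <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    g[runif(nrow(g)) < p, , drop = FALSE]
  }
  list(lr = setNames(rel(lg, rc), c("ligand", "receptor")),
       rt = setNames(rel(rc, tf), c("receptor", "tf")),
       tt = setNames(rel(tf, tg), c("tf", "target")))
}

adjusted_rand_index <- function(a, b) mclust::adjustedRandIndex(a, b)
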