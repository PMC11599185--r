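#' Multilayer network construction parameters
#'
#' @param he_fraction minimum detection fraction for a gene to count as
#'   highly expressed in a cell type (default 0.10; the filter itself is
#'   part of the method, the value is a tunable).
#' @param tf_alpha significance level for TF activation (default 0.05).
#' @param lasso_lambda_rule `"cv_1se"` (default, sparser) or `"cv_min"`.
#' @param cv_folds cross-validation folds for the LASSO (default 10).
#' @param mt_correction `"BH"` (default) or `"none"` across TF p-values.
#' @return A list of class `mlnet_params`.
#' @export
mlnet_params <- function(he_fraction = 0.10, tf_alpha = 0.05,
                         lasso_lambda_rule = c("cv_1se", "cv_min"),
                         cv_folds = 10, mt_correction = c("BH", "none")) {
  stopifnot(he_fraction > 0, he_fraction <= 1, tf_alpha > 0, tf_alpha < 1)
  structure(list(he_fraction = he_fraction, tf_alpha = tf_alpha,
                 lasso_lambda_rule = match.arg(lasso_lambda_rule),
                 cv_folds = cv_folds,
                 mt_correction = match.arg(mt_correction)),
            class = "mlnet_params")
}

#' Genes highly expressed in a cell type
#'
#' A gene is highly expressed in a type when it is detected (count > 0)
#' in at least `he_fraction` of that type's cells.
#'
#' @param expr an [expr_matrix] with `assigned_type` filled in.
#' @param cell_type type label.
#' @param he_fraction detection-fraction threshold.
#' @return Character vector of gene ids.
#' @export
highly_expressed_genes <- function(expr, cell_type, he_fraction = 0.10) {
  stopifnot(inherits(expr, "expr_matrix"))
  cells <- which(expr$cell_meta$assigned_type == cell_type)
  if (!length(cells)) stopf("no cells assigned to type '%s'", cell_type)
  frac <- Matrix::rowSums(expr$counts[, cells, drop = FALSE] > 0) / length(cells)
  expr$gene_ids[frac >= he_fraction]
}

#' Ligand-receptor edges between sender and receiver populations
#'
#' @param sender_he,receiver_he highly expressed gene sets of the sender
#'   and receiver types.
#' @param prior a [prior_db].
#' @return data.frame (`ligand`, `receptor`) of prior pairs with the
#'   ligand highly expressed in senders and the receptor in receivers.
#' @export
build_lr_edges <- function(sender_he, receiver_he, prior) {
  stopifnot(inherits(prior, "prior_db"))
  keep <- prior$lr_pairs$ligand %in% sender_he &
    prior$lr_pairs$receptor %in% receiver_he
  out <- prior$lr_pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' TF activation by target-set enrichment (one-sided Fisher test)
#'
#' For each TF in the prior, tests whether its annotated targets are
#' enriched among the receiver's highly expressed genes, against the
#' background of genes detected in receiver cells intersected with the
#' prior universe. The one-sided Fisher exact p equals the hypergeometric
#' upper tail P(X >= overlap).
#'
#' @param receiver_he highly expressed receiver gene set (must be a
#'   subset of `background`).
#' @param prior a [prior_db].
#' @param background background gene universe (detected receiver genes
#'   intersected with the prior universe).
#' @param tf_alpha retention level on the (adjusted) p-value.
#' @param mt_correction `"BH"` or `"none"`.
#' @return data.frame (`tf`, `overlap`, `n_targets`, `fisher_p`, `p_adj`,
#'   `retained`); the mapping of retained TFs is `fisher_p` filtered on
#'   `retained`.
#' @export
activated_tfs <- function(receiver_he, prior, background,
                          tf_alpha = 0.05, mt_correction = "BH") {
  stopifnot(inherits(prior, "prior_db"))
  if (!length(background)) stopf("empty background gene set")
  if (!all(receiver_he %in% background))
    stopf("receiver_he must be a subset of the background")
  he <- intersect(receiver_he, background)
  N <- length(background); n_he <- length(he)
  tfs <- sort(unique(prior$tf_target$tf))
  res <- lapply(tfs, function(tf) {
    targ <- intersect(prior$tf_target$target[prior$tf_target$tf == tf],
                      background)
    K <- length(targ); ov <- length(intersect(targ, he))
    p <- if (K == 0) 1 else
      phyper(ov - 1, K, N - K, n_he, lower.tail = FALSE)
    data.frame(tf = tf, overlap = ov, n_targets = K, fisher_p = p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- if (mt_correction == "BH") p.adjust(out$fisher_p, "BH")
    else out$fisher_p
  out$retained <- out$p_adj < tf_alpha & out$n_targets > 0
  out
}

#' TF -> target regulatory edges by cross-validated LASSO
#'
#' For each candidate target, regresses its log-normalized expression
#' across receiver cells on the log-normalized expression of the
#' activated TFs annotated to regulate it (L1 penalty, per-column
#' standardized design, lambda chosen on a log grid by `cv_folds`-fold
#' cross-validation under `lambda_rule`). The edge (tf, target) is
#' retained iff its fitted coefficient is nonzero and the pair is
#' annotated in the prior.
#'
#' @param expr an [expr_matrix] with `normalized` layer and assigned types.
#' @param receiver_type receiver cell-type label.
#' @param activated character vector of activated TFs.
#' @param candidate_targets candidate target genes (receiver highly
#'   expressed genes annotated to >= 1 activated TF).
#' @param prior a [prior_db].
#' @param lambda_rule `"cv_1se"` or `"cv_min"`.
#' @param cv_folds CV folds.
#' @param seed integer seed (fold assignment).
#' @param lambda optional fixed penalty overriding the CV choice.
#' @return data.frame (`tf`, `target`, `lasso_coef`) with nonzero
#'   coefficients only.
#' @export
tf_target_edges <- function(expr, receiver_type, activated,
                            candidate_targets, prior,
                            lambda_rule = "cv_1se", cv_folds = 10,
                            seed = 1, lambda = NULL) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(prior, "prior_db"))
  if (!length(activated)) stopf("no activated TFs")
  cells <- which(expr$cell_meta$assigned_type == receiver_type)
  if (length(cells) < 2 * cv_folds)
    stopf("only %d receiver cells for %d-fold CV; use fewer folds",
          length(cells), cv_folds)
  norm <- expr$normalized[, cells, drop = FALSE]
  edges <- list()
  set.seed(derive_seed(seed, "lasso"))
  for (t in candidate_targets) {
    tfs <- intersect(prior$tf_target$tf[prior$tf_target$target == t],
                     activated)
    tfs <- intersect(tfs, expr$gene_ids)
    tfs <- setdiff(tfs, t)
    if (!length(tfs)) next
    y <- as.numeric(norm[t, ])
    X <- t(as.matrix(norm[tfs, , drop = FALSE]))
    colnames(X) <- tfs
    coefs <- lasso_cv_fit(X, y, lambda_rule = lambda_rule,
                          cv_folds = cv_folds, lambda = lambda)
    nz <- which(coefs != 0)
    if (length(nz))
      edges[[length(edges) + 1L]] <- data.frame(
        tf = tfs[nz], target = t, lasso_coef = unname(coefs[nz]),
        stringsAsFactors = FALSE)
  }
  if (!length(edges))
    return(data.frame(tf = character(), target = character(),
                      lasso_coef = numeric()))
  out <- do.call(rbind, edges)
  # prior-membership re-check (guaranteed by construction of tfs above)
  key <- paste(out$tf, out$target)
  ann <- paste(prior$tf_target$tf, prior$tf_target$target)
  out <- out[key %in% ann, ]
  rownames(out) <- NULL
  out
}

# CV'd LASSO returning the coefficient vector at the selected lambda
# (or at a caller-forced `lambda`). glmnet needs >= 2 predictors; the
# single-predictor case is solved by the closed-form soft-threshold on
# standardized x with the same CV selection.
lasso_cv_fit <- function(X, y, lambda_rule = "cv_1se", cv_folds = 10,
                         lambda = NULL) {
  n <- nrow(X)
  if (sd(y) == 0) return(setNames(rep(0, ncol(X)), colnames(X)))
  if (ncol(X) >= 2) {
    if (!is.null(lambda)) {
      fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lambda,
                            standardize = TRUE)
      return(setNames(as.numeric(coef(fit))[-1], colnames(X)))
    }
    fit <- glmnet::cv.glmnet(X, y, alpha = 1, nfolds = cv_folds,
                             standardize = TRUE)
    s <- if (lambda_rule == "cv_1se") "lambda.1se" else "lambda.min"
    cf <- coef(fit, s = s)
    return(setNames(as.numeric(cf)[-1], colnames(X)))
  }
  # p = 1: soft-thresholded OLS on standardized x, CV over a log grid
  x <- as.numeric(X[, 1])
  if (sd(x) == 0) return(setNames(0, colnames(X)))
  if (!is.null(lambda)) {
    xs <- (x - mean(x)) / sd_pop(x)
    b <- sign(mean(xs * (y - mean(y)))) *
      pmax(abs(mean(xs * (y - mean(y)))) - lambda, 0)
    return(setNames(b / sd_pop(x), colnames(X)))
  }
  soft <- function(z, l) sign(z) * pmax(abs(z) - l, 0)
  fit1 <- function(xtr, ytr, lambda) {
    xs <- (xtr - mean(xtr)) / sd_pop(xtr)
    b <- soft(mean(xs * (ytr - mean(ytr))), lambda) # / Var(xs) = 1
    c(b = b / sd_pop(xtr), a = mean(ytr) - b / sd_pop(xtr) * mean(xtr))
  }
  lmax <- abs(mean(((x - mean(x)) / sd_pop(x)) * (y - mean(y))))
  if (lmax == 0) return(setNames(0, colnames(X)))
  grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 60))
  folds <- sample(rep(seq_len(cv_folds), length.out = n))
  errs <- matrix(NA_real_, cv_folds, length(grid))
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    for (li in seq_along(grid)) {
      cf <- fit1(x[tr], y[tr], grid[li])
      errs[f, li] <- mean((y[!tr] - cf["a"] - cf["b"] * x[!tr])^2)
    }
  }
  m <- colMeans(errs); se <- apply(errs, 2, sd) / sqrt(cv_folds)
  i_min <- which.min(m)
  i_sel <- if (lambda_rule == "cv_1se")
    min(which(m <= m[i_min] + se[i_min])) else i_min
  cf <- fit1(x, y, grid[i_sel])
  b <- unname(cf["b"])
  if (abs(b) < 1e-10) b <- 0   # numerical zero at full shrinkage
  setNames(b, colnames(X))
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Receptor -> TF edges
#'
#' Prior receptor-TF links whose receptor appears in the ligand-receptor
#' edge set and whose TF is activated.
#'
#' @param lr_edges data.frame from [build_lr_edges()].
#' @param activated character vector of activated TFs.
#' @param prior a [prior_db].
#' @return data.frame (`receptor`, `tf`).
#' @export
link_receptor_tf <- function(lr_edges, activated, prior) {
  stopifnot(inherits(prior, "prior_db"))
  keep <- prior$rec_tf$receptor %in% lr_edges$receptor &
    prior$rec_tf$tf %in% activated
  out <- prior$rec_tf[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble and prune the four-layer network
#'
#' Unions the typed edge sets and removes every node (with its edges)
#' that does not lie on at least one complete
#' ligand -> receptor -> TF -> target path, iterating to the fixed point.
#' Signaling cut off at the receptor or TF level is thereby discarded.
#'
#' @param lr_edges data.frame (`ligand`, `receptor`).
#' @param rtf_edges data.frame (`receptor`, `tf`).
#' @param tft_edges data.frame (`tf`, `target`, optionally `lasso_coef`).
#' @param grade condition label carried on the network.
#' @param sender_type,receiver_type population labels.
#' @param tf_pvalues optional named vector of TF activation p-values,
#'   stored on the R->TF edges.
#' @return An object of class `mlnet`: `layers` (list of the four ordered
#'   node sets), `edges` (data.frame `src`, `dst`, `edge_type`,
#'   `statistic`), plus the labels.
#' @export
assemble_network <- function(lr_edges, rtf_edges, tft_edges, grade = "NA",
                             sender_type = "immune",
                             receiver_type = "cancer",
                             tf_pvalues = NULL) {
  lr <- unique(data.frame(src = as.character(lr_edges$ligand),
                          dst = as.character(lr_edges$receptor),
                          stringsAsFactors = FALSE))
  rt <- unique(data.frame(src = as.character(rtf_edges$receptor),
                          dst = as.character(rtf_edges$tf),
                          stringsAsFactors = FALSE))
  tt <- data.frame(src = as.character(tft_edges$tf),
                   dst = as.character(tft_edges$target),
                   stat = if (!is.null(tft_edges$lasso_coef))
                     tft_edges$lasso_coef else
                       rep(NA_real_, length(tft_edges$tf)),
                   stringsAsFactors = FALSE)
  tt <- tt[!duplicated(tt[, 1:2]), , drop = FALSE]
  # a node survives iff it is forward-reachable from the ligand layer and
  # backward-reachable from the target layer; in a layered DAG this is
  # exactly "lies on a complete 4-path", the pruning fixed point
  r_ok <- intersect(lr$dst, rt$src)
  tf_fwd <- rt$dst[rt$src %in% r_ok]
  tf_ok <- intersect(tf_fwd, tt$src)
  r_back <- rt$src[rt$dst %in% tf_ok]
  r_ok <- intersect(r_ok, r_back)
  l_ok <- unique(lr$src[lr$dst %in% r_ok])
  lr <- lr[lr$src %in% l_ok & lr$dst %in% r_ok, , drop = FALSE]
  rt <- rt[rt$src %in% r_ok & rt$dst %in% tf_ok, , drop = FALSE]
  tt <- tt[tt$src %in% tf_ok, , drop = FALSE]
  t_ok <- unique(tt$dst)
  edges <- rbind(
    if (nrow(lr)) data.frame(lr, edge_type = "LR", statistic = NA_real_),
    if (nrow(rt)) data.frame(src = rt$src, dst = rt$dst, edge_type = "RTF",
                             statistic = if (!is.null(tf_pvalues))
                               unname(tf_pvalues[rt$dst]) else NA_real_),
    if (nrow(tt)) data.frame(src = tt$src, dst = tt$dst, edge_type = "TFT",
                             statistic = tt$stat))
  if (is.null(edges))
    edges <- data.frame(src = character(), dst = character(),
                        edge_type = character(), statistic = numeric())
  rownames(edges) <- NULL
  structure(list(layers = list(ligands = sort(unique(l_ok)),
                               receptors = sort(unique(r_ok)),
                               tfs = sort(unique(tf_ok)),
                               targets = sort(unique(t_ok))),
                 edges = edges, grade = grade, sender_type = sender_type,
                 receiver_type = receiver_type),
            class = "mlnet")
}

#' Fit the multilayer signaling network for one condition
#'
#' Runs the full construction: highly expressed gene sets for sender and
#' receiver, ligand-receptor edges, Fisher-exact TF activation over the
#' detected-receiver-genes background, LASSO TF-target selection, the
#' receptor-TF linkage, and complete-path pruning.
#'
#' @param expr an [expr_matrix], normalized and annotated.
#' @param sender_type,receiver_type population labels (defaults: immune
#'   senders, cancer receivers).
#' @param prior a [prior_db].
#' @param params an [mlnet_params].
#' @param grade condition label for the resulting network.
#' @param seed integer seed (LASSO fold assignment).
#' @return An [assemble_network()] object of class `mlnet`, with the TF
#'   activation table attached as attribute `tf_table`.
#' @export
mlnet <- function(expr, prior, sender_type = "immune",
                  receiver_type = "cancer", params = mlnet_params(),
                  grade = "NA", seed = 1) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(prior, "prior_db"),
            inherits(params, "mlnet_params"))
  send_he <- highly_expressed_genes(expr, sender_type, params$he_fraction)
  recv_he <- highly_expressed_genes(expr, receiver_type, params$he_fraction)
  recv_cells <- which(expr$cell_meta$assigned_type == receiver_type)
  detected <- expr$gene_ids[
    Matrix::rowSums(expr$counts[, recv_cells, drop = FALSE] > 0) > 0]
  background <- intersect(detected, prior$universe)
  lr <- build_lr_edges(send_he, recv_he, prior)
  tf_tab <- activated_tfs(intersect(recv_he, background), prior, background,
                          tf_alpha = params$tf_alpha,
                          mt_correction = params$mt_correction)
  act <- tf_tab$tf[tf_tab$retained]
  cand <- intersect(recv_he,
                    prior$tf_target$target[prior$tf_target$tf %in% act])
  tft <- if (length(act) && length(cand))
    tf_target_edges(expr, receiver_type, act, cand, prior,
                    lambda_rule = params$lasso_lambda_rule,
                    cv_folds = params$cv_folds, seed = seed)
  else data.frame(tf = character(), target = character(),
                  lasso_coef = numeric())
  rtf <- link_receptor_tf(lr, act, prior)
  net <- assemble_network(lr, rtf, tft, grade = grade,
                          sender_type = sender_type,
                          receiver_type = receiver_type,
                          tf_pvalues = setNames(tf_tab$p_adj, tf_tab$tf))
  attr(net, "tf_table") <- tf_tab
  net
}

#' @export
print.mlnet <- function(x, ...) {
  cat(sprintf("Multilayer signaling network (grade %s): %s -> %s\n",
              x$grade, x$sender_type, x$receiver_type))
  cat(sprintf("  layers: %d ligands, %d receptors, %d TFs, %d targets\n",
              length(x$layers$ligands), length(x$layers$receptors),
              length(x$layers$tfs), length(x$layers$targets)))
  cat(sprintf("  edges: %d (LR %d, RTF %d, TFT %d)\n", nrow(x$edges),
              sum(x$edges$edge_type == "LR"),
              sum(x$edges$edge_type == "RTF"),
              sum(x$edges$edge_type == "TFT")))
  invisible(x)
}

#' @export
summary.mlnet <- function(object, ...) {
  print(object)
  q <- enumerate_quadruples(object)
  cat(sprintf("  complete L->R->TF->T paths: %d\n", nrow(q)))
  invisible(list(network = object, n_quadruples = nrow(q)))
}

#' Convert a multilayer network to an igraph object
#'
#' @param net an `mlnet`.
#' @return A directed igraph graph with vertex attribute `layer` and edge
#'   attributes `edge_type`, `statistic`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "mlnet"))
  nodes <- data.frame(
    name = unlist(net$layers, use.names = FALSE),
    layer = rep(c("ligand", "receptor", "tf", "target"),
                times = lengths(net$layers)))
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = nodes)
}

#' @export
plot.mlnet <- function(x, ...) {
  g <- as_igraph(x)
  layer_idx <- match(igraph::V(g)$layer,
                     c("ligand", "receptor", "tf", "target"))
  lay <- cbind(layer_idx, stats::ave(seq_along(layer_idx), layer_idx,
                                     FUN = seq_along))
  cols <- c("pink", "palegreen3", "gold", "skyblue")[layer_idx]
  igraph::plot.igraph(g, layout = lay, vertex.color = cols,
                      vertex.size = 8, vertex.label.cex = 0.6,
                      edge.arrow.size = 0.3, ...)
  invisible(x)
}

#' Export a network as GraphML or a typed edge-list TSV
#'
#' @param net an `mlnet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edge_tsv <- function(net, path) {
  stopifnot(inherits(net, "mlnet"))
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
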