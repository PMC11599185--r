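typed_expr <- function(counts, types) {
  ex <- toy_expr(counts)
  ex$cell_meta$assigned_type <- types
  ex
}

test_that("highly expressed genes follow the detection-fraction rule", {
  m <- rbind(g1 = rep(1, 10), g2 = c(rep(1, 5), rep(0, 5)), g3 = rep(0, 10))
  colnames(m) <- paste0("c", 1:10)
  ex <- typed_expr(m, rep("cancer", 10))
  expect_setequal(highly_expressed_genes(ex, "cancer", 0.5), c("g1", "g2"))
  expect_setequal(highly_expressed_genes(ex, "cancer", 1.0), "g1")
  expect_setequal(highly_expressed_genes(ex, "cancer", 1e-9),
                  c("g1", "g2"))
  expect_error(highly_expressed_genes(ex, "immune", 0.5), "immune")
  # monotonicity: a larger threshold never adds genes
  for (f in c(0.2, 0.4, 0.8))
    expect_true(all(highly_expressed_genes(ex, "cancer", f + 0.1) %in%
                      highly_expressed_genes(ex, "cancer", f)))
})

test_that("ligand-receptor edges are the prior pairs with both endpoints highly expressed", {
  db <- generate_prior_db(6, 6, 3, 6, edge_density = 0.5, seed = 3)
  expect_equal(nrow(build_lr_edges(character(), db$universe, db)), 0)
  sat <- build_lr_edges(unique(db$lr_pairs$ligand),
                        unique(db$lr_pairs$receptor), db)
  expect_equal(sat, db$lr_pairs, ignore_attr = TRUE)
})

test_that("TF activation p-values are exact hypergeometric tails", {
  # worked 2x2 example: targets {g1,g2,g3}, HE {g1,g2}, background 10
  bg <- paste0("g", 1:10)
  db <- prior_db(data.frame(ligand = "L", receptor = "R"),
                 data.frame(receptor = "R", tf = "TFa"),
                 data.frame(tf = "TFa", target = c("g1", "g2", "g3")),
                 universe = c("L", "R", "TFa", bg))
  tab <- activated_tfs(c("g1", "g2"), db, bg, mt_correction = "none")
  expect_equal(tab$fisher_p, 3 / 45, tolerance = 1e-12)
  expect_equal(tab$fisher_p,
               fisher.test(matrix(c(2, 1, 0, 7), 2),
                           alternative = "greater")$p.value,
               tolerance = 1e-12)
  # TF with no annotated target in background: p = 1, never retained
  db2 <- prior_db(data.frame(ligand = "L", receptor = "R"),
                  data.frame(receptor = "R", tf = "TFb"),
                  data.frame(tf = "TFb", target = "far_away"),
                  universe = c("L", "R", "TFb", "far_away", bg))
  tab2 <- activated_tfs(c("g1", "g2"), db2, bg)
  expect_equal(tab2$fisher_p, 1)
  expect_false(any(tab2$retained))
  expect_error(activated_tfs(character(), db, character()), "background")
})

test_that("Fisher p equals explicit enumeration on random instances (bg <= 100)", {
  set.seed(101)
  for (i in 1:60) {
    N <- sample(10:100, 1)
    bg <- paste0("g", seq_len(N))
    K <- sample(1:min(N, 20), 1)
    n_he <- sample(1:N, 1)
    targ <- sample(bg, K); he <- sample(bg, n_he)
    db <- prior_db(data.frame(ligand = "L", receptor = "R"),
                   data.frame(receptor = "R", tf = "T1"),
                   data.frame(tf = "T1", target = targ),
                   universe = c("L", "R", "T1", bg))
    p <- activated_tfs(he, db, bg, mt_correction = "none")$fisher_p
    ov <- length(intersect(targ, he))
    expect_equal(p, oracle_fisher_tail(ov, K, N, n_he), tolerance = 1e-9)
  }
})

test_that("LASSO recovers a noiseless planted slope and full shrinkage removes all edges", {
  set.seed(55)
  n <- 300
  tf_expr <- rnorm(n, 2, 1)
  target <- 2.0 * tf_expr            # noiseless slope 2
  m <- rbind(TFX = tf_expr, TGX = target,
             filler = rnorm(n, 1, 0.2))
  colnames(m) <- paste0("c", 1:n)
  ex <- toy_expr(round(abs(m) * 0 + 1))  # counts unused by the lasso stage
  ex$cell_meta$assigned_type <- rep("cancer", n)
  ex$normalized <- Matrix::Matrix(m, sparse = TRUE)
  db <- prior_db(data.frame(ligand = "L", receptor = "R"),
                 data.frame(receptor = "R", tf = "TFX"),
                 data.frame(tf = "TFX", target = "TGX"),
                 universe = c("L", "R", "TFX", "TGX", "filler"))
  ed <- tf_target_edges(ex, "cancer", "TFX", "TGX", db, seed = 1)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$tf, "TFX"); expect_equal(ed$target, "TGX")
  refit <- coef(lm(target ~ tf_expr))[2]   # refit-on-support oracle
  expect_lt(abs(refit - 2.0), 0.05)
  expect_lt(abs(ed$lasso_coef - 2.0), 0.1)
  # forced lambda -> infinity: no edges retained
  ed_inf <- tf_target_edges(ex, "cancer", "TFX", "TGX", db, seed = 1,
                            lambda = 1e6)
  expect_equal(nrow(ed_inf), 0)
  expect_error(tf_target_edges(ex, "cancer", "TFX", "TGX", db,
                               cv_folds = 200), "fewer folds")
})

test_that("a pure-noise target is retained in at most a small fraction of seeds", {
  set.seed(77)
  n <- 500
  hits <- 0; reps <- 40
  for (r in 1:reps) {
    tf_expr <- rnorm(n)
    target <- rnorm(n)
    X <- cbind(TFX = tf_expr)
    b <- mlsignet:::lasso_cv_fit(X, target, lambda_rule = "cv_1se",
                                 cv_folds = 10)
    hits <- hits + (b != 0)
  }
  expect_lte(hits / reps, 0.15)
})

test_that("receptor-TF linkage is prior membership with both endpoints retained", {
  db <- generate_prior_db(4, 4, 4, 8, edge_density = 1, seed = 9)
  lr <- db$lr_pairs[1:2, ]
  expect_equal(nrow(link_receptor_tf(lr, character(), db)), 0)
  all_link <- link_receptor_tf(db$lr_pairs, unique(db$rec_tf$tf), db)
  expect_equal(all_link, db$rec_tf, ignore_attr = TRUE)
})

test_that("assembly prunes everything not on a complete 4-path", {
  lr <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R1"))
  rt <- data.frame(receptor = "R1", tf = "F1")
  tt <- data.frame(tf = "F1", target = "T1", lasso_coef = 0.5)
  net <- assemble_network(lr, rt, tt)
  expect_setequal(net$layers$ligands, c("L1", "L2"))
  # dangling ligand without receptor edge is absent
  lr2 <- rbind(lr, data.frame(ligand = "L3", receptor = "R9"))
  net2 <- assemble_network(lr2, rt, tt)
  expect_false("L3" %in% net2$layers$ligands)
  expect_false("R9" %in% net2$layers$receptors)
  # chain missing its TF->target edge vanishes entirely
  net3 <- assemble_network(lr, rt, tt[0, ])
  expect_equal(nrow(net3$edges), 0)
  expect_equal(lengths(net3$layers), c(ligands = 0L, receptors = 0L,
                                       tfs = 0L, targets = 0L))
})

test_that("pruning equals the brute-force keep-nodes-on-any-4-path oracle and is idempotent", {
  set.seed(202)
  for (i in 1:60) {
    e <- random_layered_edges()
    net <- assemble_network(e$lr, e$rt, e$tt)
    q <- oracle_quadruples(e$lr, e$rt, e$tt)
    expect_setequal(net$layers$ligands, unique(q$ligand))
    expect_setequal(net$layers$receptors, unique(q$receptor))
    expect_setequal(net$layers$tfs, unique(q$tf))
    expect_setequal(net$layers$targets, unique(q$target))
    # idempotence: re-assembling the pruned edges changes nothing
    ee <- net$edges
    net2 <- assemble_network(
      setNames(ee[ee$edge_type == "LR", 1:2], c("ligand", "receptor")),
      setNames(ee[ee$edge_type == "RTF", 1:2], c("receptor", "tf")),
      setNames(ee[ee$edge_type == "TFT", 1:2], c("tf", "target")))
    expect_equal(net2$layers, net$layers)
  }
})

test_that("planted cascades are recovered on synthetic grade-IV data", {
  fx <- pipeline_fixture(); nets <- network_fixture()
  pc <- fx$sim$truth$planted_cascades
  q4 <- enumerate_quadruples(nets$net4)
  # L-R recall on active cascades and precision of recovered LR edges
  lr <- nets$net4$edges[nets$net4$edges$edge_type == "LR", ]
  planted_lr <- unique(paste(pc$ligand, pc$receptor))
  expect_true(all(planted_lr %in% paste(lr$src, lr$dst)))
  expect_gte(mean(paste(lr$src, lr$dst) %in% planted_lr), 0.8)
  # R->TF edges cover the planted axes
  rtf <- nets$net4$edges[nets$net4$edges$edge_type == "RTF", ]
  expect_true(all(unique(paste(pc$receptor, pc$tf)) %in%
                    paste(rtf$src, rtf$dst)))
  # every retained TF->target coefficient is nonzero
  tft <- nets$net4$edges[nets$net4$edges$edge_type == "TFT", ]
  expect_true(all(tft$statistic != 0))
})
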