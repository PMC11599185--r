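chain_net <- function() assemble_network(
  data.frame(ligand = "L1", receptor = "R1"),
  data.frame(receptor = "R1", tf = "F1"),
  data.frame(tf = "F1", target = c("T1", "T2")))

manual_mlnet <- function(layers, edges) {
  structure(list(layers = layers, edges = edges, grade = "NA",
                 sender_type = "s", receiver_type = "r"), class = "mlnet")
}

test_that("differential network is empty on identical inputs and pinpoints added edges", {
  a <- chain_net()
  d <- differential_network(a, a)
  expect_equal(nrow(d$edges_only_a), 0)
  expect_equal(nrow(d$edges_only_b), 0)
  expect_length(d$nodes_only_a, 0)
  b <- assemble_network(
    data.frame(ligand = "L1", receptor = "R1"),
    data.frame(receptor = "R1", tf = "F1"),
    data.frame(tf = "F1", target = c("T1", "T2", "T3")))
  d2 <- differential_network(a, b)
  expect_equal(nrow(d2$edges_only_b), 1)
  expect_equal(d2$edges_only_b$dst, "T3")
  expect_equal(d2$nodes_only_b, "T3")
  # anti-symmetry under argument swap
  d3 <- differential_network(b, a)
  expect_equal(d3$edges_only_a[, 1:3], d2$edges_only_b[, 1:3],
               ignore_attr = TRUE)
})

test_that("the differential network contains the recovered IV-only cascade edges", {
  nets <- network_fixture()
  d <- differential_network(nets$net3, nets$net4)
  q_iv <- enumerate_quadruples(nets$net4)
  gs <- grade_specific(enumerate_quadruples(nets$net3), q_iv)
  only_iv_nodes <- unique(unlist(gs$only_b[, 1:4]))
  # every node exclusive to grade IV appears in the node difference
  expect_true(all(setdiff(only_iv_nodes,
                          unlist(nets$net3$layers)) %in% d$nodes_only_b))
})

test_that("closed-form centralities on tiny graphs", {
  # single edge u -> v with alpha = 0.1: katz (1, 1.1)
  single <- manual_mlnet(
    list(ligands = "u", receptors = "v", tfs = character(),
         targets = character()),
    data.frame(src = "u", dst = "v", edge_type = "LR", statistic = NA))
  tab <- centralities(single, katz_alpha = 0.1)
  expect_equal(tab$katz[tab$node == "u"], 1)
  expect_equal(tab$katz[tab$node == "v"], 1.1)
  # 2-cycle: pagerank (0.5, 0.5) at any damping
  cyc <- igraph::graph_from_literal(a -+ b, b -+ a)
  igraph::V(cyc)$layer <- "x"
  tabc <- centralities(cyc, katz_alpha = 0.5, pagerank_damping = 0.7)
  expect_equal(tabc$pagerank, c(0.5, 0.5))
  # directed 3-path: middle node carries the single pair
  path3 <- manual_mlnet(
    list(ligands = "a", receptors = "b", tfs = "c", targets = character()),
    data.frame(src = c("a", "b"), dst = c("b", "c"),
               edge_type = c("LR", "RTF"), statistic = NA))
  tabp <- centralities(path3, normalized_betweenness = FALSE)
  expect_equal(tabp$betweenness[tabp$node == "b"], 1)
  expect_equal(tabp$betweenness[tabp$node %in% c("a", "c")], c(0, 0))
})

test_that("katz diverges with an explicit error at/above the spectral bound", {
  cyc <- igraph::graph_from_literal(a -+ b, b -+ a)  # spectral radius 1
  igraph::V(cyc)$layer <- "x"
  expect_error(centralities(cyc, katz_alpha = 1), "diverges")
})

test_that("centralities match brute-force oracles on random digraphs (<= 12 nodes)", {
  set.seed(404)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    A <- matrix(rbinom(n * n, 1, 0.3), n, n); diag(A) <- 0
    g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
    igraph::V(g)$name <- paste0("n", 1:n)
    igraph::V(g)$layer <- "x"
    sr <- max(Mod(eigen(A, only.values = TRUE)$values))
    alpha <- if (sr > 0) 0.8 / sr else 0.2
    tab <- centralities(g, katz_alpha = alpha,
                        normalized_betweenness = FALSE)
    expect_equal(tab$katz, oracle_katz(A, alpha, n_terms = 5000),
                 tolerance = 1e-8)
    expect_equal(tab$pagerank, oracle_pagerank(A), tolerance = 1e-8)
    expect_equal(tab$betweenness, oracle_betweenness(A), tolerance = 1e-9)
  }
})

test_that("Welch comparison handles identical, degenerate and planted cases", {
  tab <- data.frame(katz = c(1, 2, 3, 4), pagerank = c(1, 2, 3, 4),
                    betweenness = c(1, 2, 3, 4))
  same <- compare_centralities(tab, tab, "katz")
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  const <- data.frame(katz = rep(2, 4))
  const2 <- data.frame(katz = rep(5, 4))
  deg <- compare_centralities(const, const2, "katz")
  expect_false(deg$defined); expect_true(is.na(deg$p))
  nets <- network_fixture()
  cmp <- compare_all_centralities(nets$net3, nets$net4)
  expect_equal(nrow(cmp), 3)
  expect_true(all(cmp$p_adj >= cmp$p - 1e-12, na.rm = TRUE))
})

test_that("degree distribution satisfies the handshake identity", {
  empty <- manual_mlnet(list(ligands = character(), receptors = character(),
                             tfs = character(), targets = character()),
                        data.frame(src = character(), dst = character(),
                                   edge_type = character(),
                                   statistic = numeric()))
  expect_equal(nrow(degree_distribution(empty)), 0)
  # star with k leaves: one hub of degree k, k leaves of degree 1
  k <- 5
  star <- manual_mlnet(
    list(ligands = "hub", receptors = paste0("leaf", 1:k),
         tfs = character(), targets = character()),
    data.frame(src = "hub", dst = paste0("leaf", 1:k),
               edge_type = "LR", statistic = NA))
  dd <- degree_distribution(star)
  expect_equal(dd$n_nodes[dd$degree == 1], k)
  expect_equal(dd$n_nodes[dd$degree == k], 1)
  # random pruned network: sum(count) = |V|, mean degree = 2|E|/|V|
  nets <- network_fixture()
  dd4 <- degree_distribution(nets$net4)
  n_nodes <- sum(lengths(nets$net4$layers))
  expect_equal(sum(dd4$n_nodes), n_nodes)
  expect_equal(sum(dd4$degree * dd4$n_nodes) / n_nodes,
               2 * nrow(nets$net4$edges) / n_nodes)
})
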