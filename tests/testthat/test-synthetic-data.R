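test_that("full-density prior databases have complete bipartite relation counts", {
  db1 <- generate_prior_db(1, 1, 1, 1, edge_density = 1, seed = 5)
  expect_equal(nrow(db1$lr_pairs), 1)
  expect_equal(nrow(db1$rec_tf), 1)
  expect_equal(nrow(db1$tf_target), 1)
  db2 <- generate_prior_db(2, 2, 2, 2, edge_density = 1, seed = 5)
  expect_equal(nrow(db2$lr_pairs), 4)
  expect_equal(nrow(db2$rec_tf), 4)
  expect_equal(nrow(db2$tf_target), 4)
})

test_that("sparse prior relation counts fall in the binomial 99% envelope", {
  db <- generate_prior_db(50, 30, 40, 150, edge_density = 0.1, seed = 11)
  env <- function(n_pairs) qbinom(c(0.005, 0.995), n_pairs, 0.1)
  e_lr <- env(50 * 30); e_rt <- env(30 * 40); e_tt <- env(40 * 150)
  expect_gte(nrow(db$lr_pairs), e_lr[1]); expect_lte(nrow(db$lr_pairs), e_lr[2])
  expect_gte(nrow(db$rec_tf), e_rt[1]); expect_lte(nrow(db$rec_tf), e_rt[2])
  # TF-target floor can only add relations
  expect_gte(nrow(db$tf_target), e_tt[1])
  expect_lte(nrow(db$tf_target), e_tt[2] + 40)
  # guaranteed-nonempty rule: every TF annotated
  expect_setequal(unique(db$tf_target$tf), sprintf("TF_%03d", 1:40))
})

test_that("generators are seed-deterministic and seed-sensitive", {
  a <- generate_prior_db(10, 8, 8, 30, edge_density = 0.2, seed = 3)
  b <- generate_prior_db(10, 8, 8, 30, edge_density = 0.2, seed = 3)
  expect_identical(a, b)
  c <- generate_prior_db(10, 8, 8, 30, edge_density = 0.2, seed = 4)
  expect_false(identical(a$lr_pairs, c$lr_pairs))

  s1 <- simulate_study(seed = 9, cells_per_type = c(cancer = 60, immune = 30,
                                                    bystander = 20))
  s2 <- simulate_study(seed = 9, cells_per_type = c(cancer = 60, immune = 30,
                                                    bystander = 20))
  expect_identical(as.matrix(s1$grade_IV$counts), as.matrix(s2$grade_IV$counts))
  expect_identical(s1$truth$planted_cascades, s2$truth$planted_cascades)
})

test_that("noiseless limit makes target counts a deterministic function of TF activity", {
  db <- generate_prior_db(5, 5, 5, 20, edge_density = 0.3, seed = 2)
  pl <- plant_cascades(db, n_cascades = 1, n_iv_only = 0, seed = 2)
  ex <- generate_expression(pl$prior, pl$cascades,
                            cells_per_type = c(cancer = 100, immune = 30,
                                               bystander = 10),
                            noise_dispersion = 0, active_boost = 1e5,
                            pct_mito_outliers = 0, seed = 2)
  truth <- ex$truth
  ax <- truth$planted_cascades[1, ]
  recv <- names(truth$cell_type_of)[truth$cell_type_of == "cancer" &
                                      grepl("^IV", names(truth$cell_type_of))]
  cnt <- as.matrix(ex$grade_IV$counts)
  eta <- truth$active_tf_activity$IV[recv, 1]
  # counts are an exact deterministic function of the latent activity
  expect_identical(cnt[ax$tf, recv],
                   round(0.05 * 1e5 * exp(eta))[recv])
  r <- cor(log(cnt[ax$tf, recv]), log(cnt[ax$target, recv]))
  expect_gt(r, 0.9999)
})

test_that("the planted QC-failure fraction is honoured exactly", {
  db <- generate_prior_db(5, 5, 5, 20, edge_density = 0.3, seed = 6)
  pl <- plant_cascades(db, n_cascades = 1, n_iv_only = 0, seed = 6)
  ex <- generate_expression(pl$prior, pl$cascades,
                            cells_per_type = c(cancer = 700, immune = 200,
                                               bystander = 100),
                            pct_mito_outliers = 0.1, seed = 6)
  expect_equal(sum(grepl("^III", ex$truth$planted_qc_failures)), 100)
  expect_equal(sum(grepl("^IV", ex$truth$planted_qc_failures)), 100)
  # and every cell has exactly one true type
  expect_setequal(names(ex$truth$cell_type_of),
                  c(ex$grade_III$cell_ids, ex$grade_IV$cell_ids))
})

test_that("planted TF-target pairs out-correlate random TF-gene pairs", {
  fx <- pipeline_fixture()
  norm <- fx$g4$expr$normalized
  recv <- fx$g4$expr$cell_ids[fx$g4$expr$cell_meta$assigned_type == "cancer"]
  pc <- fx$sim$truth$planted_cascades
  pc <- pc[pc$tf %in% rownames(norm) & pc$target %in% rownames(norm), ]
  planted_r <- abs(mapply(function(tf, tg)
    cor(norm[tf, recv], norm[tg, recv]), pc$tf, pc$target))
  set.seed(42)
  tfs <- sample(pc$tf, 200, replace = TRUE)
  genes <- sample(setdiff(rownames(norm), unique(pc$target)), 200,
                  replace = TRUE)
  random_r <- abs(mapply(function(tf, tg)
    cor(norm[tf, recv], norm[tg, recv]), tfs, genes))
  expect_gt(median(planted_r), quantile(random_r, 0.95))
})

test_that("cascade genes absent from the prior are a truth-consistency error", {
  db <- generate_prior_db(3, 3, 3, 5, edge_density = 1, seed = 1)
  bad <- data.frame(cascade = 1, ligand = "LG_999", receptor = "RC_001",
                    tf = "TF_001", target = "TG_001", slope = 1,
                    grade_tag = "both")
  expect_error(generate_expression(db, bad), "truth-consistency")
})

test_that("survival cohort honours censoring and the null model", {
  d0 <- generate_survival_cohort(100, censoring_rate = 0, seed = 2)
  expect_true(all(d0$event == 1))
  expect_true(all(d0$time_days > 0))
  # standardized expression columns
  expect_equal(unname(colMeans(as.matrix(d0[, 4:7]))), rep(0, 4),
               tolerance = 1e-10)
  expect_equal(unname(apply(as.matrix(d0[, 4:7]), 2, sd)), rep(1, 4),
               tolerance = 1e-10)

  d <- generate_survival_cohort(2000, censoring_rate = 0.3, seed = 3)
  expect_equal(mean(d$event == 0), 0.3, tolerance = 0.05)

  # all-zero betas: any median split of the score behaves as a null
  reps <- sapply(1:60, function(s) {
    dn <- generate_survival_cohort(60,
      betas = c(A = 0, B = 0, C = 0, D = 0), censoring_rate = 0.2, seed = s)
    sc <- rnorm(60)
    km_stratify(dn, sc)$p
  })
  expect_lte(mean(reps < 0.05), 0.15)
  expect_error(generate_survival_cohort(
    100, betas = c(A = 0, B = 0, C = 0, D = 0), censoring_rate = 1),
    "no events to model")
})

test_that("expression, prior and survival tables round-trip through their writers", {
  dir <- withr::local_tempdir()
  db <- generate_prior_db(4, 4, 4, 8, edge_density = 0.5, seed = 13)
  write_prior_db(db, file.path(dir, "prior"))
  db2 <- read_prior_db(file.path(dir, "prior"))
  expect_equal(db$lr_pairs, db2$lr_pairs)
  expect_equal(db$tf_target[order(db$tf_target$tf, db$tf_target$target), ],
               db2$tf_target[order(db2$tf_target$tf, db2$tf_target$target), ],
               ignore_attr = TRUE)
  expect_setequal(db$universe, db2$universe)

  pl <- plant_cascades(db, n_cascades = 1, n_iv_only = 0, seed = 13)
  ex <- generate_expression(pl$prior, pl$cascades,
                            cells_per_type = c(cancer = 30, immune = 20,
                                               bystander = 10), seed = 13)
  write_expr_mtx(ex$grade_III, file.path(dir, "expr"))
  back <- read_expr_mtx(file.path(dir, "expr"))
  expect_identical(as.matrix(back$counts), as.matrix(ex$grade_III$counts))
  expect_equal(back$cell_meta$grade, ex$grade_III$cell_meta$grade)

  sv <- generate_survival_cohort(50, censoring_rate = 0.2, seed = 13)
  write_survival_tsv(sv, file.path(dir, "surv.tsv"))
  sv2 <- read_survival_tsv(file.path(dir, "surv.tsv"))
  expect_equal(sv$time_days, sv2$time_days)
  expect_equal(sv$event, sv2$event)
})
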