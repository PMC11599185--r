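#' Prior signaling knowledge base
#'
#' A `prior_db` bundles the three directed relation tables the multilayer
#' network construction relies on: ligand-receptor pairs (intercellular),
#' receptor-TF links and TF-target annotations (intracellular), over a
#' common gene universe. Real analyses load these from curated databases;
#' the synthetic generator fabricates them with role-prefixed gene names.
#'
#' @param lr_pairs two-column data.frame (ligand, receptor).
#' @param rec_tf two-column data.frame (receptor, tf).
#' @param tf_target two-column data.frame (tf, target).
#' @param universe optional character vector of all known gene ids;
#'   defaults to the union of the genes in the three tables.
#' @return An object of class `prior_db`.
#' @export
prior_db <- function(lr_pairs, rec_tf, tf_target, universe = NULL) {
  lr_pairs <- as.data.frame(lr_pairs)[, 1:2]
  rec_tf <- as.data.frame(rec_tf)[, 1:2]
  tf_target <- as.data.frame(tf_target)[, 1:2]
  names(lr_pairs) <- c("ligand", "receptor")
  names(rec_tf) <- c("receptor", "tf")
  names(tf_target) <- c("tf", "target")
  members <- unique(c(
    lr_pairs$ligand, lr_pairs$receptor, rec_tf$receptor, rec_tf$tf,
    tf_target$tf, tf_target$target))
  if (is.null(universe)) universe <- members
  if (!all(members %in% universe))
    stopf("prior_db: %d relation members missing from the universe",
          sum(!members %in% universe))
  tfs <- unique(c(rec_tf$tf, tf_target$tf))
  no_target <- setdiff(tfs, tf_target$tf)
  if (length(no_target))
    stopf("prior_db: TFs without any annotated target: %s",
          paste(head(no_target, 5), collapse = ", "))
  structure(list(lr_pairs = lr_pairs, rec_tf = rec_tf,
                 tf_target = tf_target, universe = universe),
            class = "prior_db")
}

#' @export
print.prior_db <- function(x, ...) {
  cat("Prior signaling database\n")
  cat(sprintf("  %d ligand-receptor pairs, %d receptor-TF links, %d TF-target annotations\n",
              nrow(x$lr_pairs), nrow(x$rec_tf), nrow(x$tf_target)))
  cat(sprintf("  universe: %d genes\n", length(x$universe)))
  invisible(x)
}

#' Generate a synthetic prior signaling database
#'
#' Samples three Bernoulli(\code{edge_density}) bipartite relation tables
#' over disjoint, role-prefixed gene name spaces (`LG_`, `RC_`, `TF_`,
#' `TG_`). Every TF is guaranteed at least one annotated target: a TF left
#' target-less by the density draw receives one uniformly chosen target, so
#' an invalid database is never returned.
#'
#' @param n_ligands,n_receptors,n_tfs,n_targets layer sizes (counts >= 1).
#' @param edge_density per layer-pair relation probability in (0, 1].
#'   The default 0.02 mirrors the sparsity of curated ligand-receptor and
#'   TF-target resources.
#' @param seed integer seed; identical arguments reproduce the database.
#' @return A [prior_db] object.
#' @examples
#' db <- generate_prior_db(5, 4, 4, 10, edge_density = 0.5, seed = 1)
#' db
#' @export
generate_prior_db <- function(n_ligands, n_receptors, n_tfs, n_targets,
                              edge_density = 0.02, seed = 1) {
  for (n in c(n_ligands, n_receptors, n_tfs, n_targets))
    if (!is_count(n)) stopf("layer sizes must be counts >= 1")
  if (!is_fraction(edge_density) || edge_density <= 0)
    stopf("edge_density must be in (0, 1]")
  set.seed(derive_seed(seed, "prior"))
  lg <- sprintf("LG_%03d", seq_len(n_ligands))
  rc <- sprintf("RC_%03d", seq_len(n_receptors))
  tf <- sprintf("TF_%03d", seq_len(n_tfs))
  tg <- sprintf("TG_%03d", seq_len(n_targets))

  sample_rel <- function(a, b) {
    keep <- which(runif(length(a) * length(b)) < edge_density)
    data.frame(a = rep(a, times = length(b))[keep],
               b = rep(b, each = length(a))[keep],
               stringsAsFactors = FALSE)
  }
  lr <- sample_rel(lg, rc); names(lr) <- c("ligand", "receptor")
  rt <- sample_rel(rc, tf); names(rt) <- c("receptor", "tf")
  tt <- sample_rel(tf, tg); names(tt) <- c("tf", "target")
  # guaranteed-nonempty rule: every TF keeps >= 1 annotated target
  missing_tf <- setdiff(tf, tt$tf)
  if (length(missing_tf))
    tt <- rbind(tt, data.frame(tf = missing_tf,
                               target = sample(tg, length(missing_tf),
                                               replace = TRUE)))
  tt <- tt[order(tt$tf, tt$target), ]
  rownames(tt) <- NULL
  prior_db(lr, rt, tt, universe = c(lg, rc, tf, tg))
}

#' Plant active signaling cascades into a prior database
#'
#' Selects `n_cascades` disjoint (ligand, receptor, TF) axes, attaches
#' `targets_per_tf` regulated targets to each TF, and inserts any missing
#' chain edges into the prior so the planted cascades are fully represented.
#' The last `n_iv_only` cascades are tagged as active in the grade-IV
#' condition only.
#'
#' @param prior a [prior_db].
#' @param n_cascades number of planted cascade axes.
#' @param n_iv_only how many of them are grade-IV-specific.
#' @param targets_per_tf coupled targets per planted TF (an active TF drives
#'   a regulon, not a single gene; several targets are also what makes the
#'   Fisher activation test identifiable).
#' @param seed integer seed.
#' @return List with `prior` (augmented [prior_db]) and `cascades`, a
#'   data.frame of planted quadruples (cascade, ligand, receptor, tf,
#'   target, slope, grade_tag).
#' @export
plant_cascades <- function(prior, n_cascades = 10, n_iv_only = 3,
                           targets_per_tf = 8, seed = 1) {
  stopifnot(inherits(prior, "prior_db"))
  if (n_iv_only > n_cascades) stopf("n_iv_only cannot exceed n_cascades")
  lg <- grep("^LG_", prior$universe, value = TRUE)
  rc <- grep("^RC_", prior$universe, value = TRUE)
  tf <- grep("^TF_", prior$universe, value = TRUE)
  tg <- grep("^TG_", prior$universe, value = TRUE)
  if (min(length(lg), length(rc), length(tf)) < n_cascades)
    stopf("prior too small for %d disjoint cascades", n_cascades)
  set.seed(derive_seed(seed, "cascades"))
  L <- sample(lg, n_cascades); R <- sample(rc, n_cascades)
  TFs <- sample(tf, n_cascades)
  lr <- prior$lr_pairs; rt <- prior$rec_tf; tt <- prior$tf_target
  rows <- vector("list", n_cascades)
  for (i in seq_len(n_cascades)) {
    if (!any(lr$ligand == L[i] & lr$receptor == R[i]))
      lr <- rbind(lr, data.frame(ligand = L[i], receptor = R[i]))
    if (!any(rt$receptor == R[i] & rt$tf == TFs[i]))
      rt <- rbind(rt, data.frame(receptor = R[i], tf = TFs[i]))
    have <- tt$target[tt$tf == TFs[i]]
    need <- targets_per_tf - length(have)
    tgt <- have
    if (need > 0) {
      extra <- sample(setdiff(tg, have), need)
      tt <- rbind(tt, data.frame(tf = TFs[i], target = extra))
      tgt <- c(have, extra)
    } else {
      tgt <- sample(have, targets_per_tf)
    }
    rows[[i]] <- data.frame(
      cascade = i, ligand = L[i], receptor = R[i], tf = TFs[i],
      target = tgt,
      slope = runif(length(tgt), 0.7, 1.5),
      grade_tag = if (i > n_cascades - n_iv_only) "grade_IV_only" else "both",
      stringsAsFactors = FALSE)
  }
  list(prior = prior_db(lr, rt, tt, universe = prior$universe),
       cascades = do.call(rbind, rows))
}

#' Write / read a prior database as three two-column TSVs
#'
#' Files `lr_pairs.tsv`, `rec_tf.tsv`, `tf_target.tsv` (header row each)
#' are written under `dir`.
#'
#' @param prior a [prior_db].
#' @param dir directory (created if absent).
#' @return `write_prior_db` returns `dir` invisibly; `read_prior_db`
#'   returns a [prior_db].
#' @export
write_prior_db <- function(prior, dir) {
  stopifnot(inherits(prior, "prior_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(prior$lr_pairs, file.path(dir, "lr_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(prior$rec_tf, file.path(dir, "rec_tf.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(prior$tf_target, file.path(dir, "tf_target.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(prior$universe, file.path(dir, "universe.txt"))
  invisible(dir)
}

#' @rdname write_prior_db
#' @export
read_prior_db <- function(dir) {
  rd <- function(f) read.delim(file.path(dir, f), stringsAsFactors = FALSE)
  uni_file <- file.path(dir, "universe.txt")
  uni <- if (file.exists(uni_file)) readLines(uni_file) else NULL
  prior_db(rd("lr_pairs.tsv"), rd("rec_tf.tsv"), rd("tf_target.tsv"),
           universe = uni)
}
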