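#' Simulate two-grade single-cell expression with planted cascades
#'
#' Generates genes x cells count matrices for a grade-III and a grade-IV
#' condition over a shared gene universe: the prior-database genes, one
#' marker block per cell type (`MK_<type>_k`), housekeeping genes (`HK_`),
#' mitochondrial (`MT-`) and spike-in (`ERCC-`) genes. Counts follow a
#' gamma-Poisson (negative binomial) model; `noise_dispersion = 0` is the
#' deterministic limit (counts are the rounded means), used by the
#' noiseless identifiability checks.
#'
#' Planted cascades are "switched on" by multiplying the negative-binomial
#' mean of their genes by `active_boost` in the relevant population
#' (ligands in sender cells, receptor/TF/targets in receiver cells).
#' Each receiver cell carries a latent per-cascade TF activity
#' eta ~ N(0, activity_sd^2); the TF's log-mean is shifted by eta and each
#' coupled target's log-mean by `slope * tf_target_slope * eta`, which is
#' what makes the LASSO stage identifiable. Cascades tagged
#' `grade_IV_only` receive no boost in the grade-III condition (the genes
#' stay in the matrix at baseline, so both grades share one gene list).
#' A fixed fraction of cells receives inflated mitochondrial/ERCC counts
#' to exercise the QC stage; their ids are recorded in the truth.
#'
#' @param prior a [prior_db] (typically the augmented one from
#'   [plant_cascades()]).
#' @param cascades planted-cascade data.frame from [plant_cascades()].
#' @param cells_per_type named counts per type and grade; must include
#'   `cancer` (receiver) and `immune` (sender).
#' @param baseline_mean NB mean of an inactive gene (default 0.05: a
#'   detection fraction of about 5 percent, well below the
#'   highly-expressed threshold).
#' @param active_boost multiplicative mean shift of active-cascade genes
#'   (> 1; default 20 lifts detection to roughly 60 percent).
#' @param tf_target_slope global multiplier on the per-target activity
#'   slopes (log-mean scale).
#' @param activity_sd standard deviation of the latent TF activity.
#' @param noise_dispersion NB dispersion (variance = mu + dispersion*mu^2);
#'   0 gives deterministic rounded means.
#' @param pct_mito_outliers fraction of cells per grade planted as QC
#'   failures (inflated mito/ERCC counts).
#' @param n_markers_per_type,marker_mean marker-block shape.
#' @param n_housekeeping,housekeeping_mean always-on genes giving cells a
#'   realistic library size.
#' @param n_mito,mito_mean,n_ercc,ercc_mean,outlier_boost QC-gene shape.
#' @param seed integer seed; all randomness derives from it.
#' @return List with `grade_III`, `grade_IV` ([expr_matrix] each) and
#'   `truth` (class `synthetic_truth`): `planted_cascades`,
#'   `cell_type_of` (named vector over all cells of both grades),
#'   `active_tf_activity` (per grade: receiver cells x cascades matrix),
#'   `planted_qc_failures`, `reference_markers`.
#' @export
generate_expression <- function(prior, cascades,
                                cells_per_type = c(cancer = 500, immune = 200,
                                                   bystander = 100),
                                baseline_mean = 0.05, active_boost = 20,
                                tf_target_slope = 1, activity_sd = 1,
                                noise_dispersion = 0.3,
                                pct_mito_outliers = 0.05,
                                n_markers_per_type = 5, marker_mean = 2,
                                n_housekeeping = 80, housekeeping_mean = 3,
                                n_mito = 10, mito_mean = 1,
                                n_ercc = 5, ercc_mean = 0.4,
                                outlier_boost = 60, seed = 1) {
  stopifnot(inherits(prior, "prior_db"))
  if (!all(c("cancer", "immune") %in% names(cells_per_type)))
    stopf("cells_per_type must include 'cancer' and 'immune'")
  if (active_boost <= 1) stopf("active_boost must be > 1")
  if (!is_fraction(pct_mito_outliers)) stopf("pct_mito_outliers in [0,1]")
  casc_genes <- unique(c(cascades$ligand, cascades$receptor, cascades$tf,
                         cascades$target))
  if (!all(casc_genes %in% prior$universe))
    stopf("truth-consistency error: cascade genes absent from the prior: %s",
          paste(head(setdiff(casc_genes, prior$universe), 5), collapse = ", "))

  types <- names(cells_per_type)
  markers <- unlist(lapply(types, function(ty)
    sprintf("MK_%s_%d", ty, seq_len(n_markers_per_type))))
  marker_type <- rep(types, each = n_markers_per_type)
  hk <- sprintf("HK_%03d", seq_len(n_housekeeping))
  mt <- sprintf("MT-%d", seq_len(n_mito))
  ercc <- sprintf("ERCC-%05d", seq_len(n_ercc))
  genes <- c(prior$universe, markers, hk, mt, ercc)

  axes <- unique(cascades[, c("cascade", "ligand", "receptor", "tf",
                              "grade_tag")])
  one_grade <- function(grade) {
    set.seed(derive_seed(seed, "expr", grade))
    n_cells <- sum(cells_per_type)
    type_of <- rep(types, times = cells_per_type)
    cell_ids <- sprintf("%s_%s_%04d", grade, substr(type_of, 1, 2),
                        seq_len(n_cells))
    mu <- matrix(baseline_mean, length(genes), n_cells,
                 dimnames = list(genes, cell_ids))
    for (k in seq_along(markers))
      mu[markers[k], type_of == marker_type[k]] <- marker_mean
    mu[hk, ] <- housekeeping_mean
    mu[mt, ] <- mito_mean
    mu[ercc, ] <- ercc_mean

    recv <- which(type_of == "cancer")
    send <- which(type_of == "immune")
    active <- if (grade == "IV") axes$cascade else
      axes$cascade[axes$grade_tag == "both"]
    eta <- matrix(0, length(recv), nrow(axes),
                  dimnames = list(cell_ids[recv], paste0("cascade_", axes$cascade)))
    for (j in seq_len(nrow(axes))) {
      cid <- axes$cascade[j]
      if (!(cid %in% active)) next
      eta[, j] <- rnorm(length(recv), 0, activity_sd)
      mu[axes$ligand[j], send] <- baseline_mean * active_boost
      mu[axes$receptor[j], recv] <- baseline_mean * active_boost
      mu[axes$tf[j], recv] <- baseline_mean * active_boost * exp(eta[, j])
      ct <- cascades[cascades$cascade == cid, ]
      for (i in seq_len(nrow(ct)))
        mu[ct$target[i], recv] <- baseline_mean * active_boost *
          exp(ct$slope[i] * tf_target_slope * eta[, j])
    }

    n_out <- round(pct_mito_outliers * n_cells)
    outliers <- if (n_out > 0) sort(sample(n_cells, n_out)) else integer()
    if (length(outliers))
      mu[c(mt, ercc), outliers] <- mu[c(mt, ercc), outliers] * outlier_boost

    counts <- if (noise_dispersion > 0)
      matrix(rnbinom(length(mu), mu = mu, size = 1 / noise_dispersion),
             nrow(mu), ncol(mu), dimnames = dimnames(mu))
    else round(mu)
    meta <- data.frame(cell_id = cell_ids,
                       sample_id = paste0("S_", grade),
                       grade = grade, stringsAsFactors = FALSE)
    ex <- expr_matrix(Matrix::Matrix(counts, sparse = TRUE), cell_meta = meta)
    list(expr = ex, type_of = setNames(type_of, cell_ids), eta = eta,
         qc_fail = cell_ids[outliers])
  }

  g3 <- one_grade("III"); g4 <- one_grade("IV")
  truth <- structure(list(
    planted_cascades = cascades,
    cell_type_of = c(g3$type_of, g4$type_of),
    active_tf_activity = list(III = g3$eta, IV = g4$eta),
    planted_qc_failures = c(g3$qc_fail, g4$qc_fail),
    reference_markers = data.frame(gene = markers, cell_type = marker_type,
                                   stringsAsFactors = FALSE),
    planted_betas = NULL, censoring_rate = NA_real_),
    class = "synthetic_truth")
  list(grade_III = g3$expr, grade_IV = g4$expr, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth\n")
  cat(sprintf("  planted quadruples: %d over %d cascades (%d grade-IV-only)\n",
              nrow(x$planted_cascades),
              length(unique(x$planted_cascades$cascade)),
              length(unique(x$planted_cascades$cascade[
                x$planted_cascades$grade_tag == "grade_IV_only"]))))
  cat(sprintf("  cells: %d; planted QC failures: %d\n",
              length(x$cell_type_of), length(x$planted_qc_failures)))
  invisible(x)
}

#' One-call synthetic study
#'
#' Convenience wrapper reproducing the default study conditions: a prior
#' database, 10 planted cascade axes (3 grade-IV-only), and two-grade
#' expression matrices with 500 receiver cells per grade.
#'
#' @param seed integer seed.
#' @param n_cascades,n_iv_only planted cascade structure.
#' @param ... passed to [generate_expression()].
#' @return List with `prior`, `grade_III`, `grade_IV`, `truth`.
#' @export
simulate_study <- function(seed = 1, n_cascades = 10, n_iv_only = 3, ...) {
  db <- generate_prior_db(60, 40, 40, 200, edge_density = 0.02, seed = seed)
  pl <- plant_cascades(db, n_cascades = n_cascades, n_iv_only = n_iv_only,
                       seed = seed)
  ex <- generate_expression(pl$prior, pl$cascades, seed = seed, ...)
  c(list(prior = pl$prior), ex)
}
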