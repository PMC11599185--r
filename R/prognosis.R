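#' Univariate Cox screen of one gene
#'
#' Single-covariate Cox proportional-hazards fit (Efron tie handling)
#' with the Wald p-value. A constant covariate is degenerate and is
#' reported as beta 0, hazard ratio 1, p 1 with `flagged = TRUE`.
#'
#' @param data survival data.frame (`time_days`, `event`, gene columns).
#' @param gene covariate column name.
#' @return List `beta`, `hr`, `p`, `flagged`.
#' @export
univariate_cox <- function(data, gene) {
  if (!gene %in% names(data)) stopf("gene '%s' not in the table", gene)
  if (sum(data$event) < 2) stopf("need >= 2 events")
  x <- data[[gene]]
  if (sd(x) == 0)
    return(list(beta = 0, hr = 1, p = 1, flagged = TRUE))
  fit <- survival::coxph(
    survival::Surv(time_days, event) ~ x,
    data = data.frame(time_days = data$time_days, event = data$event, x = x),
    ties = "efron")
  s <- summary(fit)
  list(beta = unname(coef(fit)), hr = unname(exp(coef(fit))),
       p = unname(s$coefficients[1, "Pr(>|z|)"]),
       flagged = !is.finite(coef(fit)))
}

#' Multivariate Cox risk model over the cascade genes
#'
#' Joint Cox proportional-hazards fit with the Efron tie approximation,
#' returning the coefficients in the stated gene order as a `risk_model`.
#'
#' @param data survival data.frame (`time_days`, `event`, gene columns).
#' @param genes ordered covariate names (design must be full rank;
#'   collinear genes are reported).
#' @return Object of class `risk_model`: `genes`, `betas`, `fit` (the
#'   underlying `coxph` object).
#' @export
multivariate_cox <- function(data, genes) {
  miss <- setdiff(genes, names(data))
  if (length(miss)) stopf("missing gene column(s): %s",
                          paste(miss, collapse = ", "))
  if (sum(data$event) < 2) stopf("need >= 2 events")
  X <- as.matrix(data[, genes, drop = FALSE])
  qx <- qr(cbind(X))
  if (qx$rank < ncol(X)) {
    dep <- genes[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("design matrix rank deficient; collinear gene(s): %s",
          paste(dep, collapse = ", "))
  }
  df <- data.frame(time_days = data$time_days, event = data$event, X)
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(time_days, event) ~",
                            paste(genes, collapse = " + "))),
    data = df, ties = "efron",
    control = survival::coxph.control(iter.max = 50))
  if (any(!is.finite(coef(fit))))
    stopf("Cox fit did not converge (possible separation)")
  structure(list(genes = genes, betas = setNames(unname(coef(fit)), genes),
                 fit = fit),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Cox risk-score model: risk = sum(beta_g * expression_g)\n")
  for (g in x$genes)
    cat(sprintf("  %-8s beta = %+ .6f  (HR %.3f)\n", g, x$betas[g],
                exp(x$betas[g])))
  invisible(x)
}

#' Linear risk score
#'
#' `score_i = sum_g beta_g * expression_{i,g}` -- the fitted linear
#' combination, no intercept.
#'
#' @param model a `risk_model` (or list with `genes` and `betas`).
#' @param expr data.frame or matrix with the model genes as columns.
#' @return Numeric score per patient.
#' @export
risk_score <- function(model, expr) {
  miss <- setdiff(model$genes, colnames(expr))
  if (length(miss)) stopf("missing gene(s) in expression: %s",
                          paste(miss, collapse = ", "))
  drop(as.matrix(expr[, model$genes, drop = FALSE]) %*% model$betas)
}

#' @export
predict.risk_model <- function(object, newdata, ...) risk_score(object, newdata)

#' Kaplan-Meier stratification by risk score
#'
#' Splits patients into high/low risk at the median score (configurable
#' cut), estimates product-limit survival curves per stratum, and tests
#' the difference with the standard log-rank test.
#'
#' @param data survival data.frame (`time_days`, `event`).
#' @param scores per-patient risk scores (aligned with `data` rows).
#' @param cut `"median"` or a numeric cutoff.
#' @return List `fit` (survfit), `group` (factor low/high), `chisq`
#'   (log-rank statistic), `p`.
#' @export
km_stratify <- function(data, scores, cut = "median") {
  cutoff <- if (identical(cut, "median")) median(scores) else cut
  if (all(scores == scores[1]))
    stopf("all risk scores identical: cannot stratify")
  group <- factor(ifelse(scores > cutoff, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) == 0))
    stopf("a stratum is empty at the chosen cutoff")
  df <- data.frame(time_days = data$time_days, event = data$event,
                   group = group)
  fit <- survival::survfit(survival::Surv(time_days, event) ~ group,
                           data = df)
  lr <- survival::survdiff(survival::Surv(time_days, event) ~ group,
                           data = df)
  p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  list(fit = fit, group = group, chisq = unname(lr$chisq), p = p)
}

#' Time-dependent ROC AUC with censoring weights
#'
#' Cumulative-case / dynamic-control AUC at each horizon: cases are
#' patients with an observed event by the horizon, controls those still
#' at risk beyond it; case contributions are weighted by the inverse
#' Kaplan-Meier estimate of the censoring survival at their event time
#' (IPCW). Ties in the score count one half. Without censoring this
#' reduces to the ordinary binary AUC of "event by horizon" against the
#' score.
#'
#' @param data survival data.frame (`time_days`, `event`).
#' @param scores per-patient risk scores (higher = higher risk).
#' @param horizons evaluation times (same units as `time_days`).
#' @return data.frame (`horizon`, `auc`, `n_cases`, `n_controls`,
#'   `estimable`).
#' @export
time_dependent_auc <- function(data, scores, horizons) {
  time <- data$time_days; event <- data$event
  # KM of the censoring distribution G(t)
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(t) {
    s <- summary(cfit, times = t, extend = TRUE)$surv
    pmax(s, 1e-12)
  }
  rows <- lapply(horizons, function(tau) {
    cases <- which(time <= tau & event == 1)
    controls <- which(time > tau)
    if (!length(cases) || !length(controls) || tau > max(time))
      return(data.frame(horizon = tau, auc = NA_real_,
                        n_cases = length(cases),
                        n_controls = length(controls), estimable = FALSE))
    w <- 1 / G(pmin(time[cases], tau) - 1e-9)   # G(T_i^-)
    num <- 0
    for (k in seq_along(cases)) {
      i <- cases[k]
      num <- num + w[k] * (sum(scores[i] > scores[controls]) +
                             0.5 * sum(scores[i] == scores[controls]))
    }
    auc <- num / (sum(w) * length(controls))
    data.frame(horizon = tau, auc = auc, n_cases = length(cases),
               n_controls = length(controls), estimable = TRUE)
  })
  do.call(rbind, rows)
}

#' End-to-end prognostic evaluation of a gene signature
#'
#' Train/test split at a chosen ratio, multivariate Cox on the training
#' portion, risk scores on the test portion, KM median-split with
#' log-rank, and time-dependent AUC at the requested horizons
#' (years converted at 365.25 days).
#'
#' @param data survival data.frame.
#' @param genes signature gene names.
#' @param split_ratio training fraction (default 0.7).
#' @param horizons_years AUC horizons in years (default 1, 3, 5).
#' @param seed integer seed for the split.
#' @return List `model`, `km` ([km_stratify()] output), `auc`
#'   (data.frame), `split` (train/test indices).
#' @export
evaluate_prognosis <- function(data, genes, split_ratio = 0.7,
                               horizons_years = c(1, 3, 5), seed = 1) {
  set.seed(derive_seed(seed, "split"))
  n <- nrow(data)
  tr <- sort(sample(n, round(split_ratio * n)))
  te <- setdiff(seq_len(n), tr)
  model <- multivariate_cox(data[tr, ], genes)
  sc <- risk_score(model, data[te, ])
  km <- km_stratify(data[te, ], sc)
  auc <- time_dependent_auc(data[te, ], sc, horizons_years * 365.25)
  auc$horizon_years <- horizons_years
  list(model = model, km = km, auc = auc, split = list(train = tr, test = te))
}
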