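#' Simulate a survival cohort whose hazard follows a linear gene score
#'
#' Draws standardized expression for the model genes and event times from
#' an exponential proportional-hazards model with linear predictor
#' `sum(beta_g * x_g)`, so the planted score is the true log hazard
#' (relative to baseline). Censoring is independent exponential, with its
#' rate calibrated numerically so the expected censored fraction matches
#' `censoring_rate`.
#'
#' @param n_patients cohort size (>= 20).
#' @param betas named numeric vector of 4 coefficients (gene -> beta).
#' @param baseline_hazard baseline event rate per day (> 0).
#' @param censoring_rate expected fraction censored, in [0, 1).
#' @param seed integer seed.
#' @return A data.frame (`patient_id`, `time_days`, `event`, one column
#'   per gene) with attribute `truth` recording the planted betas and the
#'   requested censoring rate.
#' @export
generate_survival_cohort <- function(n_patients = 500,
                                     betas = c(LG = -0.06759852,
                                               RC = 0.08573037,
                                               TF = -0.84328532,
                                               TG = 0.82401982),
                                     baseline_hazard = 1 / 1000,
                                     censoring_rate = 0.2, seed = 1) {
  if (!is_count(n_patients) || n_patients < 20)
    stopf("n_patients must be a count >= 20")
  if (is.null(names(betas)) || any(!nzchar(names(betas))))
    stopf("betas must be a named vector (gene -> coefficient)")
  if (!is_fraction(censoring_rate))
    stopf("censoring_rate must be in [0, 1]")
  if (censoring_rate == 1)
    stopf("full censoring leaves no events to model")
  set.seed(derive_seed(seed, "survival"))
  p <- length(betas)
  X <- matrix(rnorm(n_patients * p), n_patients, p,
              dimnames = list(NULL, names(betas)))
  X <- scale(X)                      # standardized expression columns
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  lp <- drop(X %*% betas)
  rate <- baseline_hazard * exp(lp)
  t_event <- rexp(n_patients, rate)
  if (censoring_rate > 0) {
    # E[fraction censored] = mean_i c/(c + rate_i) for C ~ Exp(c)
    f <- function(cc) mean(cc / (cc + rate)) - censoring_rate
    cc <- uniroot(f, lower = 1e-12, upper = 1e6 * baseline_hazard,
                  extendInt = "upX")$root
    t_cens <- rexp(n_patients, cc)
  } else t_cens <- rep(Inf, n_patients)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(n_patients)),
                    time_days = time, event = event,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(X))
  attr(out, "truth") <- list(planted_betas = betas,
                             censoring_rate = censoring_rate,
                             baseline_hazard = baseline_hazard)
  out
}

#' Simulate a two-grade bulk cohort over the cascade genes
#'
#' Emulates the imbalanced bulk-expression setting used for grade
#' classification: `n_III` grade-III and `n_IV` grade-IV patients (the
#' default 520/172 reproduces the study imbalance), with the four cascade
#' genes mean-shifted in grade IV by `effect` standard deviations.
#'
#' @param n_III,n_IV class sizes.
#' @param genes gene (column) names.
#' @param effect per-gene mean shift for grade IV, recycled to 4.
#' @param seed integer seed.
#' @return A data.frame (`patient_id`, `grade`, gene columns).
#' @export
generate_grade_cohort <- function(n_III = 520, n_IV = 172,
                                  genes = c("LG", "RC", "TF", "TG"),
                                  effect = c(0.9, -0.7, 1.1, -1.0),
                                  seed = 1) {
  set.seed(derive_seed(seed, "grades"))
  effect <- rep_len(effect, length(genes))
  n <- n_III + n_IV
  grade <- c(rep("III", n_III), rep("IV", n_IV))
  X <- matrix(rnorm(n * length(genes)), n, length(genes),
              dimnames = list(NULL, genes))
  X[grade == "IV", ] <- sweep(X[grade == "IV", , drop = FALSE], 2, effect, `+`)
  data.frame(patient_id = sprintf("B%04d", seq_len(n)), grade = grade,
             as.data.frame(X), stringsAsFactors = FALSE)
}

#' Write / read a survival cohort TSV
#'
#' @param cohort data.frame from [generate_survival_cohort()].
#' @param path TSV path.
#' @return `read_survival_tsv` returns the data.frame.
#' @export
write_survival_tsv <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "time_days", "event") %in% names(d)))
    stopf("survival table needs patient_id, time_days, event columns")
  if (any(d$time_days <= 0)) stopf("survival times must be positive")
  d
}
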