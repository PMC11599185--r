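#' Extract labelled features for grade classification
#'
#' Subsets the bulk expression table to the cascade genes (column order
#' enforced) and joins the grade labels; grade IV is the positive class.
#'
#' @param bulk_expr data.frame with a `patient_id` column and one column
#'   per gene; may carry the labels as a `grade` column.
#' @param genes ordered gene list (all must be present; a missing gene is
#'   an error naming it).
#' @param labels optional data.frame (`patient_id`, `grade`) when the
#'   labels are not a column of `bulk_expr`; patients without a label are
#'   dropped with a warning.
#' @return List of class `labelled_features`: `X` (patients x genes
#'   matrix), `y` (factor with levels III, IV), `patient_ids`.
#' @export
extract_features <- function(bulk_expr, genes, labels = NULL) {
  miss <- setdiff(genes, names(bulk_expr))
  if (length(miss)) stopf("gene(s) missing from the table: %s",
                          paste(miss, collapse = ", "))
  d <- bulk_expr
  if (!is.null(labels)) {
    lab <- setNames(as.character(labels$grade),
                    as.character(labels$patient_id))
    d$grade <- unname(lab[as.character(d$patient_id)])
  }
  if (is.null(d$grade)) stopf("no grade labels supplied")
  if (any(is.na(d$grade))) {
    warnf("%d patients without a grade label dropped", sum(is.na(d$grade)))
    d <- d[!is.na(d$grade), ]
  }
  X <- as.matrix(d[, genes, drop = FALSE])
  if (anyNA(X)) stopf("missing expression values in the feature matrix")
  y <- factor(d$grade, levels = c("III", "IV"))
  if (any(table(y) == 0)) stopf("both classes must be present")
  structure(list(X = X, y = y, patient_ids = as.character(d$patient_id)),
            class = "labelled_features")
}

#' SMOTE minority oversampling
#'
#' Balances the classes by interpolating synthetic minority samples:
#' each synthetic point lies uniformly on the segment between a random
#' minority point and one of its `k_neighbors` nearest minority
#' neighbours (Euclidean). Already balanced input is returned unchanged.
#' Intended for training folds only; [cv_benchmark()] never applies it to
#' test folds.
#'
#' @param features a [labelled_features] object (or list with `X`, `y`).
#' @param k_neighbors neighbourhood size (default 5; reduced with a
#'   warning when the minority class is too small).
#' @param seed integer seed.
#' @return A `labelled_features` with equal class counts; synthetic rows
#'   carry patient ids prefixed `SMOTE_`.
#' @export
smote_oversample <- function(features, k_neighbors = 5, seed = 1) {
  X <- features$X; y <- features$y
  tab <- table(y)
  if (sum(tab > 0) < 2) stopf("SMOTE needs both classes present")
  if (tab[1] == tab[2]) return(features)
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_need <- max(tab) - n_min
  if (n_min < 2) stopf("minority class needs >= 2 samples")
  if (k_neighbors >= n_min) {
    warnf("k_neighbors reduced to %d (minority size %d)", n_min - 1, n_min)
    k_neighbors <- n_min - 1
  }
  set.seed(derive_seed(seed, "smote"))
  Xm <- X[y == minority, , drop = FALSE]
  d <- as.matrix(dist(Xm)); diag(d) <- Inf
  nn <- matrix(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]),
               nrow = nrow(Xm), ncol = k_neighbors, byrow = TRUE)
  base <- sample(nrow(Xm), n_need, replace = TRUE)
  mate <- nn[cbind(base, sample(k_neighbors, n_need, replace = TRUE))]
  u <- runif(n_need)
  synth <- Xm[base, , drop = FALSE] +
    u * (Xm[mate, , drop = FALSE] - Xm[base, , drop = FALSE])
  structure(list(
    X = rbind(X, synth),
    y = factor(c(as.character(y), rep(minority, n_need)),
               levels = levels(y)),
    patient_ids = c(features$patient_ids %||% rep(NA, nrow(X)),
                    sprintf("SMOTE_%04d", seq_len(n_need)))),
    class = "labelled_features")
}

# ---- classifier registry -------------------------------------------------

#' Default hyper-parameter grids
#'
#' Small published grids searched exhaustively by the inner CV of
#' [cv_benchmark()].
#' @return Named list of per-model grids (data.frames).
#' @export
default_grids <- function() {
  list(knn = data.frame(k = c(3, 5, 7)),
       dt = data.frame(cp = c(0.01, 0.05)),
       svm = data.frame(cost = c(0.1, 1, 10)),
       rf = data.frame(mtry = c(1, 2)),
       xgb = data.frame(max_depth = c(2, 4)),
       lr = data.frame(dummy = 0))
}

# fit `model` with hyper-parameters `hp` and return a prediction closure
fit_model <- function(model, X, y, hp) {
  pos <- levels(y)[2]
  switch(model,
    knn = {
      k <- hp$k
      function(Xn) class::knn(X, Xn, y, k = k)
    },
    dt = {
      fit <- rpart::rpart(y ~ ., data = data.frame(y = y, X),
                          method = "class",
                          control = rpart::rpart.control(cp = hp$cp))
      function(Xn) predict(fit, data.frame(Xn), type = "class")
    },
    svm = {
      fit <- e1071::svm(X, y, kernel = "radial", cost = hp$cost)
      function(Xn) predict(fit, Xn)
    },
    rf = {
      fit <- randomForest::randomForest(X, y, ntree = 200,
                                        mtry = min(hp$mtry, ncol(X)))
      function(Xn) predict(fit, Xn)
    },
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y == pos))
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth, eta = 0.3, nthread = 1),
        data = dtrain, nrounds = 50, verbose = 0)
      function(Xn)
        factor(ifelse(predict(fit, xgboost::xgb.DMatrix(Xn)) > 0.5,
                      pos, levels(y)[1]), levels = levels(y))
    },
    lr = {
      fit <- suppressWarnings(
        glm(y ~ ., data = data.frame(y = y, X), family = binomial()))
      function(Xn) {
        p <- suppressWarnings(predict(fit, data.frame(Xn), type = "response"))
        factor(ifelse(p > 0.5, pos, levels(y)[1]), levels = levels(y))
      }
    },
    stopf("unknown model '%s'", model))
}

# exhaustive grid search by inner-CV accuracy; returns the best row of grid
grid_search <- function(model, X, y, grid, inner_folds = 3, seed = 1) {
  if (nrow(grid) == 1) return(grid[1, , drop = FALSE])
  set.seed(seed)
  folds <- stratified_folds(y, inner_folds)
  acc <- sapply(seq_len(nrow(grid)), function(gi) {
    mean(sapply(seq_len(inner_folds), function(f) {
      tr <- folds != f
      pred <- fit_model(model, X[tr, , drop = FALSE], y[tr],
                        grid[gi, , drop = FALSE])(X[!tr, , drop = FALSE])
      mean(pred == y[!tr])
    }))
  })
  grid[which.max(acc), , drop = FALSE]
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

classification_metrics <- function(truth, pred, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  acc <- mean(pred == truth)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  100 * c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Repeated stratified cross-validation benchmark with SMOTE
#'
#' For each iteration the cross-validation portion of the data is
#' shuffled with a derived seed and split into stratified folds; within
#' each fold, SMOTE (training data only) balances the classes, each
#' model's grid is searched exhaustively by inner-CV accuracy, and the
#' winning configuration is evaluated on the untouched test fold. A
#' stratified validation split (default 20 percent) is carved out before
#' any cross-validation and scored once per model at the end. Test folds
#' and the validation split never contain synthetic points. Metrics are
#' on the percent scale; grade IV is the positive class.
#'
#' @param features a [labelled_features].
#' @param models character subset of `names(default_grids())`.
#' @param n_iterations repetitions of the k-fold protocol (protocol
#'   default 100; scale down for quick runs).
#' @param n_folds folds (default 5; each class must have >= n_folds
#'   members).
#' @param seed integer master seed; per-iteration seeds are derived and
#'   logged.
#' @param grids per-model hyper-parameter grids (default
#'   [default_grids()]).
#' @param validation_fraction held-out fraction (default 0.2).
#' @param smote apply SMOTE to training folds (default TRUE).
#' @param smote_k SMOTE neighbourhood size.
#' @return List of class `cv_report`: `summary` (per model x metric mean
#'   and sd over folds x iterations), `validation` (per model),
#'   `fold_log` (per-iteration seeds and fold sizes), `per_fold` (raw
#'   metric rows), `positive`.
#' @export
cv_benchmark <- function(features, models = names(default_grids()),
                         n_iterations = 100, n_folds = 5, seed = 1,
                         grids = default_grids(),
                         validation_fraction = 0.2, smote = TRUE,
                         smote_k = 5) {
  stopifnot(inherits(features, "labelled_features"), n_folds >= 2)
  X <- features$X; y <- features$y
  if (any(table(y) < n_folds))
    stopf("each class needs >= n_folds members")
  pos <- levels(y)[2]
  set.seed(derive_seed(seed, "valsplit"))
  val_idx <- integer()
  if (validation_fraction > 0) {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      val_idx <- c(val_idx, sample(idx, round(validation_fraction * length(idx))))
    }
  }
  cv_idx <- setdiff(seq_along(y), val_idx)
  Xcv <- X[cv_idx, , drop = FALSE]; ycv <- y[cv_idx]

  per_fold <- list(); fold_log <- list(); splits <- list()
  for (it in seq_len(n_iterations)) {
    it_seed <- derive_seed(seed, "iter", it)
    repeat {
      set.seed(it_seed)
      folds <- stratified_folds(ycv, n_folds)
      ok <- all(sapply(seq_len(n_folds), function(f)
        length(unique(ycv[folds != f])) == 2))
      if (ok) break
      it_seed <- it_seed + 1L   # degenerate training fold: resample
      fold_log[[length(fold_log) + 1L]] <-
        data.frame(iteration = it, note = "degenerate fold resampled")
    }
    fold_log[[length(fold_log) + 1L]] <-
      data.frame(iteration = it, note = sprintf("seed=%d", it_seed))
    splits[[it]] <- folds
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      train <- structure(list(X = Xcv[tr, , drop = FALSE], y = ycv[tr],
                              patient_ids = NULL),
                         class = "labelled_features")
      if (smote)
        train <- smote_oversample(train, k_neighbors = smote_k,
                                  seed = derive_seed(it_seed, "sm", f))
      for (m in models) {
        hp <- grid_search(m, train$X, train$y, grids[[m]],
                          seed = derive_seed(it_seed, "gs", f, m))
        pred <- fit_model(m, train$X, train$y, hp)(Xcv[!tr, , drop = FALSE])
        met <- classification_metrics(ycv[!tr], pred, pos)
        per_fold[[length(per_fold) + 1L]] <- data.frame(
          model = m, iteration = it, fold = f, t(met))
      }
    }
  }
  pf <- do.call(rbind, per_fold)
  metrics <- c("accuracy", "precision", "recall", "f1")
  summ <- do.call(rbind, lapply(models, function(m) {
    sub <- pf[pf$model == m, metrics]
    data.frame(model = m, metric = metrics,
               mean = colMeans(sub), sd = apply(sub, 2, sd),
               row.names = NULL)
  }))
  validation <- NULL
  if (length(val_idx)) {
    train <- structure(list(X = Xcv, y = ycv, patient_ids = NULL),
                       class = "labelled_features")
    if (smote)
      train <- smote_oversample(train, k_neighbors = smote_k,
                                seed = derive_seed(seed, "valsm"))
    validation <- do.call(rbind, lapply(models, function(m) {
      hp <- grid_search(m, train$X, train$y, grids[[m]],
                        seed = derive_seed(seed, "valgs", m))
      pred <- fit_model(m, train$X, train$y, hp)(X[val_idx, , drop = FALSE])
      data.frame(model = m,
                 t(classification_metrics(y[val_idx], pred, pos)))
    }))
  }
  structure(list(summary = summ, validation = validation,
                 fold_log = do.call(rbind, fold_log), per_fold = pf,
                 positive = pos, n_validation = length(val_idx),
                 splits = splits, val_idx = sort(val_idx),
                 cv_idx = cv_idx),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("CV benchmark (positive class: grade %s, validation n = %d)\n",
              x$positive, x$n_validation))
  acc <- x$summary[x$summary$metric %in% c("accuracy", "f1"), ]
  for (m in unique(acc$model)) {
    s <- acc[acc$model == m, ]
    cat(sprintf("  %-4s accuracy %5.1f +/- %4.1f  F1 %5.1f +/- %4.1f\n",
                m, s$mean[s$metric == "accuracy"], s$sd[s$metric == "accuracy"],
                s$mean[s$metric == "f1"], s$sd[s$metric == "f1"]))
  }
  invisible(x)
}
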