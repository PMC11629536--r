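# Random-forest property predictor with per-tree access.
#
# The ensemble prediction is the arithmetic mean of B tree outputs (regression
# values, or {0,1} class votes whose mean is the positive-class probability).
# "Fine-tuning" is a weighted refit from scratch: a forest has no incremental
# gradient step, and the confidence-weighted objective over the union of
# initial and acquired data is exactly what a weighted refit minimizes.
# Weights act through the bootstrap, so zero-confidence feedback reproduces a
# refit on the initial data bit-for-bit at a fixed seed.

#' Labeled molecule set
#'
#' @param smiles character vector of SMILES.
#' @param label numeric labels: real values (regression) or 0/1
#'   (classification).
#' @param weight nonnegative per-record weights; default 1.
#' @param origin `"initial"` or `"acquired"`.
#' @return a data.frame of class `labeled_set` with columns
#'   `smiles`, `label`, `weight`.
#' @export
labeled_set <- function(smiles, label, weight = NULL, origin = "initial") {
  if (length(smiles) != length(label)) stop_molhitl("smiles and label lengths differ")
  weight <- weight %||% rep(1, length(smiles))
  if (length(weight) == 1L) weight <- rep(weight, length(smiles))
  if (any(weight < 0)) stop_molhitl("weights must be >= 0")
  out <- data.frame(smiles = as.character(smiles), label = as.numeric(label),
                    weight = as.numeric(weight), stringsAsFactors = FALSE)
  attr(out, "origin") <- match.arg(origin, c("initial", "acquired"))
  class(out) <- c("labeled_set", "data.frame")
  out
}

rf_defaults <- function(task, p) {
  if (task == "regression")
    list(ntree = 300L, max_depth = 30L, min_split = 2L,
         mtry = max(1L, as.integer(floor(p / 3))))
  else
    list(ntree = 200L, max_depth = 10L, min_split = 2L,
         mtry = max(1L, as.integer(floor(sqrt(p)))))
}

rf_fit_matrix <- function(X, y, w, task, ntree, mtry, max_depth, min_split, seed) {
  if (nrow(X) < 2L) stop_molhitl("need at least 2 training records")
  if (task == "classification") {
    if (!all(y %in% c(0, 1))) stop_molhitl("classification labels must be 0/1")
    if (length(unique(y[w > 0])) < 2L)
      stop_molhitl("classification training data must contain both classes")
  }
  if (sum(w) <= 0) stop_molhitl("all sample weights are zero")
  # zero-weight records are dropped outright: they can influence neither the
  # bootstrap draws nor their count, so zero-confidence feedback reproduces a
  # refit on the remaining data bit-for-bit
  if (any(w == 0)) {
    keep <- w > 0
    X <- X[keep, , drop = FALSE]; y <- y[keep]; w <- w[keep]
  }
  forest <- cpp_rf_fit(X, as.numeric(y), as.numeric(w), as.integer(ntree),
                       as.integer(mtry), as.integer(max_depth),
                       as.integer(min_split), task == "classification",
                       as.double(seed))
  forest
}

#' Fit the initial property predictor
#'
#' Fits a bagged ensemble of CART trees on Morgan count fingerprints.
#' Defaults follow the reference configuration: 300 trees with
#' `min_split = 2` for regression, 200 trees with `max_depth = 10` for
#' classification. Fits are deterministic per seed.
#'
#' @param data a [labeled_set()] (classification needs both classes present).
#' @param task `"regression"` or `"classification"`.
#' @param cfg a [fingerprint_config()].
#' @param ntree,max_depth,min_split,mtry forest hyperparameters; `NULL` picks
#'   the task defaults.
#' @param seed integer seed.
#' @return an object of class `rf_ensemble`.
#' @export
fit_initial <- function(data, task = c("regression", "classification"),
                        cfg = fingerprint_config(), ntree = NULL,
                        max_depth = NULL, min_split = NULL, mtry = NULL,
                        seed = 1L) {
  task <- match.arg(task)
  if (!inherits(data, "labeled_set")) stop_molhitl("data must be a labeled_set")
  if (nrow(data) == 0L) stop_molhitl("cannot fit on an empty labeled set")
  X <- fingerprint_matrix(data$smiles, cfg)
  d <- rf_defaults(task, ncol(X))
  ntree <- as.integer(ntree %||% d$ntree)
  max_depth <- as.integer(max_depth %||% d$max_depth)
  min_split <- as.integer(min_split %||% d$min_split)
  mtry <- as.integer(mtry %||% d$mtry)
  if (ntree < 2L) stop_molhitl("need at least 2 trees")
  forest <- rf_fit_matrix(X, data$label, data$weight, task, ntree, mtry,
                          max_depth, min_split, seed)
  structure(list(task = task, forest = forest, B = ntree, cfg = cfg,
                 fit_params = list(ntree = ntree, max_depth = max_depth,
                                   min_split = min_split, mtry = mtry,
                                   seed = seed),
                 training = list(initial = data, acquired = list())),
            class = "rf_ensemble")
}

as_feature_matrix <- function(predictor, x) {
  if (is.character(x)) return(fingerprint_matrix(x, predictor$cfg))
  if (inherits(x, "molecule")) return(matrix(x$fingerprint, nrow = 1L))
  if (is.matrix(x)) {
    if (ncol(x) != predictor$cfg$length)
      stop_molhitl("feature matrix has %d columns, expected %d",
                   ncol(x), predictor$cfg$length)
    return(x)
  }
  stop_molhitl("x must be SMILES, a molecule, or a fingerprint matrix")
}

#' Predict from a fitted ensemble
#'
#' @param object an `rf_ensemble`.
#' @param newdata SMILES vector, [as_molecule()] object, or fingerprint matrix.
#' @param type `"mean"` for the ensemble mean (regression value or
#'   positive-class probability), `"tree"` for the n-by-B matrix of per-tree
#'   outputs.
#' @param ... unused.
#' @return numeric vector (`"mean"`) or matrix (`"tree"`).
#' @export
predict.rf_ensemble <- function(object, newdata, type = c("mean", "tree"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(object, newdata)
  P <- cpp_rf_predict(object$forest, X)
  if (type == "tree") P else rowMeans(P)
}

#' Ensemble mean prediction for one molecule
#'
#' @param predictor an `rf_ensemble`.
#' @param x SMILES, molecule, or fingerprint matrix.
#' @return mean of the per-tree outputs.
#' @export
predict_mean <- function(predictor, x) {
  if (!inherits(predictor, "rf_ensemble")) stop_molhitl("not a fitted rf_ensemble")
  predict(predictor, x, type = "mean")
}

#' Per-tree predictions
#'
#' Each tree is an individual parameter draw of the ensemble posterior; the
#' acquisition criteria consume these per-tree outputs directly.
#'
#' @param predictor an `rf_ensemble`.
#' @param x SMILES, molecule, or fingerprint matrix.
#' @return n-by-B matrix of tree outputs (a vector when n = 1).
#' @export
tree_predictions <- function(predictor, x) {
  if (!inherits(predictor, "rf_ensemble")) stop_molhitl("not a fitted rf_ensemble")
  P <- predict(predictor, x, type = "tree")
  if (nrow(P) == 1L) drop(P) else P
}

#' @export
print.rf_ensemble <- function(x, ...) {
  cat(sprintf("<rf_ensemble> %s forest: B = %d trees, fingerprint D = %d\n",
              x$task, x$B, x$cfg$length))
  cat(sprintf("  trained on %d initial + %d acquired records\n",
              nrow(x$training$initial),
              sum(vapply(x$training$acquired, nrow, integer(1)))))
  invisible(x)
}

#' Confidence-weighted fine-tuning
#'
#' Refits the ensemble from scratch on the union of the initial data and all
#' acquired feedback batches. Per-record weights mirror the two normalized
#' sums of the fine-tuning objective: each initial record gets `1 / N0`, each
#' acquired record gets `u_t / N_acq` (its expert confidence over the total
#' number of acquired records), so the initial data and the accumulated
#' feedback carry balanced total mass, higher expert confidence exerts
#' greater influence, and zero-confidence feedback exerts none
#' (bit-identical, at a fixed seed, to a refit on the initial data).
#' The objective is stated for a single batch of `T`; with batches
#' accumulating across rounds, a per-batch `1/T` factor would let feedback
#' outweigh the initial data by the number of batches, which demonstrably
#' destroys global fit at desk scale, so the mean is taken over all acquired
#' records instead.
#'
#' @param predictor a fitted `rf_ensemble`.
#' @param initial the initial [labeled_set()].
#' @param acquired_batches list of acquired [labeled_set()]s whose `weight`
#'   column carries the expert confidences `u_t` in \[0, 1\].
#' @param seed integer seed for the refit.
#' @return a new `rf_ensemble`.
#' @export
fine_tune <- function(predictor, initial, acquired_batches = list(), seed = 1L) {
  if (!inherits(predictor, "rf_ensemble")) stop_molhitl("not a fitted rf_ensemble")
  if (!inherits(initial, "labeled_set")) stop_molhitl("initial must be a labeled_set")
  n0 <- nrow(initial)
  smiles <- initial$smiles
  label <- initial$label
  weight <- rep(1 / n0, n0)
  n_acq <- sum(vapply(acquired_batches, nrow, integer(1)))
  for (batch in acquired_batches) {
    if (!nrow(batch)) next
    if (any(batch$weight < 0 | batch$weight > 1))
      stop_molhitl("acquired confidences must lie in [0, 1]")
    smiles <- c(smiles, batch$smiles)
    label <- c(label, batch$label)
    weight <- c(weight, batch$weight / n_acq)
  }
  X <- fingerprint_matrix(smiles, predictor$cfg)
  fp <- predictor$fit_params
  forest <- rf_fit_matrix(X, label, weight, predictor$task, fp$ntree, fp$mtry,
                          fp$max_depth, fp$min_split, seed)
  out <- predictor
  out$forest <- forest
  out$fit_params$seed <- seed
  out$training <- list(initial = initial, acquired = acquired_batches)
  out
}

#' Platt scaling calibration
#'
#' Fits a logistic regression of holdout labels on the classifier's raw mean
#' scores, mapping them to calibrated probabilities; the monotone logistic
#' preserves the score ranking.
#'
#' @param predictor a fitted classification `rf_ensemble`.
#' @param holdout a [labeled_set()] containing both classes.
#' @return an object of class `platt_calibration`; call it on raw scores, or
#'   use `predict(cal, smiles)` for end-to-end calibrated probabilities.
#' @export
platt_calibrate <- function(predictor, holdout) {
  if (!inherits(predictor, "rf_ensemble")) stop_molhitl("not a fitted rf_ensemble")
  if (predictor$task != "classification")
    stop_molhitl("Platt scaling applies to classification predictors only")
  if (length(unique(holdout$label)) < 2L)
    stop_molhitl("holdout must contain both classes")
  raw <- predict(predictor, holdout$smiles)
  fit <- suppressWarnings(
    stats::glm(holdout$label ~ raw, family = stats::binomial()))
  coefs <- stats::coef(fit)
  structure(list(intercept = unname(coefs[1L]), slope = unname(coefs[2L]),
                 predictor = predictor),
            class = "platt_calibration")
}

#' @export
predict.platt_calibration <- function(object, newdata, ...) {
  raw <- predict(object$predictor, newdata)
  stats::plogis(object$intercept + object$slope * raw)
}

#' Calibrate raw scores with a fitted Platt mapping
#'
#' @param cal a `platt_calibration`.
#' @param raw numeric raw scores.
#' @return calibrated probabilities in \[0, 1\].
#' @export
calibrate_scores <- function(cal, raw) {
  stopifnot(inherits(cal, "platt_calibration"))
  stats::plogis(cal$intercept + cal$slope * raw)
}
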