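# Multi-component scoring: [0,1] transforms and the normalized weighted sum
# s(x) = sum_j w_j sigma_j(phi_j(x)) + sum_k w_k sigma_k(f_theta_k(x)),
# with weights normalized so the total stays in [0, 1].

#' Score transforms
#'
#' Transforms map raw component values into \[0, 1\] rewards. Available kinds:
#' `identity` (values assumed already in \[0, 1\], clipped), `sigmoid`
#' (logistic around `low` with slope `steepness`), `double_sigmoid` (reward
#' plateau over \[`low`, `high`\], value 0.5 at each boundary), and `flip`
#' (`1 - p`, for objectives to be minimized).
#'
#' @param kind one of `"identity"`, `"sigmoid"`, `"double_sigmoid"`, `"flip"`.
#' @param low,high range parameters (used by `sigmoid` / `double_sigmoid`).
#' @param steepness positive slope parameter; default 10 gives a sharp but
#'   finite plateau for ranges a few units wide (e.g. LogP in \[2, 4\]).
#' @return an object of class `transform`.
#' @export
transform_spec <- function(kind = c("identity", "sigmoid", "double_sigmoid", "flip"),
                           low = 0, high = 1, steepness = 10) {
  kind <- match.arg(kind)
  if (kind == "double_sigmoid" && low >= high)
    stop_molhitl("double_sigmoid needs low < high (got %g >= %g)", low, high)
  if (steepness <= 0) stop_molhitl("steepness must be positive")
  structure(list(kind = kind, low = low, high = high, steepness = steepness),
            class = "transform")
}

#' Apply a transform
#'
#' @param tr a [transform_spec()].
#' @param x numeric vector of raw component values.
#' @return numeric vector in \[0, 1\].
#' @export
apply_transform <- function(tr, x) {
  stopifnot(inherits(tr, "transform"))
  switch(tr$kind,
    identity = pmin(pmax(x, 0), 1),
    sigmoid = stats::plogis(tr$steepness * (x - tr$low)),
    double_sigmoid = double_sigmoid(x, tr$low, tr$high, tr$steepness),
    flip = flip(x))
}

#' Double sigmoid reward over a value range
#'
#' `plogis(k (x - low)) * plogis(-k (x - high))`: close to 1 well inside
#' \[`low`, `high`\], 0.5 at each boundary when the range is wide relative to
#' `1/steepness`, and decaying to 0 far outside.
#'
#' @param x numeric vector.
#' @param low,high range of desired values, `low < high`.
#' @param steepness positive slope.
#' @return numeric vector in \[0, 1\].
#' @export
double_sigmoid <- function(x, low, high, steepness = 10) {
  if (low >= high) stop_molhitl("double_sigmoid needs low < high (got %g >= %g)", low, high)
  if (steepness <= 0) stop_molhitl("steepness must be positive")
  stats::plogis(steepness * (x - low)) * stats::plogis(-steepness * (x - high))
}

#' Probability flip
#'
#' `1 - p`, used to reward low probabilities (e.g. predicted liability such as
#' hERG activation).
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @return `1 - p`.
#' @export
flip <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_molhitl("flip needs p in [0, 1]")
  1 - p
}

#' Scoring component
#'
#' One term of the composite score: a named evaluator with a positive weight
#' and a transform. Three evaluator kinds exist: `predictor` (a fitted
#' [fit_initial()] ensemble; raw value is its mean prediction), `analytic` (a
#' function of a SMILES vector returning numerics, e.g. [penalized_logp()]),
#' and `similarity` (max Tanimoto to a reference SMILES set).
#'
#' @param name component name (unique within a scoring function).
#' @param kind `"predictor"`, `"analytic"` or `"similarity"`.
#' @param weight positive weight.
#' @param transform a [transform_spec()].
#' @param predictor fitted ensemble (kind `"predictor"`).
#' @param fn function `smiles -> numeric` (kind `"analytic"`).
#' @param reference character vector of reference SMILES (kind `"similarity"`).
#' @return an object of class `scoring_component`.
#' @export
scoring_component <- function(name, kind = c("predictor", "analytic", "similarity"),
                              weight = 1, transform = transform_spec("identity"),
                              predictor = NULL, fn = NULL, reference = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(weight) || weight <= 0) stop_molhitl("weight must be positive")
  stopifnot(inherits(transform, "transform"))
  if (kind == "predictor" && is.null(predictor))
    stop_molhitl("component '%s': kind 'predictor' needs a fitted predictor", name)
  if (kind == "analytic" && !is.function(fn))
    stop_molhitl("component '%s': kind 'analytic' needs a function", name)
  if (kind == "similarity" && (is.null(reference) || !length(reference)))
    stop_molhitl("component '%s': kind 'similarity' needs a nonempty reference set", name)
  structure(list(name = name, kind = kind, weight = weight, transform = transform,
                 predictor = predictor, fn = fn, reference = reference),
            class = "scoring_component")
}

#' Composite scoring function
#'
#' @param components list of [scoring_component()]s (nonempty, unique names).
#' @param cfg a [fingerprint_config()] used for predictor / similarity
#'   featurization.
#' @return an object of class `scoring_function`.
#' @export
scoring_function <- function(components, cfg = fingerprint_config()) {
  if (!length(components)) stop_molhitl("a scoring function needs at least one component")
  stopifnot(all(vapply(components, inherits, logical(1), "scoring_component")))
  nm <- vapply(components, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop_molhitl("duplicate component names")
  names(components) <- nm
  structure(list(components = components, cfg = cfg), class = "scoring_function")
}

# replace the predictor inside a named component (after fine-tuning)
swap_predictor <- function(sf, name, predictor) {
  stopifnot(inherits(sf, "scoring_function"))
  if (!name %in% names(sf$components)) stop_molhitl("no component named '%s'", name)
  sf$components[[name]]$predictor <- predictor
  sf
}

#' Weighted aggregation of transformed component values
#'
#' `sum(w_i v_i) / sum(w_i)`: monotone in every component, invariant to a
#' uniform rescaling of the weights, and in \[0, 1\] whenever all values are.
#'
#' @param values numeric vector (or matrix, columns = components) of
#'   transformed values in \[0, 1\].
#' @param weights positive component weights.
#' @return aggregated score(s) in \[0, 1\].
#' @export
aggregate_scores <- function(values, weights) {
  if (!length(weights)) stop_molhitl("empty component list")
  if (any(weights <= 0)) stop_molhitl("weights must be positive")
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(weights))
    return(as.numeric(values %*% weights) / sum(weights))
  }
  stopifnot(length(values) == length(weights))
  sum(values * weights) / sum(weights)
}

#' Maximum Tanimoto similarity to a reference set
#'
#' @param smiles character vector of query SMILES.
#' @param reference nonempty character vector of reference SMILES.
#' @param cfg a [fingerprint_config()].
#' @return numeric vector: per query, the maximum presence-bit Tanimoto
#'   similarity to any reference molecule.
#' @export
similarity_component <- function(smiles, reference, cfg = fingerprint_config()) {
  if (!length(reference)) stop_molhitl("empty similarity reference set")
  sim <- tanimoto_cross(fingerprint_matrix(smiles, cfg),
                        fingerprint_matrix(reference, cfg))
  unname(apply(sim, 1L, max))
}

#' Score molecules with a composite scoring function
#'
#' Evaluates every component on every molecule, applies the transforms, and
#' aggregates with normalized weights.
#'
#' @param sf a [scoring_function()].
#' @param smiles character vector of SMILES.
#' @return a data.frame with columns `smiles`, one transformed score column
#'   per component, and `total`.
#' @export
score_molecules <- function(sf, smiles) {
  stopifnot(inherits(sf, "scoring_function"))
  n <- length(smiles)
  comps <- sf$components
  vals <- matrix(0, nrow = n, ncol = length(comps),
                 dimnames = list(NULL, names(comps)))
  if (n > 0) {
    fps <- NULL
    for (cc in comps) {
      raw <- switch(cc$kind,
        predictor = {
          if (is.null(fps)) fps <- fingerprint_matrix(smiles, sf$cfg)
          predict(cc$predictor, fps)
        },
        analytic = cc$fn(smiles),
        similarity = similarity_component(smiles, cc$reference, sf$cfg))
      vals[, cc$name] <- apply_transform(cc$transform, raw)
    }
  }
  weights <- vapply(comps, `[[`, numeric(1), "weight")
  total <- if (n > 0) aggregate_scores(vals, weights) else numeric(0)
  out <- data.frame(smiles = smiles, vals, total = total,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}
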