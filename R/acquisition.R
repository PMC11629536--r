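# Data acquisition criteria over a pool of generated molecules: EPIG
# (expected predictive information gain), ensemble uncertainty, greedy, and a
# random baseline.
#
# EPIG(x) = E_{p*(x*)} KL[ p(y, y* | x, x*) || p(y|x) p(y*|x*) ]: the expected
# mutual information between the predictive outcome at a candidate x and the
# outcomes at target inputs x*, under the tree-ensemble posterior (each tree =
# one parameter draw). The target input distribution p* puts score-
# proportional weight on the top-k pool molecules. All entropies are in nats.

#' Score-weighted target input distribution
#'
#' Members are the top-`min(k, n)` pool molecules by transformed predicted
#' score; each member's weight is proportional to its score, normalized over
#' the members, and zero elsewhere.
#'
#' @param smiles pool SMILES.
#' @param scores transformed predicted scores in \[0, 1\], aligned with
#'   `smiles`.
#' @param k number of top molecules retained (reference default 1000, capped
#'   at the pool size).
#' @param degenerate what to do when all member scores are zero: `"error"`
#'   (default; the fallback is never silent) or `"uniform"`.
#' @return an object of class `target_distribution` with fields `smiles` and
#'   `weights` (summing to 1).
#' @export
target_distribution <- function(smiles, scores, k = 1000L,
                                degenerate = c("error", "uniform")) {
  degenerate <- match.arg(degenerate)
  if (!length(smiles)) stop_molhitl("empty pool")
  if (length(smiles) != length(scores)) stop_molhitl("smiles/scores length mismatch")
  if (any(scores < 0 | scores > 1)) stop_molhitl("scores must lie in [0, 1]")
  k <- min(as.integer(k), length(smiles))
  ord <- order(-scores, smiles, method = "radix")[seq_len(k)]
  s <- scores[ord]
  if (sum(s) == 0) {
    if (degenerate == "error")
      stop_molhitl("degenerate target distribution: all top-k scores are zero")
    w <- rep(1 / k, k)
  } else {
    w <- s / sum(s)
  }
  structure(list(smiles = smiles[ord], weights = w), class = "target_distribution")
}

# per-tree binary outcomes: class votes, or transformed regression outputs
# thresholded at 0.5 ("in the desired range" vs not)
tree_outcomes <- function(predictor, x, transform = NULL) {
  P <- predict(predictor, x, type = "tree")
  if (predictor$task == "classification") return(P)
  if (is.null(transform))
    stop_molhitl("regression acquisition needs the scoring component's transform")
  (apply_transform(transform, P) > 0.5) * 1
}

# elementwise MI of 2x2 joints given p11 (n x m) and marginals pa (n), pb (m);
# 0 log 0 := 0
binary_mi <- function(p11, pa, pb) {
  p10 <- pmax(pa - p11, 0)                      # recycles pa down columns
  p01 <- pmax(sweep(-p11, 2L, pb, "+"), 0)
  p00 <- pmax(1 - p11 - p10 - p01, 0)
  term <- function(p, q) ifelse(p > 0 & q > 0, p * log(p / q), 0)
  qa <- cbind(pa); qb <- rbind(pb)
  mi <- term(p11, qa %*% qb) +
        term(p10, qa %*% (1 - qb)) +
        term(p01, (1 - qa) %*% qb) +
        term(p00, (1 - qa) %*% (1 - qb))
  pmax(mi, 0)
}

#' Pairwise mutual information between two molecules' predictive outcomes
#'
#' The joint over (y, y*) is formed by matching tree indices: tree i
#' contributes the outcome pair (f_i(x), f_i(x*)); the MI of that 2x2 joint
#' against the product of its marginals is the inner KL term of the EPIG
#' criterion, in nats.
#'
#' @param predictor a fitted `rf_ensemble`.
#' @param x,x_star SMILES (or molecules / fingerprint rows).
#' @param transform required for regression: the scoring component's
#'   [transform_spec()], used to binarize tree outputs at 0.5.
#' @return mutual information >= 0 (nats).
#' @export
pairwise_mi <- function(predictor, x, x_star, transform = NULL) {
  ox <- tree_outcomes(predictor, x, transform)
  os <- tree_outcomes(predictor, x_star, transform)
  ox <- matrix(ox, nrow = 1L); os <- matrix(os, nrow = 1L)
  B <- ncol(ox)
  p11 <- (ox %*% t(os)) / B
  as.numeric(binary_mi(p11, rowMeans(ox), rowMeans(os)))
}

#' EPIG acquisition scores
#'
#' For every pool molecule, the target-weighted sum of pairwise mutual
#' informations against the target-distribution members (exact weighted sum,
#' no sampling).
#'
#' @param predictor a fitted `rf_ensemble`.
#' @param pool character vector of pool SMILES.
#' @param target a [target_distribution()].
#' @param transform regression only: the scoring component's transform.
#' @return named numeric vector of EPIG scores (>= 0), names = pool SMILES.
#' @export
epig_scores <- function(predictor, pool, target, transform = NULL) {
  if (!inherits(target, "target_distribution")) stop_molhitl("invalid target distribution")
  if (!length(target$smiles)) stop_molhitl("empty target distribution")
  O <- matrix(tree_outcomes(predictor, pool, transform), nrow = length(pool))
  Ot <- matrix(tree_outcomes(predictor, target$smiles, transform),
               nrow = length(target$smiles))
  B <- ncol(O)
  p11 <- (O %*% t(Ot)) / B
  mi <- binary_mi(p11, rowMeans(O), rowMeans(Ot))
  out <- as.numeric(mi %*% target$weights)
  names(out) <- pool
  out
}

#' Ensemble uncertainty scores
#'
#' Regression: population variance of the per-tree outputs (1/B
#' normalization). Classification: Shannon entropy (nats) of the predicted
#' positive-class probability, with 0 log 0 := 0.
#'
#' @param predictor a fitted `rf_ensemble`.
#' @param pool character vector of pool SMILES.
#' @return named numeric vector of uncertainties.
#' @export
uncertainty_scores <- function(predictor, pool) {
  P <- matrix(predict(predictor, pool, type = "tree"), nrow = length(pool))
  if (predictor$task == "regression") {
    m <- rowMeans(P)
    out <- rowMeans((P - m)^2)
  } else {
    p <- rowMeans(P)
    h <- function(q) ifelse(q > 0, -q * log(q), 0)
    out <- h(p) + h(1 - p)
  }
  names(out) <- pool
  out
}

#' Greedy acquisition scores
#'
#' The transformed predicted score itself: exploit the model's current
#' optimum.
#'
#' @param pool character vector of pool SMILES.
#' @param scores transformed predicted scores aligned with `pool`.
#' @return named numeric vector.
#' @export
greedy_scores <- function(pool, scores) {
  if (length(pool) != length(scores)) stop_molhitl("pool/scores length mismatch")
  names(scores) <- pool
  scores
}

#' Select a query batch
#'
#' Ranked criteria (`epig`, `uncertainty`, `greedy`) take the top-`T` scores
#' with ties broken by canonical SMILES order; `random` draws uniformly
#' without replacement. Molecules in `exclude` (already queried this run) are
#' never selected; if fewer than `T` candidates remain, the batch is short
#' (possibly empty - the caller ends the AL iteration).
#'
#' @param scores named numeric vector (names = pool SMILES).
#' @param T batch size (>= 1).
#' @param criterion `"epig"`, `"uncertainty"`, `"greedy"` or `"random"`.
#' @param seed integer seed (used by `random`).
#' @param exclude character vector of SMILES never to select.
#' @return an object of class `acquisition_result` with fields `criterion`,
#'   `scores` and `batch` (ordered SMILES, no duplicates).
#' @export
select_batch <- function(scores, T, criterion = c("epig", "uncertainty", "greedy", "random"),
                         seed = 1L, exclude = character(0)) {
  criterion <- match.arg(criterion)
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop_molhitl("T must be >= 1")
  pool <- names(scores)
  if (is.null(pool)) stop_molhitl("scores must be named by SMILES")
  keep <- !(pool %in% exclude) & !duplicated(pool)
  pool <- pool[keep]; s <- unname(scores[keep])
  if (criterion == "random") {
    idx <- sample_stream(length(pool), min(T, length(pool)), derive_seed(seed, 7919))
    batch <- pool[idx]
  } else {
    ord <- order(-s, pool, method = "radix")
    batch <- pool[ord][seq_len(min(T, length(pool)))]
  }
  structure(list(criterion = criterion, scores = scores, batch = batch),
            class = "acquisition_result")
}
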