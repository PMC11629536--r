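# Ground-truth oracles, simulated noisy experts, and the conversion of
# agreement scores into labels and confidences.
#
# Oracles stand in for wet-lab measurement: deterministic functions of the
# molecule. Two built-ins make every stage testable offline: a penalized-LogP
# analogue (partition estimate minus synthetic-accessibility score minus the
# long-cycle count, all computed from this package's own descriptors), and a
# synthetic fingerprint-linear oracle whose recoverable structure supports
# parameter-recovery experiments.

# simplified atom-contribution partition (logP) estimate: per-element
# contributions, aromatic variants, hydrogen terms, charge penalty
.LOGP_ATOM <- c(C = 0.36, N = -0.80, O = -0.75, S = 0.25, P = -0.50,
                F = 0.22, Cl = 0.65, Br = 0.86, I = 1.10, B = 0.10)
.LOGP_ATOM_AROM <- c(C = 0.29, N = -0.50, O = -0.30, S = 0.40, P = -0.40,
                     B = 0.10)
.LOGP_H_ON_C <- 0.12
.LOGP_H_ON_HET <- -0.25
.LOGP_CHARGE <- -1.00

#' Partition coefficient estimate (atom contributions)
#'
#' A deterministic, simplified octanol-water partition estimate: summed
#' per-atom contributions (element and aromaticity specific), hydrogen terms
#' (hydrophobic on carbon, polar on heteroatoms) and a charge penalty. A
#' stand-in for published fragment schemes, sufficient to define a smooth,
#' structure-sensitive optimization target.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector of partition estimates.
#' @export
logp_estimate <- function(smiles) {
  vapply(smiles, function(s) {
    mol <- mol_of(s)
    contrib <- ifelse(mol$arom,
                      .LOGP_ATOM_AROM[mol$elem],
                      .LOGP_ATOM[mol$elem])
    hterm <- ifelse(mol$elem == "C", .LOGP_H_ON_C, .LOGP_H_ON_HET) * mol$hcount
    sum(contrib) + sum(hterm) + .LOGP_CHARGE * sum(abs(mol$charge))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Synthetic-accessibility heuristic
#'
#' A deterministic complexity heuristic on a 1-10 scale (lower = easier to
#' synthesize): size, ring count, fused-ring and macrocycle penalties, and
#' branching. A simplified analogue of published SA scores.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector of SA scores in \[1, 10\].
#' @export
sa_score <- function(smiles) {
  vapply(smiles, function(s) {
    mol <- mol_of(s)
    n <- length(mol$elem)
    rings <- mol_rings(mol)
    nring <- length(rings)
    fused <- 0L
    if (nring > 1L)
      for (i in seq_len(nring - 1L))
        for (j in seq((i + 1L), nring))
          if (length(intersect(rings[[i]], rings[[j]]))) fused <- fused + 1L
    macro <- sum(lengths(rings) > 6L)
    deg <- integer(n)
    for (k in seq_along(mol$bfrom)) {
      deg[mol$bfrom[k]] <- deg[mol$bfrom[k]] + 1L
      deg[mol$bto[k]] <- deg[mol$bto[k]] + 1L
    }
    sa <- 1 + 0.05 * n + 0.3 * nring + 0.7 * fused + 1.0 * macro +
      1.5 * mean(deg >= 3L)
    min(max(sa, 1), 10)
  }, numeric(1), USE.NAMES = FALSE)
}

# rings with more than `size` atoms
long_cycle_count <- function(smiles, size = 6L) {
  vapply(smiles, function(s) sum(lengths(mol_rings(mol_of(s))) > size),
         integer(1), USE.NAMES = FALSE)
}

#' Penalized LogP
#'
#' Partition estimate minus synthetic-accessibility score minus the number of
#' long cycles (rings with more than six atoms). Deterministic; the long-cycle
#' term is exactly zero for acyclic molecules.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector.
#' @export
penalized_logp <- function(smiles) {
  logp_estimate(smiles) - sa_score(smiles) - long_cycle_count(smiles)
}

#' Drug-likeness estimate in \[0, 1\]
#'
#' A simplified quantitative drug-likeness score: the geometric mean of
#' Gaussian desirabilities on heavy-atom count, partition estimate, ring
#' count, and hydrogen-bond donor/acceptor counts. An analogue of QED for the
#' package's own descriptor set.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector in \[0, 1\].
#' @export
qed_score <- function(smiles) {
  vapply(smiles, function(s) {
    mol <- mol_of(s)
    n <- length(mol$elem)
    nring <- length(mol_rings(mol))
    het <- mol$elem %in% c("N", "O")
    hbd <- sum(mol$hcount[het] > 0L)
    hba <- sum(het)
    lp <- logp_estimate(s)
    d <- c(exp(-((n - 23) / 12)^2),
           exp(-((lp - 2.5) / 3)^2),
           exp(-((nring - 2) / 2)^2),
           exp(-((hbd - 1.5) / 2.5)^2),
           exp(-((hba - 3) / 3.5)^2))
    exp(mean(log(pmax(d, 1e-6))))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Oracle objects
#'
#' An oracle is a deterministic ground-truth evaluator `f*`. `oracle()` wraps
#' any SMILES-vector function; `penalized_logp_oracle()` wraps
#' [penalized_logp()]; `synthetic_linear_oracle()` is a fingerprint-linear
#' oracle `w . x + b` (optionally squashed through a logistic to \[0, 1\] for
#' classification-style targets), whose known structure supports
#' parameter-recovery tests.
#'
#' @param fn function mapping a character vector of SMILES to numerics.
#' @param kind oracle label.
#' @param range `"real"` or `"unit"` (outputs in \[0, 1\]).
#' @return an object of class `oracle`.
#' @export
oracle <- function(fn, kind = "custom", range = c("real", "unit")) {
  stopifnot(is.function(fn))
  structure(list(kind = kind, fn = fn, range = match.arg(range)),
            class = "oracle")
}

#' @rdname oracle
#' @export
penalized_logp_oracle <- function() oracle(penalized_logp, "penalized_logp", "real")

#' @rdname oracle
#' @param weights numeric weight vector over fingerprint positions
#'   (length `cfg$length`).
#' @param bias intercept.
#' @param sigmoided squash `w . x + b` through a logistic into \[0, 1\]?
#' @param cfg a [fingerprint_config()].
#' @export
synthetic_linear_oracle <- function(weights, bias = 0, sigmoided = FALSE,
                                    cfg = fingerprint_config()) {
  if (length(weights) != cfg$length)
    stop_molhitl("weights length %d does not match fingerprint length %d",
                 length(weights), cfg$length)
  force(bias); force(sigmoided)
  fn <- function(smiles) {
    v <- as.numeric(fingerprint_matrix(smiles, cfg) %*% weights) + bias
    if (sigmoided) stats::plogis(v) else v
  }
  oracle(fn, "synthetic_linear", if (sigmoided) "unit" else "real")
}

#' Random sparse weights for a synthetic linear oracle
#'
#' @param seed integer seed.
#' @param cfg a [fingerprint_config()].
#' @param density fraction of nonzero positions.
#' @param sd standard deviation of the nonzero weights.
#' @return numeric vector of length `cfg$length`.
#' @export
random_linear_weights <- function(seed, cfg = fingerprint_config(),
                                  density = 0.05, sd = 1) {
  D <- cfg$length
  w <- numeric(D)
  nz <- sample_stream(D, max(1L, as.integer(round(density * D))),
                      derive_seed(seed, 271828))
  w[nz] <- sd * rnorm_stream(derive_seed(seed, 314159), seq_along(nz))
  w
}

#' Threshold oracle values into binary labels
#'
#' Label 1 iff the value strictly exceeds the threshold `delta`.
#'
#' @param values numeric vector.
#' @param delta threshold.
#' @return integer vector of 0/1 labels.
#' @export
binary_labels <- function(values, delta) as.integer(values > delta)

#' Simulated expert models
#'
#' An expert model wraps an oracle with Gaussian noise of standard deviation
#' `sigma_eps` (and, for classification-style experts, clipping to \[0, 1\]):
#' `f_human(x) = f*(x) + eps` or `g(f*(x) + eps)`. Noise comes from a
#' dedicated counter-based stream, so expert noise is reproducible and
#' independent of all other randomness; with `sigma_eps = 0` the expert is
#' exactly the oracle.
#'
#' @param oracle an [oracle()].
#' @param sigma_eps noise standard deviation, `>= 0`.
#' @param clip clip outputs to \[0, 1\] (classification experts)?
#' @param seed integer seed of the expert's noise stream.
#' @return an object of class `expert_model`.
#' @export
expert_model <- function(oracle, sigma_eps = 0, clip = FALSE, seed = 1L) {
  stopifnot(inherits(oracle, "oracle"))
  if (sigma_eps < 0) stop_molhitl("sigma_eps must be >= 0")
  state <- new.env(parent = emptyenv())
  state$counter <- 0L
  state$n_queries <- 0L
  structure(list(oracle = oracle, sigma_eps = sigma_eps, clip = isTRUE(clip),
                 seed = as.integer(seed), state = state),
            class = "expert_model")
}

#' Query a simulated expert
#'
#' Evaluates the expert's oracle, adds seeded Gaussian noise, and clips to
#' \[0, 1\] when the expert is a classification-style (agreement) expert. The
#' noise stream position advances by one per molecule queried.
#'
#' @param expert an [expert_model()].
#' @param smiles character vector of query SMILES.
#' @return numeric vector: noisy oracle values (regression) or agreement
#'   scores in \[0, 1\] (clipped experts).
#' @export
query_expert <- function(expert, smiles) {
  stopifnot(inherits(expert, "expert_model"))
  vals <- expert$oracle$fn(smiles)
  idx <- expert$state$counter + seq_along(smiles)
  expert$state$counter <- expert$state$counter + length(smiles)
  expert$state$n_queries <- expert$state$n_queries + length(smiles)
  if (expert$sigma_eps > 0)
    vals <- vals + expert$sigma_eps * rnorm_stream(expert$seed, idx)
  if (expert$clip) vals <- pmin(pmax(vals, 0), 1)
  vals
}

#' @rdname query_expert
#' @export
simulate_regression_expert <- function(expert, smiles) {
  if (expert$clip) stop_molhitl("regression experts must have clip = FALSE")
  query_expert(expert, smiles)
}

#' @rdname query_expert
#' @export
simulate_classification_expert <- function(expert, smiles) {
  if (!expert$clip) stop_molhitl("classification experts must have clip = TRUE")
  if (expert$oracle$range != "unit")
    stop_molhitl("classification experts need an oracle with outputs in [0, 1]")
  query_expert(expert, smiles)
}

#' Convert agreement scores into feedback labels and confidences
#'
#' Classification: the agreement slider `a` in \[0, 1\] yields label
#' `h = 1` iff `a >= 0.5`, with confidence `u = a` when agreeing and
#' `u = 1 - a` when disagreeing (so `u = max(a, 1 - a)`; e.g. agreement 40%
#' gives label 0 with confidence 60%). The tie `a = 0.5` maps to `h = 1` with
#' the minimal confidence 0.5, so the choice is nearly inert in retraining.
#' Regression: the expert's (noisy) value estimate is used directly as the
#' label with unit confidence.
#'
#' @param agreement numeric vector: agreement scores in \[0, 1\]
#'   (classification) or value estimates (regression).
#' @param task `"classification"` or `"regression"`.
#' @return data.frame with columns `agreement`, `label` (`h_t`) and
#'   `confidence` (`u_t`).
#' @export
agreement_to_feedback <- function(agreement, task = c("classification", "regression")) {
  task <- match.arg(task)
  if (task == "classification") {
    if (any(agreement < 0 | agreement > 1))
      stop_molhitl("agreement scores must lie in [0, 1]")
    label <- as.integer(agreement >= 0.5)
    confidence <- ifelse(label == 1L, agreement, 1 - agreement)
  } else {
    label <- agreement
    confidence <- rep(1, length(agreement))
  }
  data.frame(agreement = agreement, label = label, confidence = confidence)
}

#' Feedback CSV round-trip
#'
#' Supports real-human feedback without a GUI: write the queried molecules
#' with their predicted scores, collect an `agreement` column offline, read it
#' back.
#'
#' @param smiles queried molecules.
#' @param predicted_score their predicted scores at query time.
#' @param path CSV path.
#' @export
write_feedback_csv <- function(smiles, predicted_score, path) {
  utils::write.csv(data.frame(smiles = smiles, predicted_score = predicted_score,
                              agreement = NA_real_),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feedback_csv
#' @export
read_feedback_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("smiles", "agreement")
  if (!all(need %in% names(df)))
    stop_molhitl("feedback CSV needs columns: %s", paste(need, collapse = ", "))
  df
}
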