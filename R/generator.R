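# Generator contract: a proposal agent, the policy-gradient loss of the
# SMILES-RNN generator (as a pure function), the diversity-filter scaffold
# memory, and pool construction.
#
# The full RNN generator is out of scope; a library-reweighting agent stands
# in: it samples proposals from a fixed molecule library with probabilities
# proportional to adaptive weights and sharpens them multiplicatively toward
# high scores. The contract (propose / update / log-likelihoods, frozen prior)
# is what a real sequence generator would plug into.

#' Library-reweighting generator agent
#'
#' @param library character vector of (unique) SMILES the agent can propose.
#' @param weights optional initial proposal weights (default uniform); frozen
#'   as the prior.
#' @return an object of class `generator_agent` with fields `library`,
#'   `weights` (current state psi) and `prior` (frozen psi_0).
#' @export
generator_agent <- function(library, weights = NULL) {
  library <- canonicalize(library)
  if (anyDuplicated(library)) stop_molhitl("agent library must be unique")
  w <- weights %||% rep(1, length(library))
  if (length(w) != length(library) || any(w <= 0))
    stop_molhitl("weights must be positive and aligned with the library")
  w <- w / sum(w)
  structure(list(library = library, weights = w, prior = w),
            class = "generator_agent")
}

#' Agent / prior log-likelihood of molecules
#'
#' @param agent a [generator_agent()].
#' @param smiles molecules from the agent's library.
#' @param prior evaluate under the frozen prior instead of the current state?
#' @return numeric vector of log probabilities.
#' @export
agent_loglik <- function(agent, smiles, prior = FALSE) {
  idx <- match(canonicalize(smiles), agent$library)
  if (anyNA(idx)) stop_molhitl("molecule not in the agent's library")
  log((if (prior) agent$prior else agent$weights)[idx])
}

#' Policy-gradient generator loss
#'
#' The squared disagreement between the score-augmented prior log-likelihood
#' and the agent log-likelihood, averaged over the proposal batch:
#' `mean((prior + lambda * score - agent)^2)` under the augmented-likelihood
#' sign convention (maximizing reward raises the target likelihood). The
#' printed form with `prior - lambda * score` is available via
#' `sign = "printed"`.
#'
#' @param prior_loglik,agent_loglik,scores equal-length numeric vectors;
#'   scores in \[0, 1\].
#' @param lambda positive reward scale (128 mono-objective, 180
#'   multi-objective by convention).
#' @param sign `"augmented"` (default) or `"printed"`.
#' @return nonnegative batch-mean loss.
#' @export
reinvent_loss <- function(prior_loglik, agent_loglik, scores, lambda = 128,
                          sign = c("augmented", "printed")) {
  sign <- match.arg(sign)
  if (length(prior_loglik) != length(agent_loglik) ||
      length(prior_loglik) != length(scores))
    stop_molhitl("prior_loglik, agent_loglik and scores must have equal length")
  if (!length(scores)) stop_molhitl("empty batch")
  if (lambda <= 0) stop_molhitl("lambda must be positive")
  s <- if (sign == "augmented") lambda * scores else -lambda * scores
  mean((prior_loglik + s - agent_loglik)^2)
}

#' Propose a batch of molecules
#'
#' Seeded draw of `P` molecules (with replacement) with probability
#' proportional to the agent's current weights.
#'
#' @param agent a [generator_agent()].
#' @param P batch size (>= 0).
#' @param seed integer seed.
#' @return character vector of `P` canonical SMILES.
#' @export
propose_batch <- function(agent, P, seed = 1L) {
  P <- as.integer(P)
  if (is.na(P) || P < 0L) stop_molhitl("P must be >= 0")
  if (P == 0L) return(character(0))
  if (!length(agent$library)) stop_molhitl("agent library is empty")
  idx <- sample_stream(length(agent$library), P, derive_seed(seed, 6131),
                       replace = TRUE, prob = agent$weights)
  agent$library[idx]
}

#' Update the agent toward high-scoring proposals
#'
#' Multiplicative-weights step: `w(x) <- w(x) * exp(eta * s(x))` for every
#' batch member (applied once per occurrence), then renormalized. The frozen
#' prior is never modified; with a static scorer, repeated updates make the
#' expected proposal score nondecreasing.
#'
#' @param agent a [generator_agent()].
#' @param smiles proposed batch members.
#' @param scores their total scores in \[0, 1\].
#' @param eta nonnegative learning rate.
#' @return the updated `generator_agent`.
#' @export
update_agent <- function(agent, smiles, scores, eta = 1) {
  if (length(smiles) != length(scores)) stop_molhitl("smiles/scores length mismatch")
  if (eta < 0) stop_molhitl("eta must be >= 0")
  if (any(scores < 0 | scores > 1)) stop_molhitl("scores must lie in [0, 1]")
  if (!length(smiles) || eta == 0) return(agent)
  idx <- match(smiles, agent$library)
  if (anyNA(idx)) stop_molhitl("molecule not in the agent's library")
  bump <- tapply(scores, idx, sum)
  at <- as.integer(names(bump))
  w <- agent$weights
  w[at] <- w[at] * exp(eta * as.numeric(bump))
  agent$weights <- w / sum(w)
  agent
}

# ---- diversity-filter memory ------------------------------------------------

#' Diversity-filter scaffold memory
#'
#' Stores high-scoring molecules in scaffold-keyed buckets: a molecule is
#' accepted only if its total score reaches the threshold, its canonical
#' SMILES is not already stored, and its scaffold bucket is below capacity.
#' Once a bucket is full, further molecules with that scaffold are rejected,
#' discouraging the generator from collapsing onto one ring system.
#'
#' @param capacity per-bucket capacity.
#' @param score_threshold minimum total score for storage.
#' @return an object of class `memory_buckets`.
#' @export
memory_buckets <- function(capacity = 25L, score_threshold = 0.4) {
  structure(list(buckets = list(), capacity = as.integer(capacity),
                 score_threshold = score_threshold),
            class = "memory_buckets")
}

#' Add a scored molecule to the memory
#'
#' @param mem a [memory_buckets()].
#' @param scored one-row data.frame from [score_molecules()] (columns `smiles`,
#'   component scores, `total`).
#' @return list with fields `memory` (updated), `accepted` (logical) and
#'   `reason` (`"accepted"`, `"low_score"`, `"duplicate"` or `"bucket_full"`).
#' @export
memory_add <- function(mem, scored) {
  stopifnot(inherits(mem, "memory_buckets"), is.data.frame(scored),
            nrow(scored) == 1L)
  if (scored$total < mem$score_threshold)
    return(list(memory = mem, accepted = FALSE, reason = "low_score"))
  key <- scaffold_key(scored$smiles)
  bucket <- mem$buckets[[key]]
  if (!is.null(bucket)) {
    if (scored$smiles %in% bucket$smiles)
      return(list(memory = mem, accepted = FALSE, reason = "duplicate"))
    if (nrow(bucket) >= mem$capacity)
      return(list(memory = mem, accepted = FALSE, reason = "bucket_full"))
  }
  row <- cbind(scored, scaffold = key, stringsAsFactors = FALSE)
  mem$buckets[[key]] <- if (is.null(bucket)) row else rbind(bucket, row)
  list(memory = mem, accepted = TRUE, reason = "accepted")
}

# batch variant used by the generation loop; returns per-row reasons so the
# diversity filter can zero the reward of duplicate / bucket-full proposals
memory_add_batch <- function(mem, scored) {
  reasons <- character(nrow(scored))
  for (i in seq_len(nrow(scored))) {
    res <- memory_add(mem, scored[i, , drop = FALSE])
    mem <- res$memory
    reasons[i] <- res$reason
  }
  list(memory = mem, accepted = sum(reasons == "accepted"), reasons = reasons)
}

#' All molecules currently stored in memory
#'
#' @param mem a [memory_buckets()].
#' @return data.frame (possibly zero rows) of stored scored molecules.
#' @export
memory_molecules <- function(mem) {
  stopifnot(inherits(mem, "memory_buckets"))
  if (!length(mem$buckets)) return(NULL)
  out <- do.call(rbind, mem$buckets)
  rownames(out) <- NULL
  out
}

#' Build the acquisition pool from memory
#'
#' Deduplicated memory contents, optionally filtered on a named predictor
#' component score (multi-objective mode keeps only molecules whose component
#' score exceeds `min_component_score`; mono-objective mode applies no
#' component filter since the memory threshold already selects high scorers).
#'
#' @param mem a [memory_buckets()].
#' @param component optional component (column) name to filter on.
#' @param min_component_score strict lower cutoff for that component.
#' @return data.frame of pool molecules (zero rows when the pool is empty;
#'   callers skip the AL round with a warning).
#' @export
build_pool <- function(mem, component = NULL, min_component_score = 0.5) {
  mols <- memory_molecules(mem)
  if (is.null(mols) || !nrow(mols)) {
    out <- data.frame(smiles = character(0), total = numeric(0))
    return(out)
  }
  mols <- mols[!duplicated(mols$smiles), , drop = FALSE]
  if (!is.null(component)) {
    if (!component %in% names(mols))
      stop_molhitl("no component score named '%s' in memory", component)
    mols <- mols[mols[[component]] > min_component_score, , drop = FALSE]
  }
  rownames(mols) <- NULL
  mols
}
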