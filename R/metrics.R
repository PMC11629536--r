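# Distribution-learning evaluation metrics (benchmark-style): MAE against the
# oracle, internal diversity, nearest-neighbour similarity (SNN), fragment
# profile cosine similarity, novelty, uniqueness, mean SA and drug-likeness.

# fragment profile: cut every acyclic single (non-aromatic) bond, canonical
# fragment SMILES counts
fragment_profile <- function(smiles) {
  counts <- list()
  for (s in smiles) {
    mol <- mol_of(s)
    keep <- mol$ring_bond | mol$barom | mol$border > 1L
    comp <- graph_components(length(mol$elem), mol$bfrom[keep], mol$bto[keep])
    for (g in unique(comp)) {
      frag <- write_canonical(mol_subgraph(mol, which(comp == g)))
      counts[[frag]] <- (counts[[frag]] %||% 0) + 1
    }
  }
  unlist(counts)
}

cosine_profiles <- function(a, b) {
  keys <- union(names(a), names(b))
  va <- ifelse(keys %in% names(a), a[keys], 0)
  vb <- ifelse(keys %in% names(b), b[keys], 0)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  sum(va * vb) / (na * nb)
}

#' Evaluation metrics for a generated molecule set
#'
#' Computes, following distribution-benchmark conventions: mean absolute error
#' between predicted and oracle values (when a predictor is supplied);
#' internal diversity `1 - mean pairwise Tanimoto` (diagonal included);
#' `SNN` = mean nearest-neighbour Tanimoto from generated to reference
#' molecules; `Frag` = cosine similarity of fragment-count profiles; novelty =
#' fraction of generated molecules absent from the training set; uniqueness =
#' fraction of distinct canonical SMILES; mean SA and mean drug-likeness.
#' Query-relative similarity metrics (`snn_queries`, `frag_queries`) are added
#' when `queries` is supplied.
#'
#' @param generated character vector of generated SMILES (nonempty).
#' @param train character vector of training-set SMILES.
#' @param queries optional character vector of expert-queried SMILES.
#' @param oracle an [oracle()] providing ground-truth values.
#' @param predictor optional fitted `rf_ensemble` for the MAE.
#' @param cfg a [fingerprint_config()].
#' @return one-row data.frame of metrics.
#' @export
evaluate_metrics <- function(generated, train, queries = NULL, oracle = NULL,
                             predictor = NULL, cfg = fingerprint_config()) {
  if (!length(generated)) stop_molhitl("empty generated set")
  gen <- canonicalize(generated)
  trn <- canonicalize(train)
  Fg <- fingerprint_matrix(gen, cfg)
  sim_gg <- tanimoto_cross(Fg, Fg)
  out <- data.frame(
    n = length(gen),
    int_div = 1 - mean(sim_gg),
    novelty = mean(!gen %in% trn),
    uniqueness = length(unique(gen)) / length(gen),
    sa = mean(sa_score(gen)),
    qed = mean(qed_score(gen))
  )
  if (length(trn)) {
    sim_gt <- tanimoto_cross(Fg, fingerprint_matrix(trn, cfg))
    out$snn_train <- mean(apply(sim_gt, 1L, max))
    out$frag_train <- cosine_profiles(fragment_profile(gen), fragment_profile(trn))
  }
  if (!is.null(queries) && length(queries)) {
    q <- canonicalize(queries)
    sim_gq <- tanimoto_cross(Fg, fingerprint_matrix(q, cfg))
    out$snn_queries <- mean(apply(sim_gq, 1L, max))
    out$frag_queries <- cosine_profiles(fragment_profile(gen), fragment_profile(q))
  }
  if (!is.null(predictor) && !is.null(oracle))
    out$mae <- mean(abs(predict(predictor, gen) - oracle$fn(gen)))
  out
}
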