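# End-to-end orchestration: alternating generation cycles and active-learning
# rounds. Each round r runs N_steps proposal/score/update steps (filling the
# diversity-filter memory M_r), builds the pool U_r of high-scoring molecules,
# acquires L batches of T expert queries (re-scoring acquisitions against the
# current predictor each iteration), fine-tunes the predictor on all feedback,
# and swaps the updated predictor into the scoring function for the next
# round. A no-feedback twin runs identical generation cycles with the
# predictor frozen.

#' Experiment configuration
#'
#' Bundles every knob of a run. The defaults are a desk-scale profile: a
#' 5000-molecule fixture library, 200 initial training molecules, proposal
#' batches of 128 over 40 steps per cycle, 3 rounds with 2 AL iterations of 10
#' queries each, and a reduced fingerprint (radius 2, 512 positions) and
#' forest (64 trees) for speed; reference-scale values (radius 3 / 2048, 300
#' or 200 trees, 250 steps, L = 5) are configuration choices away.
#'
#' @param task `"regression"` or `"classification"`.
#' @param acquisition `"epig"`, `"uncertainty"`, `"greedy"` or `"random"`.
#' @param R rounds (>= 0); `n_steps` generation steps per cycle; `P` proposal
#'   batch size; `L` AL iterations per round; `T` query batch size; `top_k`
#'   target-distribution size (capped at the pool).
#' @param lambda reward scale of the generator loss (logged; the stand-in
#'   agent itself uses `eta`).
#' @param eta multiplicative-weights learning rate of the stand-in agent.
#' @param library_size,n0 fixture library size and initial labeled-set size.
#' @param d0_scaffolds optional: number of distinct scaffold keys the initial
#'   data is drawn from (`NULL`, the default, samples D0 from the whole
#'   library, as in the regression reference setup). Restricting D0 to a few
#'   scaffold families models the low-diversity assay sets of early
#'   bioactivity projects.
#' @param fingerprint a [fingerprint_config()].
#' @param forest list: `ntree`, `max_depth`, `min_split`, `mtry` (NULL = task
#'   default).
#' @param oracle an [oracle()]; default: a synthetic fingerprint-linear oracle
#'   drawn from `oracle_seed` (bias 2, 5% density), sigmoided for
#'   classification.
#' @param oracle_seed seed fixing the default oracle (part of the stated
#'   world, not varied across replicate seeds).
#' @param delta label threshold for classification (`y = 1` iff `f* > delta`).
#' @param transform the predictor component's [transform_spec()]; default
#'   double sigmoid over \[2, 4\] (regression) or identity (classification).
#' @param sigma_eps simulated expert noise sd; `clip` clips expert outputs to
#'   \[0, 1\] (classification experts).
#' @param memory_capacity,memory_threshold diversity-filter parameters.
#' @param pool_component,pool_cutoff optional component filter for the pool
#'   (multi-objective mode).
#' @param extra_components list of additional [scoring_component()]s.
#' @param no_feedback run the baseline twin (no expert, frozen predictor)?
#' @param top_eval pool size for the round MAE (top molecules by predicted
#'   score).
#' @param seeds named list of integer seeds: `generator`, `forest`, `expert`,
#'   `acquisition`, `library`.
#' @return an object of class `loop_config`.
#' @export
loop_config <- function(task = c("regression", "classification"),
                        acquisition = c("epig", "uncertainty", "greedy", "random"),
                        R = 3L, n_steps = 40L, P = 128L, L = 2L, T = 10L,
                        top_k = 1000L, lambda = 128, eta = 2,
                        library_size = 5000L, n0 = 200L, d0_scaffolds = NULL,
                        fingerprint = fingerprint_config(radius = 2L, length = 512L),
                        forest = list(ntree = 64L, max_depth = 16L,
                                      min_split = 2L, mtry = NULL),
                        oracle = NULL, oracle_seed = 42L, delta = 0.5,
                        transform = NULL, sigma_eps = 0, clip = NULL,
                        memory_capacity = 25L, memory_threshold = 0.4,
                        pool_component = NULL, pool_cutoff = 0.5,
                        extra_components = list(), no_feedback = FALSE,
                        top_eval = 100L,
                        seeds = list()) {
  task <- match.arg(task)
  acquisition <- match.arg(acquisition)
  R <- as.integer(R); n_steps <- as.integer(n_steps); P <- as.integer(P)
  L <- as.integer(L); T <- as.integer(T)
  if (R < 0L) stop_molhitl("R must be >= 0")
  if (n_steps < 1L) stop_molhitl("n_steps must be >= 1")
  if (T < 1L) stop_molhitl("T must be >= 1")
  if (L < 1L) stop_molhitl("L must be >= 1")
  if (P < 1L) stop_molhitl("P must be >= 1")
  if (n0 < 2L) stop_molhitl("n0 must be >= 2")
  seeds <- utils::modifyList(list(generator = 1L, forest = 2L, expert = 3L,
                                  acquisition = 4L, library = 7L), seeds)
  if (is.null(transform))
    transform <- if (task == "regression")
      transform_spec("double_sigmoid", low = 2, high = 4, steepness = 10)
    else transform_spec("identity")
  if (is.null(clip)) clip <- task == "classification"
  if (is.null(oracle)) {
    # weight support dense enough that every molecule's fingerprint overlaps
    # it (a property oracle constant on part of chemical space is degenerate),
    # scaled to a penalized-LogP-like spread over the library (sd ~ 1.4) so
    # the configured expert noise levels are meaningful relative to signal
    w <- random_linear_weights(oracle_seed, fingerprint, density = 0.25, sd = 0.6)
    oracle <- synthetic_linear_oracle(w, bias = 2,
                                      sigmoided = task == "classification",
                                      cfg = fingerprint)
  }
  stopifnot(inherits(oracle, "oracle"), inherits(transform, "transform"))
  structure(list(task = task, acquisition = acquisition, R = R,
                 n_steps = n_steps, P = P, L = L, T = T, top_k = as.integer(top_k),
                 lambda = lambda, eta = eta,
                 library_size = as.integer(library_size), n0 = as.integer(n0),
                 d0_scaffolds = if (!is.null(d0_scaffolds)) as.integer(d0_scaffolds),
                 fingerprint = fingerprint, forest = forest, oracle = oracle,
                 oracle_seed = oracle_seed, delta = delta, transform = transform,
                 sigma_eps = sigma_eps, clip = clip,
                 memory_capacity = as.integer(memory_capacity),
                 memory_threshold = memory_threshold,
                 pool_component = pool_component, pool_cutoff = pool_cutoff,
                 extra_components = extra_components,
                 no_feedback = isTRUE(no_feedback),
                 top_eval = as.integer(top_eval), seeds = seeds),
            class = "loop_config")
}

# serializable echo of a config (closures replaced by their labels)
config_echo <- function(cfg) {
  list(task = cfg$task, acquisition = cfg$acquisition, R = cfg$R,
       n_steps = cfg$n_steps, P = cfg$P, L = cfg$L, T = cfg$T,
       top_k = cfg$top_k, lambda = cfg$lambda, eta = cfg$eta,
       library_size = cfg$library_size, n0 = cfg$n0,
       d0_scaffolds = cfg$d0_scaffolds,
       fingerprint = unclass(cfg$fingerprint),
       forest = cfg$forest[!vapply(cfg$forest, is.null, logical(1))],
       oracle = cfg$oracle$kind, oracle_seed = cfg$oracle_seed,
       delta = cfg$delta, transform = unclass(cfg$transform),
       sigma_eps = cfg$sigma_eps, clip = cfg$clip,
       memory_capacity = cfg$memory_capacity,
       memory_threshold = cfg$memory_threshold,
       pool_component = cfg$pool_component, pool_cutoff = cfg$pool_cutoff,
       no_feedback = cfg$no_feedback, top_eval = cfg$top_eval,
       seeds = cfg$seeds)
}

#' Run one generation cycle
#'
#' `n_steps` iterations of propose -> score -> memory add -> agent update
#' against a static scoring function.
#'
#' @param agent a [generator_agent()].
#' @param sf a [scoring_function()].
#' @param mem a [memory_buckets()].
#' @param n_steps,P steps and proposal batch size.
#' @param eta agent learning rate.
#' @param seed integer seed.
#' @param round round index recorded in the step log.
#' @param predictor_component name of the predictor component tracked in the
#'   step log (NULL: track `total` only).
#' @return list: `agent`, `memory`, `steps` (per-step log data.frame).
#' @export
run_generation_cycle <- function(agent, sf, mem, n_steps, P, eta = 2, seed = 1L,
                                 round = 1L, predictor_component = NULL) {
  steps <- vector("list", n_steps)
  for (step in seq_len(n_steps)) {
    batch <- propose_batch(agent, P, derive_seed(seed, round, step))
    scored <- score_molecules(sf, batch)
    added <- memory_add_batch(mem, scored)
    mem <- added$memory
    # reward gating by the diversity filter: only proposals newly accepted
    # into memory earn their score. Duplicates and full buckets earn zero
    # (discouraging collapse onto harvested scaffolds); sub-threshold
    # proposals earn zero too, which keeps the multiplicative-weights agent
    # stationary where an RNN agent's regression-to-augmented-prior loss
    # would be (unbounded per-occurrence compounding otherwise)
    reward <- ifelse(added$reasons == "accepted", scored$total, 0)
    agent <- update_agent(agent, scored$smiles, reward, eta)
    steps[[step]] <- data.frame(
      round = round, step = step,
      mean_total = mean(scored$total),
      mean_pred_score = if (!is.null(predictor_component))
        mean(scored[[predictor_component]]) else NA_real_,
      accepted = added$accepted)
  }
  list(agent = agent, memory = mem, steps = do.call(rbind, steps))
}

# MAE of the current predictor against the oracle on the top molecules of a
# pool (ranked by transformed predicted score). Molecules already queried are
# excluded: they are training data, and the quantity tracked is generalization
# to new high-scoring molecules (at reference scale generated molecules are
# novel by construction; a small combinatorial library re-proposes them).
pool_mae <- function(predictor, pool_smiles, cfg, exclude = character(0)) {
  pool_smiles <- setdiff(pool_smiles, exclude)
  if (!length(pool_smiles)) return(NA_real_)
  pred <- predict(predictor, pool_smiles)
  sc <- apply_transform(cfg$transform, pred)
  ord <- order(-sc, pool_smiles, method = "radix")
  top <- pool_smiles[ord][seq_len(min(cfg$top_eval, length(pool_smiles)))]
  mean(abs(predict(predictor, top) - cfg$oracle$fn(top)))
}

acquisition_scores <- function(cfg, predictor, pool_smiles) {
  tr <- if (predictor$task == "regression") cfg$transform else NULL
  pred <- predict(predictor, pool_smiles)
  tscore <- apply_transform(cfg$transform, pred)
  switch(cfg$acquisition,
    epig = {
      target <- target_distribution(pool_smiles, tscore, cfg$top_k,
                                    degenerate = "uniform")
      epig_scores(predictor, pool_smiles, target, tr)
    },
    uncertainty = uncertainty_scores(predictor, pool_smiles),
    greedy = greedy_scores(pool_smiles, tscore),
    random = stats::setNames(rep(0, length(pool_smiles)), pool_smiles))
}

#' Run one active-learning round
#'
#' `L` iterations of acquire -> expert evaluation -> feedback conversion ->
#' confidence-weighted fine-tune. Acquisition scores are recomputed against
#' the current predictor at every iteration; molecules queried earlier in the
#' run are never re-queried.
#'
#' @param pool_smiles pool U_r (character vector of SMILES).
#' @param predictor current `rf_ensemble`.
#' @param expert an [expert_model()].
#' @param initial the initial [labeled_set()].
#' @param cfg a [loop_config()].
#' @param round round index.
#' @param acquired previously acquired batches (list of labeled sets).
#' @param queried previously queried SMILES.
#' @return list: `predictor`, `acquired`, `queried`, `n_finetunes`,
#'   `queries` (data.frame log of this round's queries).
#' @export
run_al_round <- function(pool_smiles, predictor, expert, initial, cfg,
                         round = 1L, acquired = list(), queried = character(0)) {
  n_finetunes <- 0L
  qlog <- list()
  for (l in seq_len(cfg$L)) {
    remaining <- setdiff(pool_smiles, queried)
    if (!length(remaining)) break
    scores <- acquisition_scores(cfg, predictor, pool_smiles)
    sel <- select_batch(scores, cfg$T, cfg$acquisition,
                        seed = derive_seed(cfg$seeds$acquisition, round, l),
                        exclude = queried)
    if (!length(sel$batch)) break
    predicted <- predict(predictor, sel$batch)
    agreement <- query_expert(expert, sel$batch)
    fb <- agreement_to_feedback(agreement, cfg$task)
    batch_set <- labeled_set(sel$batch, fb$label, fb$confidence,
                             origin = "acquired")
    acquired <- c(acquired, list(batch_set))
    queried <- c(queried, sel$batch)
    predictor <- fine_tune(predictor, initial, acquired,
                           seed = derive_seed(cfg$seeds$forest, round, l))
    n_finetunes <- n_finetunes + 1L
    qlog[[l]] <- data.frame(round = round, iteration = l, smiles = sel$batch,
                            predicted = predicted, agreement = agreement,
                            label = fb$label, confidence = fb$confidence)
  }
  list(predictor = predictor, acquired = acquired, queried = queried,
       n_finetunes = n_finetunes,
       queries = if (length(qlog)) do.call(rbind, qlog) else NULL)
}

#' Run a full experiment
#'
#' Fits the initial predictor on oracle-labeled molecules, then alternates
#' generation cycles and active-learning rounds for `R` rounds (Algorithm-1
#' style); with `no_feedback = TRUE` the expert is never queried and the
#' predictor never refit.
#'
#' @param cfg a [loop_config()].
#' @return an object of class `hitl_run`: step and round logs, query log,
#'   final predictor / agent / memory, and provenance (config echo and seeds).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "loop_config"))
  lib <- fixture_library(cfg$seeds$library, cfg$library_size)
  d0_candidates <- lib
  if (!is.null(cfg$d0_scaffolds)) {
    # limited-diversity initial data: the largest few scaffold families,
    # mirroring assay sets restricted to a handful of chemical series
    keys <- scaffold_key(lib)
    tab <- table(keys)
    sizes <- as.integer(tab); nms <- names(tab)
    ord <- order(-sizes, nms, method = "radix")
    top <- nms[ord][seq_len(min(cfg$d0_scaffolds, length(nms)))]
    d0_candidates <- lib[keys %in% top]
    if (length(d0_candidates) < cfg$n0)
      stop_molhitl("only %d molecules in the %d largest scaffold families; reduce n0 or raise d0_scaffolds",
                   length(d0_candidates), cfg$d0_scaffolds)
  }
  d0_smiles <- d0_candidates[sample_stream(length(d0_candidates), cfg$n0,
                                           derive_seed(cfg$seeds$library, 11))]
  truth <- cfg$oracle$fn(d0_smiles)
  labels <- if (cfg$task == "classification") binary_labels(truth, cfg$delta)
            else truth
  if (cfg$task == "classification" && length(unique(labels)) < 2L)
    stop_molhitl("initial data has a single class; adjust delta or the oracle")
  d0 <- labeled_set(d0_smiles, labels)
  predictor <- fit_initial(d0, cfg$task, cfg$fingerprint,
                           ntree = cfg$forest$ntree,
                           max_depth = cfg$forest$max_depth,
                           min_split = cfg$forest$min_split,
                           mtry = cfg$forest$mtry,
                           seed = cfg$seeds$forest)
  comps <- c(list(scoring_component("property", "predictor", weight = 1,
                                    transform = cfg$transform,
                                    predictor = predictor)),
             cfg$extra_components)
  sf <- scoring_function(comps, cfg$fingerprint)
  agent <- generator_agent(lib)
  expert <- expert_model(cfg$oracle, cfg$sigma_eps, cfg$clip, cfg$seeds$expert)

  steps <- list(); rounds <- list(); qlogs <- list()
  acquired <- list(); queried <- character(0)
  n_finetunes <- 0L
  final_mem <- memory_buckets(cfg$memory_capacity, cfg$memory_threshold)

  for (r in seq_len(cfg$R)) {
    mem <- memory_buckets(cfg$memory_capacity, cfg$memory_threshold)
    gen <- run_generation_cycle(agent, sf, mem, cfg$n_steps, cfg$P,
                                eta = cfg$eta,
                                seed = cfg$seeds$generator, round = r,
                                predictor_component = "property")
    agent <- gen$agent
    final_mem <- gen$memory
    steps[[r]] <- gen$steps
    pool <- build_pool(gen$memory, cfg$pool_component, cfg$pool_cutoff)
    mae_pre <- pool_mae(predictor, pool$smiles, cfg, exclude = queried)
    nq <- 0L
    if (!nrow(pool)) {
      warning(sprintf("round %d: empty pool, AL round skipped", r))
    } else if (!cfg$no_feedback) {
      al <- run_al_round(pool$smiles, predictor, expert, d0, cfg, r,
                         acquired, queried)
      nq <- length(al$queried) - length(queried)
      predictor <- al$predictor
      acquired <- al$acquired
      queried <- al$queried
      n_finetunes <- n_finetunes + al$n_finetunes
      if (!is.null(al$queries)) qlogs[[r]] <- al$queries
      sf <- swap_predictor(sf, "property", predictor)
    }
    rounds[[r]] <- data.frame(round = r, pool_size = nrow(pool),
                              n_queries = nq,
                              mae_pre = mae_pre,
                              mae_post = pool_mae(predictor, pool$smiles, cfg,
                                                  exclude = queried))
  }

  structure(list(
    config = config_echo(cfg),
    steps = if (length(steps)) do.call(rbind, steps) else NULL,
    rounds = if (length(rounds)) do.call(rbind, rounds) else NULL,
    queries = if (length(qlogs)) do.call(rbind, qlogs) else NULL,
    initial = d0, acquired = acquired,
    predictor = predictor, agent = agent, memory = final_mem,
    expert_calls = expert$state$n_queries, n_finetunes = n_finetunes),
    class = "hitl_run")
}
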