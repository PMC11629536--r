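# End-to-end loop: determinism, conservation, baseline contract, metrics,
# reporting. Small configurations keep the suite fast; the full desk-scale
# parameter-recovery runs live in the acceptance suite.

tiny_cfg <- function(...) {
  defaults <- list(R = 2, n_steps = 8, P = 32, L = 2, T = 4,
                   library_size = 400, n0 = 60, memory_threshold = 0.3)
  do.call(loop_config, utils::modifyList(defaults, list(...)))
}

test_that("R = 0 leaves the predictor at its initial fit with no AL records", {
  cfg <- tiny_cfg(R = 0)
  run <- run_experiment(cfg)
  expect_null(run$rounds)
  expect_null(run$steps)
  expect_identical(run$expert_calls, 0L)
  expect_identical(run$n_finetunes, 0L)
  ref <- fit_initial(run$initial, cfg$task, cfg$fingerprint,
                     ntree = cfg$forest$ntree, max_depth = cfg$forest$max_depth,
                     min_split = cfg$forest$min_split, mtry = cfg$forest$mtry,
                     seed = cfg$seeds$forest)
  probe <- fixture_library(2, 20)
  expect_identical(predict(run$predictor, probe, type = "tree"),
                   predict(ref, probe, type = "tree"))
})

test_that("identical configs and seeds reproduce the run log byte-for-byte", {
  cfg <- tiny_cfg(seeds = list(generator = 5, forest = 6, expert = 7,
                               acquisition = 8))
  j1 <- runlog_json(run_experiment(cfg))
  j2 <- runlog_json(run_experiment(cfg))
  expect_identical(j1, j2)
})

test_that("the no-feedback baseline never queries the expert nor refits", {
  run <- run_experiment(tiny_cfg(no_feedback = TRUE))
  expect_identical(run$expert_calls, 0L)
  expect_identical(run$n_finetunes, 0L)
  expect_true(all(run$rounds$n_queries == 0L))
  expect_true(all(run$rounds$mae_pre == run$rounds$mae_post))
  expect_length(run$acquired, 0L)
})

test_that("acquired data is conserved: |D_R| = N0 + sum of batch sizes, no re-queries", {
  run <- run_experiment(tiny_cfg())
  batch_sizes <- vapply(run$acquired, nrow, integer(1))
  expect_identical(sum(run$rounds$n_queries), sum(batch_sizes))
  all_queried <- unlist(lapply(run$acquired, `[[`, "smiles"))
  # every acquired molecule appears exactly once across the run
  expect_identical(anyDuplicated(all_queried), 0L)
  expect_identical(nrow(run$initial) + length(all_queried),
                   nrow(run$initial) + sum(batch_sizes))
  # L = 2, T = 4 per round, pool permitting: at most 8 distinct per round
  expect_true(all(run$rounds$n_queries <= 8L))
  # final predictor was trained on exactly the initial union acquired data
  expect_identical(nrow(run$predictor$training$initial), nrow(run$initial))
  expect_identical(sum(vapply(run$predictor$training$acquired, nrow, integer(1))),
                   sum(batch_sizes))
})

test_that("query batches larger than the pool yield short batches, not errors", {
  run <- run_experiment(tiny_cfg(T = 500, L = 1, library_size = 300, n0 = 50))
  expect_true(all(run$rounds$n_queries <= run$rounds$pool_size))
  expect_gt(sum(run$rounds$n_queries), 0L)
})

test_that("run logs serialize and reload losslessly", {
  run <- run_experiment(tiny_cfg())
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  runlog_save(run, p1)
  rec <- runlog_load(p1)
  expect_equal(rec$rounds$mae_post, run$rounds$mae_post)
  expect_identical(rec$config$acquisition, run$config$acquisition)
  # re-serializing the loaded record reproduces the file
  writeLines(as.character(jsonlite::toJSON(rec, digits = NA, na = "null",
                                           auto_unbox = TRUE,
                                           dataframe = "columns", null = "null")),
             p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("evaluation metrics match their defining identities", {
  lib <- fixture_library(19, 40)
  train <- lib[1:20]
  cfg <- small_fp_cfg()
  # generated == train: SNN 1, novelty 0, uniqueness 1
  m <- evaluate_metrics(train, train, cfg = cfg)
  expect_equal(m$snn_train, 1.0)
  expect_equal(m$novelty, 0.0)
  expect_equal(m$uniqueness, 1.0)
  expect_equal(m$frag_train, 1.0)
  expect_true(m$int_div >= 0 && m$int_div <= 1)
  # all distinct -> uniqueness 1; duplicates lower it
  m2 <- evaluate_metrics(c(train, train[1]), train[1:5], cfg = cfg)
  expect_lt(m2$uniqueness, 1.0)
  # predicted == oracle -> MAE 0 (constant-leaf predictor vs constant oracle)
  const <- make_ensemble(list(make_leaf(1.5), make_leaf(1.5)), "regression",
                         D = cfg$length)
  const$cfg <- cfg
  orc <- oracle(function(s) rep(1.5, length(s)), "const")
  m3 <- evaluate_metrics(train, train, oracle = orc, predictor = const, cfg = cfg)
  expect_equal(m3$mae, 0)
  expect_error(evaluate_metrics(character(0), train), "empty")
})

test_that("reports aggregate replicates and refuse incompatible configs", {
  cfg1 <- tiny_cfg(seeds = list(generator = 1))
  cfg2 <- tiny_cfg(seeds = list(generator = 2))
  r1 <- run_experiment(cfg1)
  r2 <- run_experiment(cfg2)
  rep1 <- report(list(r1))
  expect_identical(nrow(rep1$table), 2L)
  # identical logs: zero sd
  rep2 <- report(list(r1, r1))
  expect_true(all(rep2$table$mae_sd == 0))
  # mixed configurations refused with the differing fields named
  other <- run_experiment(tiny_cfg(acquisition = "greedy"))
  expect_error(report(list(r1, other)), "acquisition")
  # different seeds are compatible replicates
  expect_identical(report(list(r1, r2))$n_replicates, 2L)
})
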