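# Ensemble predictor: fitting, per-tree access, confidence-weighted
# fine-tuning, Platt calibration.

test_that("fits are deterministic per seed and learn a separable toy set", {
  d <- toy_separable()
  cfg <- small_fp_cfg()
  p1 <- fit_initial(d, "classification", cfg, ntree = 25, seed = 3)
  p2 <- fit_initial(d, "classification", cfg, ntree = 25, seed = 3)
  probe <- fixture_library(5, 20)
  expect_identical(predict(p1, probe, type = "tree"),
                   predict(p2, probe, type = "tree"))
  # training accuracy 1.0 on a linearly separable set
  expect_equal(as.integer(predict(p1, d$smiles) >= 0.5), d$label)
  # different seeds give different forests
  p3 <- fit_initial(d, "classification", cfg, ntree = 25, seed = 4)
  expect_false(identical(predict(p1, probe, type = "tree"),
                         predict(p3, probe, type = "tree")))
})

test_that("degenerate training sets are rejected", {
  expect_error(fit_initial(labeled_set(character(0), numeric(0)),
                           "regression"), "empty")
  one_class <- labeled_set(c("CCO", "CCC", "CCCC"), c(1, 1, 1))
  expect_error(fit_initial(one_class, "classification", small_fp_cfg()),
               "both classes")
})

test_that("mean and per-tree predictions agree with hand-built ensembles", {
  # classification votes [0, 1, 1, 1] -> 0.75
  ens <- make_ensemble(list(make_leaf(0), make_leaf(1), make_leaf(1), make_leaf(1)))
  x <- matrix(0, 1, 4)
  expect_equal(predict_mean(ens, x), 0.75)
  expect_identical(unname(tree_predictions(ens, x)), c(0, 1, 1, 1))
  # constant regression trees
  reg <- make_ensemble(list(make_leaf(2.5), make_leaf(2.5)), task = "regression")
  expect_equal(predict_mean(reg, x), 2.5)
  # B = 2 regression outputs (1, 3) -> 2
  reg2 <- make_ensemble(list(make_leaf(1), make_leaf(3)), task = "regression")
  expect_equal(predict_mean(reg2, x), 2.0)
})

test_that("per-tree predictions are consistent with the mean and stay in bounds", {
  fit <- fitted_toy_classifier()
  P <- predict(fit$predictor, fit$lib, type = "tree")
  expect_identical(ncol(P), fit$predictor$B)
  expect_true(all(P %in% c(0, 1)))
  m <- predict(fit$predictor, fit$lib)
  expect_equal(rowMeans(P), m)
  expect_true(all(m >= apply(P, 1, min) & m <= apply(P, 1, max)))
})

test_that("zero-confidence feedback leaves seeded refits bit-identical", {
  d <- toy_separable()
  cfg <- small_fp_cfg()
  p <- fit_initial(d, "classification", cfg, ntree = 20, seed = 2)
  probe <- fixture_library(5, 25)
  zero <- labeled_set(probe[1:5], c(1, 1, 0, 0, 1), weight = rep(0, 5),
                      origin = "acquired")
  ft_zero <- fine_tune(p, d, list(zero), seed = 8)
  ft_none <- fine_tune(p, d, list(), seed = 8)
  expect_identical(predict(ft_zero, probe, type = "tree"),
                   predict(ft_none, probe, type = "tree"))
})

test_that("fine-tuning with no acquisitions is equivalent to the initial fit", {
  d <- toy_separable()
  p <- fit_initial(d, "classification", small_fp_cfg(), ntree = 20, seed = 2)
  ft <- fine_tune(p, d, list(), seed = 2)
  probe <- fixture_library(5, 25)
  expect_identical(predict(ft, probe, type = "tree"),
                   predict(p, probe, type = "tree"))
})

test_that("higher confidence moves predictions at least as far toward the label", {
  d <- toy_separable()
  cfg <- small_fp_cfg()
  # feedback molecule outside the toy set's chemistry, labeled active
  x <- "c1ccc2oc(C(F)(F)F)cc2c1"
  h <- 1
  moved <- sapply(1:5, function(seed) {
    p <- fit_initial(d, "classification", cfg, ntree = 40, seed = seed)
    fb <- function(u) labeled_set(rep(x, 2), rep(h, 2), weight = rep(u, 2),
                                  origin = "acquired")
    base <- predict_mean(fine_tune(p, d, list(), seed = seed + 50), x)
    lo <- predict_mean(fine_tune(p, d, list(fb(0.5)), seed = seed + 50), x)
    hi <- predict_mean(fine_tune(p, d, list(fb(1.0)), seed = seed + 50), x)
    c(lo_shift = lo - base, hi_shift = hi - base)
  })
  # median over seeds: full confidence pulls at least as hard as half
  expect_gte(median(moved["hi_shift", ]), median(moved["lo_shift", ]))
  expect_gt(median(moved["hi_shift", ]), 0)
})

test_that("Platt scaling yields monotone calibrated probabilities", {
  fit <- fitted_toy_classifier(ntree = 30)
  lib2 <- fixture_library(13, 80)
  w <- random_linear_weights(9, fit$cfg, density = 0.1)
  y2 <- binary_labels(synthetic_linear_oracle(w, cfg = fit$cfg)$fn(lib2), 0)
  holdout <- labeled_set(lib2, y2)
  cal <- platt_calibrate(fit$predictor, holdout)
  raw <- seq(0, 1, by = 0.1)
  out <- calibrate_scores(cal, raw)
  expect_true(all(out >= 0 & out <= 1))
  # logistic preserves (or wholly reverses, with negative slope) ranking;
  # on informative holdouts the slope is positive
  expect_gt(cal$slope, 0)
  expect_true(all(diff(out) > 0))
  expect_error(platt_calibrate(
    fit_initial(labeled_set(c("CCO", "CCC", "CO", "CC"), c(0, 1, 2, 3)),
                "regression", small_fp_cfg(), ntree = 5, seed = 1),
    holdout), "classification")
})

test_that("a holdout split evenly at raw score 0.5 calibrates it to about 0.5", {
  fit <- fitted_toy_classifier(ntree = 30)
  lib2 <- fixture_library(17, 300)
  raw <- predict(fit$predictor, lib2)
  # labels drawn from the raw scores themselves: the predictor is then
  # calibrated by construction, so Platt scaling should be near identity
  set.seed(33)
  y <- rbinom(length(raw), 1, pmin(pmax(raw, 0.02), 0.98))
  cal <- platt_calibrate(fit$predictor, labeled_set(lib2, y))
  expect_equal(calibrate_scores(cal, 0.5), 0.5, tolerance = 0.1)
})
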