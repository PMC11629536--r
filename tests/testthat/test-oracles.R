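# Oracles, simulated experts, and feedback conversion.

test_that("penalized LogP is deterministic and its long-cycle term behaves", {
  expect_identical(penalized_logp("CCO"), penalized_logp("CCO"))
  # acyclic molecule: penalized value is exactly logp - sa (no cycle term)
  expect_equal(penalized_logp("CCCCO"),
               logp_estimate("CCCCO") - sa_score("CCCCO"))
  # a ring with more than six atoms costs one extra unit
  small_ring <- "C1CCCCC1"   # six-membered: no penalty
  big_ring <- "C1CCCCCCC1"   # eight-membered: one long cycle
  expect_equal(penalized_logp(small_ring),
               logp_estimate(small_ring) - sa_score(small_ring))
  expect_equal(penalized_logp(big_ring),
               logp_estimate(big_ring) - sa_score(big_ring) - 1)
})

test_that("ethanol's partition estimate matches an independent recomputation", {
  # independent recomputation from the same atom-contribution descriptors:
  # 2 aliphatic C, 1 hydroxyl O, 5 H on C, 1 H on O
  expected <- 2 * 0.36 + (-0.75) + 5 * 0.12 + 1 * (-0.25)
  expect_equal(logp_estimate("CCO"), expected, tolerance = 1e-12)
  expect_equal(penalized_logp("CCO"), expected - sa_score("CCO"))
})

test_that("the synthetic linear oracle is w . x + b with a sigmoided variant", {
  cfg <- small_fp_cfg()
  zero <- synthetic_linear_oracle(numeric(cfg$length), bias = 0, cfg = cfg)
  expect_equal(zero$fn(c("CCO", "c1ccccc1")), c(0, 0))
  # unit weight on one position reads off the count there
  fp <- ecfp_count("CCO", cfg)
  j <- which(fp > 0)[1]
  w <- numeric(cfg$length); w[j] <- 1
  expect_equal(synthetic_linear_oracle(w, cfg = cfg)$fn("CCO"), fp[j])
  # sigmoided variant: 0.5 exactly at w . x + b = 0
  sig <- synthetic_linear_oracle(numeric(cfg$length), bias = 0,
                                 sigmoided = TRUE, cfg = cfg)
  expect_equal(sig$fn("CCO"), 0.5)
  expect_error(synthetic_linear_oracle(1:3, cfg = cfg), "length")
})

test_that("binary labels threshold strictly above delta", {
  expect_identical(binary_labels(c(0.2, 0.9), 0.5), c(0L, 1L))
  expect_identical(binary_labels(0.5, 0.5), 0L)  # exactly delta -> 0
  expect_identical(binary_labels(c(1, 2, 3), -10), c(1L, 1L, 1L))
})

test_that("regression expert noise has the configured moments", {
  orc <- penalized_logp_oracle()
  truth <- orc$fn("c1ccccc1CCO")
  exact <- expert_model(orc, sigma_eps = 0, clip = FALSE, seed = 1)
  expect_equal(simulate_regression_expert(exact, "c1ccccc1CCO"), truth)
  noisy <- expert_model(orc, sigma_eps = 1.0, clip = FALSE, seed = 1)
  draws <- simulate_regression_expert(noisy, rep("c1ccccc1CCO", 10000))
  expect_equal(mean(draws), truth, tolerance = 0.05)
  expect_equal(sd(draws), 1.0, tolerance = 0.05)
  # the reference noise levels are plain configuration values
  for (s in c(1.0, 5.0)) expect_silent(expert_model(orc, sigma_eps = s))
})

test_that("classification experts clip to [0, 1] for any noise level", {
  cfg <- small_fp_cfg()
  w <- random_linear_weights(3, cfg)
  orc <- synthetic_linear_oracle(w, sigmoided = TRUE, cfg = cfg)
  mols <- fixture_library(21, 50)
  for (s in c(0.15, 0.3, 0.7)) {
    e <- expert_model(orc, sigma_eps = s, clip = TRUE, seed = 2)
    a <- simulate_classification_expert(e, mols)
    expect_true(all(a >= 0 & a <= 1))
  }
  e0 <- expert_model(orc, sigma_eps = 0, clip = TRUE, seed = 2)
  expect_equal(simulate_classification_expert(e0, mols), orc$fn(mols))
  expect_error(simulate_classification_expert(
    expert_model(orc, clip = FALSE), mols), "clip")
})

test_that("expert noise streams are reproducible and independent of R's RNG", {
  orc <- penalized_logp_oracle()
  e1 <- expert_model(orc, sigma_eps = 2, seed = 7)
  set.seed(1); a <- query_expert(e1, c("CCO", "CCC"))
  e2 <- expert_model(orc, sigma_eps = 2, seed = 7)
  set.seed(999); b <- query_expert(e2, c("CCO", "CCC"))
  expect_identical(a, b)
  # the stream advances: a fresh query differs from the first
  expect_false(identical(query_expert(e1, "CCO"), a[1]))
})

test_that("agreement scores convert to labels and confidences", {
  # the worked slider example: 40% agreement -> label 0, confidence 60%
  fb <- agreement_to_feedback(0.40, "classification")
  expect_identical(fb$label, 0L)
  expect_equal(fb$confidence, 0.60)
  # full agreement
  fb1 <- agreement_to_feedback(1.0, "classification")
  expect_identical(fb1$label, 1L)
  expect_equal(fb1$confidence, 1.0)
  # tie at the midpoint: agree with minimal influence
  fb5 <- agreement_to_feedback(0.5, "classification")
  expect_identical(fb5$label, 1L)
  expect_equal(fb5$confidence, 0.5)
  expect_error(agreement_to_feedback(1.3, "classification"), "\\[0, 1\\]")
  # u = max(a, 1 - a): confidences live in [0.5, 1]
  a <- seq(0, 1, by = 0.05)
  fbv <- agreement_to_feedback(a, "classification")
  expect_equal(fbv$confidence, pmax(a, 1 - a))
  expect_true(all(fbv$confidence >= 0.5))
  # regression: the value estimate passes through with unit confidence
  fr <- agreement_to_feedback(c(-2.5, 3.7), "regression")
  expect_equal(fr$label, c(-2.5, 3.7))
  expect_equal(fr$confidence, c(1, 1))
})

test_that("feedback CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_feedback_csv(c("CCO", "CCC"), c(0.8, 0.6), path)
  df <- read_feedback_csv(path)
  expect_identical(df$smiles, c("CCO", "CCC"))
  expect_true(all(is.na(df$agreement)))
})
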