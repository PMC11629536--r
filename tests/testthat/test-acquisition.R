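# Acquisition criteria: target distribution, pairwise MI / EPIG, uncertainty,
# greedy, batch selection.

test_that("target distribution weights are score-proportional over the top k", {
  td <- target_distribution(c("CCO", "CCC"), c(0.6, 0.2), k = 2)
  expect_equal(unname(td$weights[match(c("CCO", "CCC"), td$smiles)]),
               c(0.75, 0.25))
  # equal scores -> uniform
  td2 <- target_distribution(c("CCO", "CCC", "CCCC"), rep(0.4, 3), k = 3)
  expect_equal(unname(td2$weights), rep(1 / 3, 3))
  # weights always sum to one; k capped at the pool
  td3 <- target_distribution(paste0("C", strrep("C", 1:9)), (1:9) / 10, k = 100)
  expect_equal(sum(td3$weights), 1, tolerance = 1e-9)
  expect_length(td3$smiles, 9L)
  # degenerate all-zero scores: explicit choice, never silent
  expect_error(target_distribution(c("CCO", "CCC"), c(0, 0)), "degenerate")
  td4 <- target_distribution(c("CCO", "CCC"), c(0, 0), degenerate = "uniform")
  expect_equal(unname(td4$weights), c(0.5, 0.5))
})

test_that("pairwise MI matches hand-enumerated 2x2 joints", {
  # perfectly coupled outcomes [0,1] vs [0,1] -> ln 2
  ens <- make_ensemble(list(make_stump(1, 0, 1), make_stump(1, 1, 0)))
  x <- matrix(c(1, 0, 0, 0), 1)  # feature 1 set
  expect_equal(pairwise_mi(ens, x, x), log(2), tolerance = 1e-12)
  # constant outcomes at x_star -> zero MI
  const <- make_ensemble(list(make_stump(1, 0, 1), make_stump(1, 0, 1)))
  xs <- matrix(c(1, 0, 0, 0), 1)
  x0 <- matrix(0, 1, 4)  # both trees vote 0 at x0: deterministic y
  expect_equal(pairwise_mi(const, x0, xs), 0)
  # B = 4, outcomes [0,0,1,1] vs [0,1,0,1]: joint is the product of marginals
  ind <- make_ensemble(list(make_leaf(0), make_stump(2, 0, 1),
                            make_stump(1, 0, 1), make_leaf(1)))
  xa <- matrix(c(1, 0, 0, 0), 1)
  xb <- matrix(c(0, 1, 0, 0), 1)
  expect_identical(unname(tree_predictions(ind, xa)), c(0, 0, 1, 1))
  expect_identical(unname(tree_predictions(ind, xb)), c(0, 1, 0, 1))
  expect_equal(pairwise_mi(ind, xa, xb), 0, tolerance = 1e-12)
})

test_that("pairwise MI equals brute-force joint enumeration on random forests", {
  checked <- 0L
  for (rep in 1:5) {
    fit <- fitted_toy_classifier(ntree = 2L + (rep %% 4) * 2L, seed = rep)
    P <- predict(fit$predictor, fit$lib, type = "tree")
    set.seed(rep)
    pairs <- cbind(sample(length(fit$lib), 25, TRUE),
                   sample(length(fit$lib), 25, TRUE))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      got <- pairwise_mi(fit$predictor, fit$lib[i], fit$lib[j])
      expect_equal(got, mi_brute(P[i, ], P[j, ]), tolerance = 1e-12)
      # MI bounded by each marginal entropy
      h <- function(v) { p <- mean(v); ifelse(p %in% c(0, 1), 0,
                                              -p * log(p) - (1 - p) * log(1 - p)) }
      expect_lte(got, min(h(P[i, ]), h(P[j, ])) + 1e-12)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 100L)
})

test_that("EPIG reduces to pairwise MI and vanishes when trees agree", {
  # all trees agree on every target member -> EPIG identically zero
  agree <- make_ensemble(list(make_leaf(1), make_leaf(1), make_leaf(1)))
  pool <- fixture_library(3, 10)
  td <- target_distribution(pool[1:3], c(0.5, 0.3, 0.2), k = 3)
  expect_true(all(epig_scores(agree, pool, td) == 0))
  # single target member: EPIG(x) = pairwise_mi(x, member)
  fit <- fitted_toy_classifier(ntree = 8)
  td1 <- target_distribution(fit$lib[5], 1, k = 1)
  e <- epig_scores(fit$predictor, fit$lib[1:10], td1)
  for (i in 1:10)
    expect_equal(unname(e[i]),
                 pairwise_mi(fit$predictor, fit$lib[i], fit$lib[5]),
                 tolerance = 1e-12)
  expect_true(all(e >= 0))
  # pool molecule identical to the single coupled target member -> ln 2
  cfg4 <- fingerprint_config(radius = 0L, length = 4L)
  j <- which(ecfp_count("C", cfg4) > 0)[1]
  coupled <- make_ensemble(list(make_stump(j, 0, 1), make_stump(j, 1, 0)))
  td_self <- structure(list(smiles = "C", weights = 1),
                       class = "target_distribution")
  expect_equal(unname(epig_scores(coupled, "C", td_self)[1]), log(2),
               tolerance = 1e-12)
})

test_that("EPIG is invariant to duplicating target members with halved weights", {
  fit <- fitted_toy_classifier(ntree = 8)
  members <- fit$lib[1:4]
  w <- c(0.4, 0.3, 0.2, 0.1)
  td <- structure(list(smiles = members, weights = w),
                  class = "target_distribution")
  td_dup <- structure(list(smiles = rep(members, 2), weights = rep(w / 2, 2)),
                      class = "target_distribution")
  pool <- fit$lib[5:20]
  expect_equal(epig_scores(fit$predictor, pool, td),
               epig_scores(fit$predictor, pool, td_dup), tolerance = 1e-12)
})

test_that("uncertainty scores: entropy for classifiers, 1/B variance for regressors", {
  # predicted probability 0.5 -> ln 2; degenerate probabilities -> 0
  half <- make_ensemble(list(make_leaf(0), make_leaf(1)))
  x <- matrix(0, 1, 4)
  expect_equal(unname(uncertainty_scores(half, "CCO")[1]), log(2))
  sure <- make_ensemble(list(make_leaf(1), make_leaf(1)))
  expect_equal(unname(uncertainty_scores(sure, "CCO")[1]), 0)
  # regression tree outputs (1, 2, 3): population variance 2/3
  reg <- make_ensemble(list(make_leaf(1), make_leaf(2), make_leaf(3)),
                       task = "regression")
  expect_equal(unname(uncertainty_scores(reg, "CCO")[1]), 2 / 3)
  # symmetry about 0.5 and maximum there
  fit <- fitted_toy_classifier(ntree = 16)
  p <- predict(fit$predictor, fit$lib)
  u <- uncertainty_scores(fit$predictor, fit$lib)
  ent <- function(q) ifelse(q %in% c(0, 1), 0, -q * log(q) - (1 - q) * log(1 - q))
  expect_equal(unname(u), ent(p))
  expect_equal(ent(p), ent(1 - p))
  expect_true(all(u <= log(2) + 1e-12))
})

test_that("greedy scores are the stored predicted scores", {
  g <- greedy_scores(c("CCO", "CCC"), c(0.9, 0.3))
  expect_identical(unname(g), c(0.9, 0.3))
  expect_identical(names(g), c("CCO", "CCC"))
  expect_length(greedy_scores(character(0), numeric(0)), 0L)
  # ranking by greedy equals ranking by score
  s <- c(a = 0.2, b = 0.9, c = 0.5)
  expect_identical(order(-greedy_scores(names(s), unname(s))), order(-s))
})

test_that("batch selection takes top-T, honors exclusions, breaks ties lexicographically", {
  scores <- c(a = 0.9, b = 0.5, c = 0.1)
  expect_identical(select_batch(scores, 2, "greedy")$batch, c("a", "b"))
  # T larger than the pool: whole pool, no error
  expect_identical(select_batch(scores, 10, "greedy")$batch, c("a", "b", "c"))
  # exclusions are never selected; empty signal when all excluded
  expect_identical(select_batch(scores, 2, "greedy", exclude = c("a", "b"))$batch, "c")
  expect_length(select_batch(scores, 2, "greedy", exclude = names(scores))$batch, 0L)
  # ties broken by canonical SMILES order
  tied <- c(CCC = 0.5, CCO = 0.5, CC = 0.5)
  expect_identical(select_batch(tied, 2, "uncertainty")$batch, c("CC", "CCC"))
  # random: seeded and reproducible, without replacement
  r1 <- select_batch(scores, 2, "random", seed = 9)
  r2 <- select_batch(scores, 2, "random", seed = 9)
  expect_identical(r1$batch, r2$batch)
  expect_length(unique(r1$batch), 2L)
  expect_error(select_batch(scores, 0, "greedy"), "T must be")
})
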