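# Generator contract: loss function, stand-in proposal agent, diversity-filter
# memory, pool construction.

test_that("the generator loss matches hand arithmetic and its invariants", {
  # perfect agreement at zero score
  expect_equal(reinvent_loss(c(-5, -7), c(-5, -7), c(0, 0)), 0)
  # P = 1, prior = agent = -12, score 0.5, lambda 128 -> (64)^2
  expect_equal(reinvent_loss(-12, -12, 0.5, lambda = 128), 4096)
  # permutation invariance of the batch
  p <- c(-10, -12, -8); a <- c(-9, -13, -8); s <- c(0.2, 0.9, 0.4)
  o <- c(3, 1, 2)
  expect_equal(reinvent_loss(p, a, s), reinvent_loss(p[o], a[o], s[o]))
  # the printed sign convention is exposed but distinct
  expect_equal(reinvent_loss(-12, -12, 0.5, 128, sign = "printed"), 4096)
  expect_false(isTRUE(all.equal(reinvent_loss(-12, -10, 0.5, 128),
                                reinvent_loss(-12, -10, 0.5, 128, sign = "printed"))))
  # zero iff agent equals the augmented prior for every member
  expect_equal(reinvent_loss(c(-10, -8), c(-10 + 12.8, -8 + 64), c(0.1, 0.5), 128), 0)
  expect_error(reinvent_loss(c(-1, -2), -1, 0.5), "equal length")
})

test_that("proposals are seeded draws proportional to agent weights", {
  lib <- fixture_library(9, 20)
  ag <- generator_agent(lib)
  expect_identical(propose_batch(ag, 50, seed = 3), propose_batch(ag, 50, seed = 3))
  expect_identical(propose_batch(ag, 0), character(0))
  # uniform initial weights: 10,000 draws close to multinomial expectation
  draws <- propose_batch(ag, 10000, seed = 5)
  counts <- table(factor(draws, levels = lib))
  expected <- 10000 / 20
  sd3 <- 3 * sqrt(10000 * (1 / 20) * (19 / 20))
  expect_true(all(abs(counts - expected) <= sd3))
})

test_that("agent updates sharpen multiplicatively and never touch the prior", {
  lib <- c("CCO", "CCC", "CCCC")
  ag <- generator_agent(lib)
  prior0 <- ag$prior
  # eta = 0: unchanged
  expect_identical(update_agent(ag, "CCO", 1, eta = 0)$weights, ag$weights)
  # repeated full-score updates of one molecule: probability increases to 1
  probs <- numeric(30)
  cur <- ag
  for (i in 1:30) {
    cur <- update_agent(cur, "CCO", 1, eta = 1)
    probs[i] <- cur$weights[match("CCO", cur$library)]
  }
  expect_true(all(diff(probs) > 0))
  expect_gt(probs[30], 0.999)
  expect_identical(cur$prior, prior0)
  # hand check of one multiplicative step
  one <- update_agent(ag, "CCO", 0.5, eta = 2)
  w <- ag$weights; j <- match("CCO", lib)
  w[j] <- w[j] * exp(1)
  expect_equal(one$weights, w / sum(w))
})

test_that("agent log-likelihoods expose current and prior state", {
  lib <- fixture_library(9, 10)
  ag <- generator_agent(lib)
  expect_equal(agent_loglik(ag, lib[1]), log(1 / 10))
  ag2 <- update_agent(ag, lib[1], 1, eta = 2)
  expect_gt(agent_loglik(ag2, lib[1]), agent_loglik(ag2, lib[1], prior = TRUE))
  expect_error(agent_loglik(ag, "C#CC#CC#C"), "library")
})

test_that("memory buckets enforce threshold, uniqueness and capacity", {
  mem <- memory_buckets(capacity = 1L, score_threshold = 0.4)
  row <- function(s, total) data.frame(smiles = canonicalize(s), total = total,
                                       stringsAsFactors = FALSE)
  low <- memory_add(mem, row("c1ccccc1CC", 0.2))
  expect_false(low$accepted); expect_identical(low$reason, "low_score")
  ok <- memory_add(mem, row("c1ccccc1CC", 0.8))
  expect_true(ok$accepted)
  dup <- memory_add(ok$memory, row("c1ccccc1CC", 0.9))
  expect_identical(dup$reason, "duplicate")
  # same scaffold, different molecule, capacity-1 bucket
  full <- memory_add(ok$memory, row("c1ccccc1CCC", 0.9))
  expect_identical(full$reason, "bucket_full")
  # novel scaffold above threshold is accepted
  novel <- memory_add(ok$memory, row("C1CCCCC1C", 0.7))
  expect_true(novel$accepted)
  stored <- memory_molecules(novel$memory)
  expect_true(all(stored$total >= 0.4))
})

test_that("pools deduplicate memory and honor component cutoffs", {
  mem <- memory_buckets(capacity = 5L, score_threshold = 0.1)
  rows <- data.frame(smiles = canonicalize(c("c1ccccc1CC", "C1CCCCC1C")),
                     property = c(0.6, 0.4), total = c(0.6, 0.4),
                     stringsAsFactors = FALSE)
  for (i in 1:2) mem <- memory_add(mem, rows[i, ])$memory
  # component cutoff 0.5 keeps one molecule
  expect_identical(nrow(build_pool(mem, "property", 0.5)), 1L)
  # cutoff 0 keeps everything; pool is a subset of memory
  p0 <- build_pool(mem, "property", 0)
  expect_identical(sort(p0$smiles), sort(rows$smiles))
  expect_identical(nrow(build_pool(mem)), 2L)
  # empty memory: zero-row pool, caller's signal
  expect_identical(nrow(build_pool(memory_buckets())), 0L)
})

test_that("a static scorer plus the stand-in agent yields optimization pressure", {
  cfg <- small_fp_cfg()
  w <- random_linear_weights(5, cfg, density = 0.1)
  orc <- synthetic_linear_oracle(w, bias = 2, cfg = cfg)
  sf <- scoring_function(list(scoring_component(
    "prop", "analytic", transform = transform_spec("double_sigmoid", 2, 4, 10),
    fn = orc$fn)), cfg)
  gains <- sapply(1:5, function(seed) {
    ag <- generator_agent(fixture_library(seed, 300))
    run <- run_generation_cycle(ag, sf, memory_buckets(), n_steps = 50, P = 32,
                                eta = 2, seed = seed)
    mean(tail(run$steps$mean_total, 10)) - mean(head(run$steps$mean_total, 10))
  })
  expect_gt(median(gains), 0)
})

test_that("agent checkpoints round-trip through JSON", {
  ag <- generator_agent(fixture_library(9, 15))
  ag <- update_agent(ag, ag$library[2], 0.9, eta = 2)
  path <- withr::local_tempfile(fileext = ".json")
  agent_save(ag, path)
  back <- agent_load(path)
  expect_identical(back$library, ag$library)
  expect_equal(back$weights, ag$weights)
  expect_equal(back$prior, ag$prior)
})
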