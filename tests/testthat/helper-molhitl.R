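# Shared fixtures: handcrafted forests with exactly controlled per-tree
# outputs, small toy data sets, and an independent brute-force mutual
# information oracle.

# a decision stump on one (1-based) fingerprint position
make_stump <- function(feature, v_left, v_right, threshold = 0.5) {
  list(feature = c(feature - 1L, -1L, -1L),
       threshold = c(threshold, 0, 0),
       left = c(1L, -1L, -1L),
       right = c(2L, -1L, -1L),
       value = c(0, v_left, v_right))
}

# a constant (single-leaf) tree
make_leaf <- function(value) {
  list(feature = -1L, threshold = 0, left = -1L, right = -1L, value = value)
}

# wrap handcrafted trees as an rf_ensemble over D raw features
make_ensemble <- function(trees, task = "classification", D = 4L) {
  structure(list(task = task, forest = trees, B = length(trees),
                 cfg = fingerprint_config(radius = 0L, length = D),
                 fit_params = list(ntree = length(trees)),
                 training = list(initial = labeled_set(character(0), numeric(0)),
                                 acquired = list())),
            class = "rf_ensemble")
}

# independent brute-force MI oracle: enumerate the full 2x2 joint
mi_brute <- function(ox, os) {
  mi <- 0
  for (a in 0:1) for (b in 0:1) {
    p <- mean(ox == a & os == b)
    pa <- mean(ox == a); pb <- mean(os == b)
    if (p > 0) mi <- mi + p * log(p / (pa * pb))
  }
  mi
}

# linearly separable toy set: actives carry a marker substructure
toy_separable <- function() {
  actives <- c("OCC(O)CO", "OCCC(O)CO", "OC(CO)CO", "OCC(O)CCO", "OCCC(O)CCO",
               "OC(CO)CCO", "OCC(O)C(O)CO", "OCCC(O)C(C)O", "OCC(C)C(O)CO",
               "OC(C)C(O)CO")
  inactives <- c("CCCC", "CCCCC", "CCCCCC", "CC(C)C", "CC(C)CC", "CCC(C)C",
                 "CC(C)(C)C", "CCCCCCC", "CC(C)CCC", "CCCC(C)C")
  labeled_set(c(actives, inactives), rep(c(1, 0), each = 10))
}

small_fp_cfg <- function() fingerprint_config(radius = 2L, length = 256L)

# small fitted classification forest over the fixture library
fitted_toy_classifier <- function(ntree = 8L, seed = 5L) {
  lib <- fixture_library(3, 60)
  cfg <- small_fp_cfg()
  w <- random_linear_weights(9, cfg, density = 0.1)
  y <- binary_labels(synthetic_linear_oracle(w, cfg = cfg)$fn(lib), 0)
  if (length(unique(y)) < 2) y[1:5] <- 1 - y[1:5]
  list(predictor = fit_initial(labeled_set(lib, y), "classification", cfg,
                               ntree = ntree, seed = seed),
       lib = lib, cfg = cfg)
}
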