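---
title: "Human-in-the-loop active learning for goal-oriented molecule generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Human-in-the-loop active learning for goal-oriented molecule generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molhitl)
```

## The problem

Goal-oriented molecule generation optimizes a generator against a scoring
function that contains a learned property predictor (a QSAR/QSPR model). The
predictor is trained once, on whatever labeled data a project happens to have,
and is then asked to score molecules in regions of chemical space the
generator actively steers *away* from that data. The result is a familiar
failure mode: molecules with near-perfect predicted scores and mediocre true
properties.

`molhitl` implements a corrective loop: after each generation cycle, an
acquisition criterion picks a small batch of generated molecules that would be
most informative to know the truth about; an expert (a human, or a simulated
noisy oracle) judges them; and the predictor is re-fitted with the feedback,
weighted by the expert's confidence. The updated predictor replaces the old
one in the scoring function for the next cycle.

## The model and its pieces

**Score.** A molecule `x` (a count fingerprint) is scored by
`s(x) = sum_i w_i sigma_i(c_i(x)) / sum_i w_i`, each component `c_i` being an
analytic property, a predictor, or a max-Tanimoto similarity to a reference
set, each mapped into [0, 1] by a transform `sigma_i`. For interval targets
(e.g. a partition estimate in [2, 4]) the transform is a double sigmoid
`logistic(k (x - low)) * logistic(-k (x - high))`: ~1 well inside the window,
0.5 at each boundary, 0 far outside. Steepness `k` defaults to 10 — a sharp
but finite plateau for windows a few units wide; it is a configuration knob
because no canonical value exists for the general case. Classification
predictors already emit probabilities and use the identity transform; `flip`
(`1 - p`) rewards *low* probabilities of a liability.

**Predictor.** A bagged ensemble of CART trees on Morgan count fingerprints,
with per-tree access: the ensemble prediction is the arithmetic mean of B tree
outputs (class votes in {0,1}, whose mean is the positive-class probability).
Reference-scale defaults are 300 trees / `min_split = 2` (regression) and 200
trees / depth 10 (classification). Sample weights act through the bootstrap:
each tree draws its training rows with probability proportional to weight, so
a zero-weight record can influence nothing and a refit is bit-reproducible per
seed. "Fine-tuning" is a weighted refit from scratch — a forest has no
incremental gradient step, and the confidence-weighted training objective over
the union of initial and acquired data is exactly what the weighted refit
minimizes. Each initial record carries weight `1/N0`; each acquired record
carries `u_t / N_acq`, its expert confidence over the total number of
acquired records, so initial data and accumulated feedback hold balanced
total mass (see the synthetic-world section for why the per-batch alternative
was rejected).

**Acquisition.** Four criteria over the pool of high-scoring generated
molecules:

* **EPIG** — expected predictive information gain: the target-weighted sum of
  mutual informations between the predictive outcome at a candidate and the
  outcomes at the molecules one actually cares about (the score-weighted
  top-k of the pool). Each tree is treated as a posterior parameter draw; the
  joint over a pair of outcomes is read off matched tree indices, and the MI
  of the 2x2 joint is computed in closed form (nats). The expectation over the
  target distribution is an exact weighted sum over its members, not a Monte
  Carlo estimate — with k capped at the pool size there is nothing to sample.
* **Uncertainty** — per-tree population variance (regression, 1/B
  normalization) or Shannon entropy of the mean probability (classification).
* **Greedy** — the transformed predicted score itself.
* **Random** — a seeded uniform draw, the baseline.

For regression ensembles EPIG needs a binary predictive outcome per tree; the
package thresholds each tree's *transformed* output at 0.5, i.e. "does this
tree place the molecule in the desired property window?". This matches the
top-scoring semantics of the target distribution and reuses the closed-form
binary machinery; a Gaussian-mixture Monte Carlo estimator was deliberately
not built. Batches are selected without replacement across the whole run — a
human asked twice about the same structure is wasted effort — and ranked-
criterion ties break by canonical SMILES order so runs are reproducible.

**Feedback.** A classification expert reports agreement `a` in [0, 1] with
the predicted label (slider semantics): the label is `h = 1` iff `a >= 0.5`
and the confidence is `u = max(a, 1 - a)` — agreement 40% means label 0 with
confidence 60%. The tie `a = 0.5` maps to `h = 1` with the minimum confidence
0.5: the convention is nearly inert because that weight is minimal, and it
matches the definition that only values *below* 50% disagree. Regression
experts return a noisy value estimate used directly as the label with unit
confidence — no confidence notion is defined for value feedback, which is the
one place the package must interpret rather than transcribe. Simulated experts
are `f*(x) + eps`, `eps ~ N(0, sigma_eps)`, clipped to [0, 1] for agreement
experts; their noise comes from a dedicated counter-based stream, so expert
noise is reproducible independently of every other random decision.

**Generator.** The real system this emulates trains a SMILES RNN by policy
gradient against the squared gap between the agent log-likelihood and the
score-augmented prior log-likelihood (`reinvent_loss()`, exposed as a pure
function; the printed sign convention that *subtracts* the reward is
available behind a flag but contradicts reward maximization, so the augmented
form is the default). Training an RNN is out of scope at desk scale; the
stand-in is a library-reweighting agent: proposals are seeded draws from a
fixed fixture library with probability proportional to adaptive weights, and
`update_agent` applies the textbook multiplicative-weights step
`w <- w * exp(eta * s)`. One subtlety: the RNN loss is *stationary* (it
regresses toward a fixed augmented-prior target), while multiplicative
weights compound per occurrence without bound. The orchestration therefore
feeds the agent a proposal's score only when the diversity filter accepts it
into memory; duplicates, full scaffold buckets and sub-threshold proposals
earn zero. Without this gating the agent provably collapses onto a single
recurring molecule within two cycles.

**Diversity filter and pool.** Accepted molecules go into scaffold-keyed
buckets (Murcko-type ring framework as key; empty key for acyclic molecules)
with a per-bucket capacity (default 25) and a total-score threshold (default
0.4) — the mechanism is named in the reference design, its parameters are
not, so both are knobs. The acquisition pool of a round is the deduplicated
memory content, optionally filtered on a named predictor component score
(> 0.5 in multi-objective mode).

## The chemistry layer

No cheminformatics toolkit exists for R in this environment, so the package
carries its own, scoped to what the loop needs: a SMILES parser (organic
subset, aromatic lowercase, bracket atoms with hydrogen counts and charges,
branches, ring closures; no stereochemistry, isotopes or fragments), Morgan-
rank canonicalization fixed in tests by round-trip identity rather than string
constants, ECFP-style hashed count fingerprints (radius 3, 2048 positions by
default; counts feed the predictor, presence bits feed Tanimoto similarity),
and iterative-pruning Murcko scaffolds that retain atoms multiple-bonded to
the framework. Canonicalization uses invariant refinement with deterministic
tie splitting; tied atoms that survive refinement are automorphic in
chemistry-sized graphs for all practical purposes, which is the one known
theoretical gap.

The penalized-LogP oracle (partition estimate minus synthetic-accessibility
score minus the count of rings larger than six atoms) and the drug-likeness
score are *simplified deterministic analogues* built on the package's own
atom-contribution tables — the published heuristics need fragment parameter
sets that are not available offline. They are internally consistent stand-ins
for optimization targets, not literature-accurate property calculators, and
the documentation of each says so.

## The synthetic world, and what a green test establishes

The fixture library enumerates ~6,200 valid, unique molecules from 21 ring
scaffolds crossed with 26 substituents; a seed only shuffles the fixed
enumeration. The default experiment profile is desk-scale: library 5,000,
`N0 = 200`, proposal batches of 128 over 40 steps per cycle, `R = 3` rounds
of `L = 2` x `T = 10` queries, fingerprint radius 2 / 512 positions, 64
trees. These reductions (vs. 250 steps, radius 3 / 2048, 200-300 trees at
reference scale) are purely computational and are the package defaults so
that every experiment in the test suite re-runs in minutes on one CPU.

Three deliberate choices make the synthetic world behave like the problem the
loop was designed for:

* The default oracle is fingerprint-linear with a weight support dense enough
  (25% of positions) that every molecule's fingerprint overlaps it — an
  "assay" that returns a constant on part of chemical space is degenerate,
  and an early version with 5% density did exactly that on half the library,
  parking the generator on an uninformative reward plateau. The weight scale
  gives the oracle a penalized-LogP-like spread (sd ~1.4 over the library),
  so expert noise levels such as `sigma_eps = 1.0` are meaningful relative to
  signal.
* The fine-tuning objective is stated for a single feedback batch of size
  `T`. Accumulating batches each with their own `1/T` factor would let 6
  batches outweigh the initial data 6:1 in total bootstrap mass, which
  measurably degrades global fit even with noise-free labels; `fine_tune()`
  therefore takes the mean over *all* acquired records (`u_t / N_acq`),
  keeping initial data and accumulated feedback balanced. With a single
  batch the two readings coincide.
* Round MAE is measured on the top-100 pool molecules *excluding* anything
  already queried: the tracked quantity is generalization to new high-scoring
  molecules. At reference scale generated molecules are novel by
  construction; a small combinatorial library re-proposes queried molecules,
  and including them would read memorized noisy labels back out of the
  forest.

What the green tests establish: the acquisition mathematics is exact (MI
against brute-force enumeration at 1e-12), the confidence-weighting contract
holds bit-for-bit, runs are byte-reproducible, and feedback demonstrably
closes the generalization gap — median round-3 MAE below round 1 and below
the seed-matched frozen baseline over 5 seeds, with a noise-free expert and
with Gaussian noise at sd 1.0 (about 0.74 signal sd, harsher than the
reference "moderate" level relative to signal). What they do not establish:
behavior on real chemistry, real experts, or a generator that can leave its
library; the margins at desk scale are modest (MAE differences of 0.05-0.1
oracle units), so single seeds can go either way — the medians are the claim.

## Numerical conventions and degenerate inputs

Entropies and mutual informations are in nats with `0 log 0 := 0`; MI is
clipped at 0 against floating-point negatives. A target distribution whose
top-k scores are all zero is an explicit error unless the caller opts into a
uniform fallback (the orchestration does, since an uninformative early
predictor is routine). Batch selection with an exhausted pool returns an
empty batch and the AL round ends; an empty pool skips the round with a
warning. Classification fits require both classes; all-zero weight vectors
are errors. All randomness flows through counter-based streams derived from
four named seeds (generator, forest, expert, acquisition) plus a library
seed, so a run log is a pure function of its configuration.

## A worked run

```{r example, eval = FALSE}
cfg <- loop_config(R = 2, n_steps = 20, P = 64, L = 2, T = 5,
                   library_size = 1000, n0 = 100,
                   seeds = list(generator = 1, forest = 2,
                                expert = 3, acquisition = 4))
run <- run_experiment(cfg)
print(run)
summary(run)
plot(run)

baseline <- run_experiment(modifyList(cfg, list(no_feedback = TRUE)))
report(list(run))
```

## Known limitations

* The SMILES dialect covers the fixture chemistry and common drug-like
  notation, not the full OpenSMILES grammar (no stereochemistry, isotopes,
  or multi-fragment inputs).
* LogP / SA / drug-likeness are simplified analogues; absolute values are
  not comparable to published calculators.
* The stand-in agent cannot propose outside its library; conclusions about
  generator creativity do not transfer.
* Multi-task predictor fine-tuning is out of scope; multi-objective runs
  fine-tune a single designated predictor component.
* Confidence-weighted refits degrade when expert noise approaches the full
  signal spread of the target region, and the per-batch feedback weighting
  printed in the reference objective amplifies this as batches accumulate
  (hence the balanced mean weighting described above); a noise-aware
  reweighting would be a method change and is left to future work.
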