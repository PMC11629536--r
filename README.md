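# molhitl

Human-in-the-loop active learning for goal-oriented molecule generation.

## The problem

De novo design loops optimize a molecule generator against a scoring function
`s(x) = Σ w_i σ_i(c_i(x)) / Σ w_i` whose key component is a learned property
predictor — a random forest `f_θ(x) = (1/B) Σ_i f_{θ_i}(x)` over Morgan count
fingerprints. Trained once on small, low-diversity assay data, the predictor
is then asked to score exactly the molecules the generator has steered away
from that data, and its confident mistakes become the optimization target.

`molhitl` closes the loop for the people who run such campaigns
(computational chemists and ML-for-chemistry researchers): after each
generation cycle it selects a small batch of generated molecules by an
acquisition criterion, collects expert verdicts on them (from a human via a
feedback CSV, or from a simulated noisy oracle `f*(x) + ε`,
`ε ~ N(0, σ_ε)`), converts agreement sliders into labels
`h_t = 1{a ≥ 0.5}` with confidences `u_t = max(a, 1 − a)`, and re-fits the
predictor with per-record weights `1/N₀` (initial data) and `u_t/T`
(feedback), so confident feedback pulls hardest. The acquisition criteria:

* **EPIG** — expected predictive information gain,
  `EPIG(x) = E_{p*(x*)} KL[ p(y, y* | x, x*) ‖ p(y|x) p(y*|x*) ]`, the
  expected mutual information between a candidate's predictive outcome and
  the outcomes at the score-weighted top-k pool molecules, computed in closed
  form from per-tree predictions;
* **uncertainty** — per-tree variance (regression) or predictive entropy
  (classification);
* **greedy** — the transformed predicted score;
* **random** — the baseline.

A diversity-filter memory (scaffold-keyed buckets with capacity and score
threshold) collects high-scoring generated molecules; its deduplicated
contents form the query pool. Everything runs offline: a combinatorial
fixture library stands in for a trained generator's proposal space, and two
built-in oracles (a penalized-LogP analogue and a synthetic fingerprint-linear
oracle) stand in for wet-lab truth. The package ships its own SMILES toolkit
(parser, canonicalizer, ECFP-style count fingerprints, Murcko scaffolds,
Tanimoto similarity) since no cheminformatics toolkit is available for R in
this environment.

## Worked example

```r
library(molhitl)

# an expert sets the agreement slider to 40%
agreement_to_feedback(0.40, "classification")
#>   agreement label confidence
#> 1       0.4     0        0.6

# desk-scale experiment: synthetic linear oracle, noise-free expert, EPIG
cfg <- loop_config(seeds = list(generator = 103, forest = 203,
                                expert = 303, acquisition = 403))
run <- run_experiment(cfg)
print(run)
#> <hitl_run> regression | epig acquisition | R = 3 rounds
#>   generation: 40 steps x 128 proposals per round; AL: L = 2 x T = 10
#>   expert calls: 60 | fine-tunes: 6
#>   round summary:
#>  round pool_size n_queries   mae_pre  mae_post
#>      1       187        20 0.8737179 0.9435370
#>      2       176        20 0.8021287 0.6388643
#>      3       177        20 0.7230895 0.7105252
```

Each round: 40 generation steps fill the scaffold memory (`pool_size`
high-scoring unique molecules), 2 AL iterations of 10 queries go to the
expert, and the forest is re-fitted with the confidence-weighted feedback.
`mae_pre`/`mae_post` is the mean absolute error between predicted and oracle
values on the top-100 not-yet-queried pool molecules before and after the
round's fine-tuning: it falls from 0.94 after round 1 to 0.71 after round 3,
while the seed-matched frozen-predictor baseline
(`loop_config(no_feedback = TRUE, ...)`) ends at 0.92 — the feedback loop
closes a quarter of the generalization gap with 60 queries, and the
generator's mean total score climbs (0.76 over the last steps) because it now
optimizes a predictor that agrees better with the oracle. `plot(run)` draws
both trajectories; `report(list(...))` aggregates replicate runs.

A thin CLI over the same functions is installed at `inst/cli/molhitl`
(subcommands `fixtures`, `run`, `baseline`, `evaluate`, `report`; JSON
configs).

## Acceptance script

`scripts/acceptance.R` recomputes the package's checkable reference
quantities from scratch — it runs the feedback-conversion rule on the worked
slider reading (agreement 40%) and reports the resulting confidence (in
percent) and binary label:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
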