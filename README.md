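# flowbo

Batch Bayesian optimization of mixed continuous/categorical reaction
conditions for continuous-flow chemistry.

Screening a flow reaction means tuning coupled settings — reagent
equivalents, catalyst loading (mol%), temperature, substrate concentration,
pump flow rate — plus an engineering variable with no numeric scale: the
micromixer (reactor) type. `flowbo` is for synthetic and process chemists
who want to drive such campaigns with a surrogate model instead of
one-variable-at-a-time screening, and for methods people who want a small,
fully seeded mixed-variable batch-BO engine to benchmark against.

## The method

- **Encoding.** Continuous parameters are min–max scaled to $[0,1]$; a
  $k$-way categorical becomes a one-hot block ($k$ coordinates, single 1).
  During acquisition optimization the block relaxes to fractional values
  and is decoded by nearest-vertex rounding — no descriptors or
  featurization of the categorical choices.
- **Surrogate.** Exact GP regression with a Matérn-5/2 ARD kernel over the
  encoded space; hyperparameters maximize the log marginal likelihood
  (multi-restart L-BFGS-B, seeded; noise floored at $10^{-6}$).
- **Acquisition.** Confidence bound on the maximized yield,
  $\alpha(x) = \mu(x) + \beta\,\sigma(x)$ (the LCB of the negated
  objective; $\beta = 2$ by default), plus closed-form expected
  improvement.
- **Batches.** $q$ conditions per round (default 3) by sequential
  hallucination (kriging believer): each selected point is "observed" at
  its posterior mean, shrinking variance there, before the acquisition is
  re-optimized. Proposals are snapped to per-parameter lab precision grids
  and deduplicated against the history and the growing batch.

The package ships transcriptions of two published 15-experiment flow
biaryl-coupling campaigns (6 screening runs + 3 BO rounds of 3) as
validated fixtures, a seeded synthetic flow-yield benchmark with
mixer-dependent optima, and a CLI for the propose → experiment → record
loop.

## Worked example

Replay the packaged campaign, then ask for the next batch as if standing
after the six screening experiments:

```r
library(flowbo)

t1 <- load_fixture("table1")
replay_stats(t1)
#> <flowbo_replay>
#>  round entries max_yield best_so_far
#>      0     1-6        75          75
#>      1     7-9        81          81
#>      2   10-12        79          81
#>      3   13-15        96          96
#>   overall best: 96% (entry 15)
```

The campaign started from six spread-out screening runs (best 75% NMR
yield), improved to 81% in the first batch, and ended at 96% with the
Comet X mixer. Proposing a fresh batch from the same six starting points:

```r
sp <- widened_space()
st <- new_campaign(sp, t1[1:6, ], acq_config(kind = "parallel_lcb", seed = 7))
model <- gp_fit(encode_conditions(sp, conditions_from_records(sp, t1[1:6, ])),
                t1$yield_pct[1:6], seed = 1)
propose_batch(st, model)
#> <flowbo_proposal> round 1, 3 conditions
#>   1. mixer=t_shaped equiv=2.7 tfoh_mol_pct=0.21 temp_c=75 conc_m=0.145 flow_ml_min=0.081  (acq 86.75)
#>   2. mixer=comet_x equiv=1 tfoh_mol_pct=0.79 temp_c=65 conc_m=0.139 flow_ml_min=0.184  (acq 80.94)
#>   3. mixer=t_shaped equiv=3.2 tfoh_mol_pct=0.7 temp_c=80 conc_m=0.118 flow_ml_min=0.191  (acq 80.05)
```

Three distinct, in-bounds, lab-grid conditions; the acquisition value is
the optimistic yield bound $\mu + 2\sigma$ at each proposed condition
(e.g. 86.75 means "plausibly up to ~87% yield here"). The exact conditions
depend on the seed — the published campaign's own suggestions are not
numerically reproducible because its GP internals were never published.

Residence time for a dual-feed reactor is `V / (2 f)`:

```r
residence_time(mixer_spec("comet_x", 2.4), 0.08)
#> [1] 15
```

The same workflow from a shell:

```sh
flowbo replay --records inst/extdata/table1.csv
flowbo suggest --records campaign.csv --acq parallel_lcb --batch 3 --seed 42
flowbo residence --mixer comet_x --flow 0.08
```

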