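---
title: "Methods: mixed-variable batch Bayesian optimization for flow reaction screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-variable batch Bayesian optimization for flow reaction screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowbo)
```

## The screening problem

Optimizing a continuous-flow reaction means tuning several coupled settings
at once: stoichiometry of the coupling partner, catalyst loading,
temperature, substrate concentration, pump flow rate — and at least one
*engineering* variable with no natural numeric scale, the micromixer
(reactor) type. Classical one-variable-at-a-time screening wastes material
and silently assumes the parameters are independent. `flowbo` implements a
batch Bayesian-optimization (BO) loop for this setting: a Gaussian-process
(GP) surrogate is fitted to all experiments run so far, an acquisition
function scores candidate conditions, and a batch of `q` conditions is
proposed for the next round of parallel experiments.

The package ships the design space of an organocatalytic biaryl
cross-coupling campaign — five continuous parameters (arenol equivalents,
TfOH mol%, temperature, concentration, per-stream flow rate) and one
categorical parameter (mixer ∈ {Comet X, β-type, T-shaped}) — together with
transcriptions of two real 15-experiment campaigns (`load_fixture("table1")`
and `"table2"`), each consisting of 6 initial screening runs followed by
three BO rounds of batch size 3.

## Encoding mixed variables

Continuous parameters are min–max scaled to $[0,1]$, so one shared
lengthscale prior is sensible across units as heterogeneous as °C and
mL/min. A categorical parameter with $k$ choices becomes a one-hot block of
$k$ coordinates: choice $j$ is the vertex with a single 1 in position $j$
(e.g. the three mixers map to `1 0 0`, `0 1 0`, `0 0 1`). During acquisition
optimization the block is *relaxed* to fractional values in $[0,1]^k$; a
relaxed block is decoded by the largest-component rule (nearest vertex),
with ties broken deterministically to the lowest choice index. This
relax-and-round treatment needs no chemical descriptors or featurization of
the categorical choices — the point of the method is that a reactor type can
be screened like any other variable.

Decoded proposals are finally snapped to a per-parameter *laboratory
precision grid* (defaults: 0.1 equiv, 0.01 mol%, 5 °C, 0.001 M,
0.001 mL/min), because a syringe pump cannot be set to 0.081437 mL/min. The
grids reproduce the printed precision of the packaged campaign tables.

Two space configurations ship with the package. `default_space()` carries
the announced screening ranges (e.g. temperature 20–60 °C).
`widened_space()` extends the bounds (equiv ≤ 3.5, TfOH 0.2–2.5 mol%,
15–85 °C, ≤ 0.15 M, flow ≥ 0.014 mL/min) because the recorded campaigns
contain optimizer-suggested conditions outside the initial ranges (85 °C,
3.5 equiv, 0.15 M…); the widened space is the default for replay and
benchmarking so every recorded condition validates.

## Residence time

All packaged reactors are fed by two syringe pumps at the same per-stream
rate $f$, so the residence time is $t_R = V/(2f)$ with $V$ the mixer volume
(Comet X 2.4 mL, β-type 2.7 mL, T-shaped 1.6 mL). A few printed residence
values in the source tables round this convention to the nearest half
minute (e.g. 5.5 min where $V/(2f) = 5.33$); the computed convention is
canonical in this package and the printed value is kept only as
informational data in the fixtures.

## The surrogate

The GP uses a Matérn-5/2 kernel with automatic relevance determination
(ARD): one lengthscale per encoded dimension, one-hot coordinates included.
No kernel is mandated by the screening methodology itself; Matérn-5/2 is
the standard BO default (smoother than Matérn-3/2, less restrictive than
squared-exponential), and treating one-hot dimensions as ordinary
coordinates is what makes the relax-and-round scheme consistent.

Yields are standardized per fit (mean 0, sd 1); a constant-yield degenerate
set uses sd 1 to avoid division by zero. Hyperparameters maximize the log
marginal likelihood by L-BFGS-B in log space with 5 seeded restarts (one
fixed default start, four log-uniform draws), within bounds: lengthscales
$[10^{-2}, 10]$ (unit-cube scale), signal variance $[10^{-2}, 10^{2}]$,
noise variance $[10^{-6}, 1]$ (the lower bound is the noise floor).
Cholesky factorizations escalate additive jitter from $10^{-10}$ to
$10^{-6}$ before failing; posterior variances are clamped at zero after
round-off, with the clamp count recorded on the prediction object. All of
this is covered by dense-inversion oracle tests at $10^{-6}$ tolerance.

One honest caveat: with ~20–30 observations in an 8-dimensional encoded
space, evidence maximization sometimes prefers a near-interpolating
solution (noise at the floor) even when the data are noisy. That is a real
property of maximum-likelihood type-II inference at small *n*, not a
numerical defect — the test suite verifies the chosen optimum beats random
hyperparameter draws — but it makes the surrogate overconfident near data
on some landscapes, which is visible in the benchmark results below.

## Acquisition and batches

The campaign maximizes yield, and the confidence-bound acquisition is kept
on that scale: $\alpha_{CB}(x) = \mu(x) + \beta\,\sigma(x)$ — the
optimistic bound on yield, identical to the lower confidence bound of the
negated objective. This is stated explicitly to avoid sign bugs; `beta`
defaults to 2.0 and is held constant across rounds to keep runs
interpretable. Expected improvement,
$\alpha_{EI}(x) = \mathbb{E}[\max(0, y - y^{*} - \xi)]$, is provided in
closed form for comparison.

Batches of `q` (default 3) conditions are built by *sequential
hallucination* (kriging believer): after each selection the surrogate is
conditioned on its own posterior-mean prediction at the selected point —
which shrinks variance there without moving the mean — and the acquisition
is re-optimized. The hallucinated surrogate keeps the fitted kernel and the
standardization frame; only the cached solve is rebuilt. Kriging believer
is used rather than a constant liar because it only removes variance,
matching the confidence-bound family of batch constructions.

Each inner optimization draws a seeded pool of `n_candidates` (default
4096) relaxed vectors uniform in the unit cube, locally refines the top 10
by projected finite-difference gradient ascent (batched central
differences, box-clipped; a deliberately derivative-free-friendly scheme
since the acquisition of a snapped candidate is piecewise constant in the
one-hot block), then decodes and grid-snaps every candidate. **Ranking and
the reported acquisition value use the snapped vertex encoding**, not the
relaxed point. This is a deliberate design choice: the acquisition value
attached to a proposal then refers to the condition actually proposed, and
batch construction on a fully enumerable space is *exactly* the
brute-force sequential-hallucination argmax, which the test suite verifies
by exhaustive enumeration on a 12-point space. Duplicates — against the
history or the growing batch, compared after snapping — are skipped in
ranked order; exhausting all candidates raises an error.

Everything is deterministic given (history, config, seed): candidate-pool
seeds derive from the config seed, round and batch slot; the surrogate fit
seed derives from the config seed and round. A campaign saved to JSON and
reloaded proposes byte-identical batches.

## Initial design

New campaigns default to a maximin Latin-hypercube sample over the
continuous dimensions (snapped to the lab grid) with balanced categorical
coverage — six points over three mixers gives each reactor two runs,
mirroring the recorded campaigns' six spread-out screening experiments. The
recorded campaigns' own entries 1–6 ship as fixtures and are used directly
when replaying.

## The synthetic benchmark

No mechanistic yield model exists for these couplings, so the in-silico
benchmark uses a seeded Gaussian-bump surface per mixer:
$$y(x, m) = A_m \prod_d \exp\!\left(-\frac{(x_d - o_{m,d})^2}{2 w_{m,d}^2}\right),$$
clipped to $[0, 100]$, with evaluation noise of sd 2 yield points
(reproducible given seed and call index — roughly NMR-yield
reproducibility). Per seed: the best mixer's amplitude is drawn
U[85, 100], every other mixer sits 10–30 points lower (so the categorical
choice matters), optima are drawn U[0.15, 0.85] per unit-scaled dimension
and widths U[0.4, 0.75]. The width range was chosen so that a uniformly
random condition scores around 40% of the mixer amplitude, matching the
28–75% spread of the six shared screening points in the packaged
campaigns; landscapes are redrawn per seed so no test can overfit one
surface.

The evaluation harness (`evaluate_optimizer()`) treats every optimizer
through the same interface: per seed it runs a full campaign (6 initial +
9 rounds × 3 for the default budget of 33, the same shape as the recorded
campaigns extended to a measurable horizon) and records the best-so-far
trace and the first evaluation reaching 95% of the true optimum (censored
at budget + 1 when never reached). The shipped comparison runs 20 seeds
per optimizer; with these problem sizes the full suite and the acceptance
script each run in minutes on one CPU.

What passing benchmarks do and do not show: the synthetic surface is
smooth, unimodal per mixer, and noise-homoscedastic; real yield surfaces
can have cliffs (decomposition above a temperature), interactions the
product form lacks, and drift. Benchmark success demonstrates the
machinery optimizes a plausible surrogate landscape better than random
sampling — not that it reproduces any particular real campaign. On these
landscapes the fixed-β confidence bound is exploration-heavy: it
reliably identifies the right mixer and clearly beats random search on
final best yield, but localizes the 5-dimensional continuous optimum to
within 5% in only a minority of seeds at budget 33 — random search
essentially never does (`scripts/acceptance.R` recomputes both counts).

## Replay of the packaged campaigns

`replay_stats()` recomputes what the recorded campaigns achieved:
campaign 1 improves from 75% (best of the six screening runs) through 81%
(first batch) to 96% in the final batch; campaign 2 reaches 69%. The exact
conditions those campaigns' optimizers suggested are *not* reproducible —
the original GP kernel, hyperparameters and acquisition internals are
unpublished — so the suite asserts behavioural properties instead
(distinctness and validity of proposals from the same starting data,
oracle equivalence of each layer), and reports, without asserting,
whether a first batch covers all three mixers as the recorded campaign's
did.

## Known limitations

- Box bounds only: no conditional parameters (e.g. a parameter that only
  exists for one mixer), no constraints, no multi-objective or cost-aware
  acquisition, no asynchronous batching.
- Exact dense GP only; fine for campaign-scale data (tens of experiments),
  unsuitable for thousands.
- Evidence maximization at small *n* can under-estimate noise (see above);
  a fixed-β confidence bound then over-trusts the interpolant. If a
  campaign's yields are known to be noisy, bounding `noise_bounds` from
  below at the known replicate variance is the pragmatic fix.
- The categorical treatment assumes a handful of choices; a one-hot block
  per hundreds-level categorical would bloat the ARD space.
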