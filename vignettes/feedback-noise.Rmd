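---
title: "Feedback-loop placement and AMP expression noise: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-loop placement and AMP expression noise: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the circuits

Innate immune signaling pathways are wrapped in negative feedback loops
(NFLs) that act at different cellular locations: near the receptor (the Imd
pathway's Pirk, which removes cell-surface receptors) or at the transcription
factor (the Imd Repressosome, which competes with NF-kB for the AMP promoter,
and the Toll pathway's Cactus, which removes active NF-kB before it reaches
the nucleus). `ampnoise` implements minimal stochastic circuits for the two
architectures and asks how NFL placement shapes *intrinsic noise* in
antimicrobial-peptide (AMP) expression, and how the loops evolve when AMP
overexpression is costly.

Each circuit tracks six counts: bacteria `B`, free receptors `R`, active
NF-kB `N`, Pirk `P`, the downstream-NFL protein `S` (Repressosome or Cactus)
and AMPs `A`. The reaction channels are:

* bacterial set: proliferation (`k0 * B`) and AMP-mediated elimination
  (`kappa_kill * A * B`);
* immune set: receptor production `beta1 * N` (the positive feedback loop,
  PFL), NF-kB activation `beta2 * R * B` (receptor and bacterium catalytic),
  Pirk production `beta3 * N`, downstream-NFL production `beta4 * N`, AMP
  production (below), Pirk-mediated receptor removal `delta_pirk * P * R`,
  and first-order degradation `lam * X` of every immune protein
  `X in {R, N, P, S, A}`. The Toll variant adds Cactus-mediated NF-kB removal
  `c_cactus * S * N`.

The bacteria–receptor complex is implicit (both species catalytic in the
activation channel), Pirk acts catalytically, and bacteria change only
through their own set. The constants `kappa_kill`, `delta_pirk` and
`c_cactus` are structural couplings with no further biological anchoring;
they default to 1 and are configurable.

## The AMP production rate

Cactus never appears in the Toll AMP rate, which is `beta5 * N / Zn`. For the
Imd model the Repressosome competes with NF-kB at the promoter with binding
energies `Zn`, `Zs` (smaller = stronger binding); with `Zn = Zs` the
competition factor `(N/Zn) / (N/Zn + S/Zs)` depends only on the
Repressosome-to-NF-kB ratio. Three forms are available (`amp_form`):

* `"competitive"` (default): `beta5 * (N/Zn) * (N/Zn)/(N/Zn + S/Zs)`. Chosen
  as the default because it reduces *exactly* to the Toll rate when `S = 0`,
  so the two topologies differ only through the downstream NFL — with both
  NFLs knocked down, Imd and Toll trajectories are bit-identical under the
  same seed, which is both a model-design requirement and a convenient
  engine cross-check.
* `"occupancy"`: `beta5 * (N/Zn)/(N/Zn + S/Zs)`, occupancy-only and bounded
  by `beta5`. With `S = 0` this is flat in `N` (any positive NF-kB count
  saturates the promoter), which decouples AMP output from NF-kB abundance
  and makes the no-NFL Imd and Toll circuits different objects.
* `"leaky"`: `beta5 * (N/Zn)/(1 + N/Zn + S/Zs)`.

Ratio forms are defined as 0 when the total promoter weight is below `1e-9`;
integer stochastic states never trip the floor, which exists to keep the ODE
Jacobian (which grows like `1/(N/Zn + S/Zs)`) bounded as both species decay.

## The stochastic engine

Time is discrete with host lifetime `T = 1000` steps. Per step at most two
reactions fire: one from the bacterial set and one from the immune set, each
chosen with probability proportional to its propensity *within its set*
(nothing fires from a set whose total propensity is zero). Both sets are
evaluated on the step's starting state and the two state changes are applied
jointly; whether the immune propensities should instead see the post-bacterial
state is not determinable from the model description, and the joint
convention was fixed for bit-reproducibility. Two consequences of the scheme
are worth keeping in mind when reading results:

* rates act only *relatively* within a set. With `A = 0` the bacterial set
  has a single positive channel, so `B` grows by one every step regardless of
  `k0`; `k0` matters through the proliferation-versus-elimination ratio
  `k0/(k0 + kappa_kill * A)` once AMPs appear.
* adding channels (e.g. switching on a strong NFL) dilutes the per-step
  probability of every other immune reaction, which slows the circuit's
  effective clock as well as redistributing flux.

Pathogen encounters add `inoculum` (default 1) bacteria at
`t = 0, period, 2*period, ...` for every multiple below `T`, applied before
that step's reactions; with the default period 200 and `T = 1000` the host
sees five encounters. The initial state is empty except for a single seed
receptor `R0 = 1`: receptor production requires NF-kB and NF-kB activation
requires receptors, so an all-zero start is absorbing and one receptor is the
minimal ignition. Both `R0` and the inoculum are configurable; the matched
noise directions reported by `analysis/01_matched_noise.R` were checked to be
insensitive to `R0` in 1..20.

A structural property of this reaction set: once `R = N = 0` the immune
pathway can never re-ignite (later encounters only add bacteria), so
replicates that lose the response accumulate bacteria for the rest of the
lifetime. Lifetime-mean bacterial loads, and hence absolute fitness values
`exp(-(B + A))`, are therefore astronomically small for many parameter sets;
only fitness *comparisons* are meaningful.

Randomness: every trajectory runs on an `mt19937_64` stream with an explicit
53-bit uniform (no library distribution objects, so streams are identical
across platforms), seeded by `splitmix64` from `(base_seed, replicate)`.
Ensembles are therefore reproducible, chunkable (`rep_offset`) and parallel
safe; sweep grid points derive their seeds from `(base_seed, grid_index)` so
adding regimes never reshuffles existing points.

## The deterministic engine

`solve_deterministic()` integrates the mass-action counterpart (raw rates as
written above) with the BDF method, `atol = 1e-6`, `rtol = 1e-8`, restarting
at each encounter jump. Because one immune reaction fires per stochastic
step, the ODE with raw rates is *not* the literal mean-field limit of the
stochastic engine, and only qualitative comparisons between the two are
meaningful (the package compares them through fitness, never trajectory-wise).
Two numerical regularizations, both inert for healthy states:

* the vector field is evaluated on the state clamped to `>= 0`, so a
  tolerance-level undershoot of zero is not amplified by growth terms like
  `k0 * B`;
* species below an extinction cutoff of `1e-9` are treated as absent.
  Without this, a cleared infection leaves `B ~ 1e-12` which regrows
  exponentially and re-ignites the system at a time set by integration
  error — solutions then depend qualitatively on `rtol`. With the cutoff,
  extinction is absorbing exactly as it is for the integer-valued stochastic
  model, and halving `rtol` moves integer-grid outputs by `< 1e-6` relative.

## Noise metrics and the matched comparison

Noise at time `t` is the coefficient of variation of AMP counts across
replicates, with the population standard deviation (no finite-sample
correction; the convention matters only at tiny ensembles) and `CV = 0` when
mean and standard deviation are both zero — note this makes a fully silent
circuit "quiet", so die-out reduces measured noise. The circuit's noise score
and average expression are arithmetic means over all `T + 1` recorded time
points of the columnwise CV and mean.

Because CV is confounded with the mean, regimes are compared only between
background parameter sets with (nearly) the same average AMP expression: all
cross pairs within a tolerance (`delta_noise_matched()`), with a greedy
one-to-one nearest variant as an option. The full-scale convention is
`|dAvg| <= 0.001` with 10,000 replicates; desk-scale runs loosen it to 0.05
because exact matches are rare on sparse grids. This looser matching is the
main caveat of desk-scale output: with 200 replicates the Monte-Carlo
standard error of the average exceeds 0.05 for moderately expressed
circuits, so many "matches" pair circuits whose true averages differ, and
the upstream-NFL amplification — which concentrates where expression is low
and matching is dense — is diluted by sign-mixed pairs from the
high-expression region. Densifying the grid and tightening the tolerance
recovers it; the packaged analyses report the low-expression stratum
separately for this reason.

`pfl_slope_analysis()` regresses the noise score on the swept PFL strength
`beta1` (or the positive regulator `beta2`) by ordinary least squares within
each fixed background combination; at full granularity this yields exactly
1,000 slopes per regime.

## Evolutionary simulations

Six parameters evolve: `beta1, beta2, beta5` and `lam` (backgrounds) plus
`beta3, beta4` (the NFLs), on grids 1..10 (step 1) and 0.1..1 (step 0.1),
initialized uniformly on those grids. Each generation mutates one uniformly
chosen parameter by one step in a random direction; proposals leaving the
bounds are rejected, not clamped (clamping would bias boundary occupancy).
Fitness is `exp(-(B + A))` with `B`, `A` lifetime means (or `exp(-B)` for the
load-only variant), estimated from `n_eval` replicate simulations; a mutant
is accepted only if its estimate *strictly* exceeds the incumbent's cached
value. Caching is the literal reading of greedy acceptance, but under noisy
independent-stream estimates the cached value is a running maximum of noise
and the search slows once it exceeds the true fitness; `use_crn = TRUE`
evaluates every candidate on one common stream to remove this flicker, and
`re_evaluate_incumbent = TRUE` is the conservative alternative. Both are off
by default to keep the base algorithm minimal. Lineages whose end-of-run
noise (estimated on a fixed `noise_reps` ensemble) exceeds the initial noise
by more than 5% relative are flagged `noise_increased`; final architectures
are classified by whether `beta3`/`beta4` exceed 5, the midpoint of their
range.

## Problem sizes

The packaged analyses and checks run at desk scale: 3 levels per background
parameter (81 sets per regime), 200 replicates per set, lifetime 500 for the
sweep comparisons; 27 fixed combinations x 10 PFL levels for the slope
analysis; 20 lineages x 300 generations with 20 evaluations per fitness call
for the evolutionary runs. The corresponding full-scale design is 10 levels
(10,000 sets per regime, 40,000 across regimes), 10,000 replicates, lifetime
1,000, and 500 lineages x 5,000 generations; all of it is reachable with the
same functions by changing `sweep_spec()` / `evolve_config()` arguments.

## Known limitations

* Desk-scale matched comparisons are noisy and tolerance-limited (above);
  directional medians can flip sign relative to dense-grid runs.
* The synthetic conditions model intrinsic reaction noise only: no extrinsic
  parameter fluctuations, no explicit ligand chemistry or complex species,
  no transcription–translation separation, no compartments. Passing checks
  say nothing about those features of real pathways.
* Greedy hill climbing with noisy evaluations at desk scale moves parameters
  slowly; outcome shares from 300-generation runs are indicative, not
  converged.
* The deterministic engine shares the reaction structure but not the
  stochastic engine's clock; compare the two only through summary
  functionals.
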