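---
title: "Methods: adaptive social distancing on a lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive social distancing on a lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidistance)
```

This vignette documents the models implemented in `epidistance`, the
assumptions behind them, and the numerical and design choices that a user
should know before trusting the output.

## The spatial and epidemic model

Individuals occupy the nodes of a bounded `side x side` square lattice
(default 50 x 50, N = 2500) with no periodic wrapping. Neighbourhood
membership is Euclidean: `j` is a neighbour of `i` when their distance is at
most the awareness radius `r0` (default 4, giving at most 48 neighbours;
fewer near an edge). Distances are compared as squared integers against
`r0^2`, so membership at the radius boundary is exact and never subject to
floating-point misclassification. The bounded (non-periodic) boundary is a
deliberate choice: at full contact the 50 x 50 lattice then carries exactly
56 054 undirected neighbour pairs per step (56.05 million over the 1000-step
horizon), whereas a torus would carry 60 000.

Disease dynamics are discrete-time stochastic SIR. Within one step, in this
order:

1. every susceptible observes its infection load `I` (infected neighbours /
   total neighbours within `r0`, always evaluated on the full awareness
   neighbourhood regardless of the current contact radius) and sets its
   contact radius `r = r0 * sqrt(1 - I^alpha)` with its current risk
   attitude `alpha`; infected and recovered individuals keep radius `r0`
   (the response model is posed for susceptibles only);
2. contacts form;
3. every susceptible with `m` infected contacts becomes infected with
   probability `1 - (1-p)^m` (independent per-contact transmission with
   probability `p`, default 0.05);
4. every individual infected *before* the step recovers with probability `q`
   (default 0.2); a newly infected individual cannot recover in the same
   step.

Updates are synchronous. A run starts with `floor(I0 * N)` infected placed
uniformly at random (default `I0 = 0.06`) and stops when no infected remain
or at `max_steps` (default 1000; games use 60).

Two contact rules coexist, and they are intentionally different:

* **transmission** uses the susceptible's own radius: it makes contact with
  all neighbours within its chosen radius, and each infected one is a
  transmission opportunity; the infected partner's radius is not consulted;
* **contact-volume accounting** counts unordered pairs once, and requires
  the distance to be within *both* radii (the "min rule") — the symmetric
  completion of "contact with all neighbours within the infection radius".
  At full radii this reproduces the 56 054 pairs/step bookkeeping above.

Whether a pair contact should instead require only one-directional inclusion
is not determinable from the bookkeeping we reproduce; the min rule is the
choice, documented here, and `count_pairs()` implements it symmetrically.

Outcome definitions: the **attack rate** is the final fraction ever infected
(recovered, plus infected at the cap for censored runs); the **peak attack
rate** is peak prevalence — the maximum fraction *simultaneously* infected,
including the initial seeding — not peak incidence; the **duration** is the
first step with zero infected (or the cap); the **contact volume** sums the
per-step pair counts and adds the full-contact count for every step between
epidemic extinction and the horizon, since full contact is assumed to resume
once the epidemic is over.

## The cognitive model and its inversion

`response_radius(I, alpha, r0)` is monotone decreasing in the load and
increasing in the attitude, with `r(0) = r0` and `r(1) = 0`. Its inverse
`infer_alpha(r, I, r0) = log(1 - (r/r0)^2) / log(I)` is defined only when
infection is present and contact was reduced (`0 < I < 1`, `r < r0`). We
also map `I = 1` to undefined: the denominator `log(1)` would be zero, and
at `I = 1` the response forces `r = 0` regardless of `alpha`, so the step
carries no information about the attitude. Undefined steps return the typed
sentinel `NA_real_` and are excluded from every analysis — never coerced to
zero or infinity.

Radii are continuous reals throughout (the participatory game lets a player
resize a circle continuously); the lattice discretizes contact *sets*, not
radii.

**Numerical domain of the inversion.** The round trip
`infer_alpha(response_radius(I, alpha), I)` is an algebraic identity, and in
double precision it holds to ten significant figures wherever
`I^alpha >= ~1e-6`. Below that, `1 - I^alpha` is within rounding of 1, the
chosen radius is within machine rounding of `r0`, and the cancellation in
`1 - (r/r0)^2` destroys the trailing figures; below `2e-16` the radius
*equals* `r0` in double precision and the step is undefined by the domain
rule — the numerical analogue of a player being unable to express a radius
that close to the maximum. Tests assert the identity on a grid restricted to
this representable domain.

## The population model

`log alpha_{i,k,t} = mu + lambda_i + eta_{i,k} + eps_{i,k,t}` with
independent zero-mean normal components: `lambda` per participant, `eta` per
participant-game, `eps` per step. The shipped presets are the fitted Models
A-D; Model A (`mu = -1.934`, sds 0.7354 / 0.2730 / 0.5833) is the default
behavioural model for simulations.

In epidemic runs each agent is its own "participant" (`lambda` drawn per
agent per run) and each replicate run plays the role of one "game" (`eta`
redrawn per agent per run); `eps` is redrawn every step. Whether the game
effect should instead be frozen across replicates is not observable from
single-run outcomes; per-replicate redraw is the choice, and since `eta`
enters the per-step attitude exactly like `lambda`, the alternative only
reallocates variance between the two run-constant components.

## The synthetic gameplay generator

`generate_game()` embeds one focal susceptible in the simulation with the
game mechanics: 60-day cap, game over on focal infection (no points that
day), survivor status when the epidemic dies out (bonus points equal to
full-contact day-equivalents through day 60), points equal to the focal
player's contacts each completed day. The focal player's radius follows the
response curve at its true per-day attitude; the computer-controlled
susceptibles adopt the focal player's *effective* attitude each day — the
inversion of its observed choice, which equals the generating attitude
whenever defined. On undefined days they keep the previous value, and before
any defined day they do not respond (full radius); how the original game
handled those days is unknown, and this choice is the most conservative
(no information, no response).

What the generator emulates: the mechanics, the end conditions, the points,
and the nested log-normal attitude structure. What it deliberately does not
emulate: human learning across games (the practice-game effect — first games
being systematically shorter — is a property of people, not of this
generator), deviations from the response model (players who *raise* contact
under load), and any coupling between psychology and behaviour. Passing
tests therefore show that the pipeline is correct and well calibrated on
model-generated behaviour; they cannot show that the response model is true
of people. One visible consequence: the per-game MAPE distribution of
synthetic cohorts is only mildly right-skewed, whereas human cohorts show a
heavy tail driven by games that contradict the model.

## The inference pipeline

Traces are filtered before analysis: the first game of each participant
(practice), games beyond the fifth, and one-step games are dropped. The
inversion is applied day by day; only defined days enter. A game's attitude
summary is the geometric mean of its per-day attitudes, its fit quality the
mean absolute percentage error `MAPE_k = 100/n_k * sum |r - rhat| / r` over
its `n_k` defined days, with `rhat` predicted from the response curve at the
geometric-mean attitude. Zero denominators cannot occur on defined days
(`r = 0` implies `I = 1`, which is excluded); this is asserted, not skipped.
Games with no defined day carry a no-fit marker (`n_steps = 0`, `NA`
estimates). The per-game 95% interval for the attitude is a t-interval on
the mean log attitude — the construction is a documented guess, as the
interval convention is not fixed by the analysis we mirror. Cohort skewness
is the adjusted Fisher-Pearson coefficient (the common software default),
with the convention that degenerate samples have skewness 0.

## Variance-component fitting

Models A-C are fitted by marginal maximum likelihood (`REML = FALSE`) with
`lme4::lmer`; ML rather than REML so that AIC comparisons across the model
family are coherent. Model D is the closed-form normal MLE. Free-parameter
counts for AIC: 2 (D), 3 (B), 3 (C), 4 (A). Model C is interpreted as a
game-*number* random effect shared by all participants (`eta_k`,
k = 2..5) — treated as random, not fixed — since one is interested in an
unspecified population of games; this interpretation is documented rather
than derivable. Unbalanced designs are supported throughout. An independent
closed-form marginal likelihood for the one-way layout, optimized directly,
cross-checks the lme4 route in the tests.

## Experiment drivers and reproducibility

`run_sweep()` and `headline_comparison()` derive one child seed per
(grid value, replicate) cell from the master seed by hashing the pair, so
grids can be extended without perturbing existing cells and all outputs are
deterministic under the master seed. Early-terminating runs use the analytic
post-epidemic contact accounting (`(max_steps - duration) * 56 054` full
pairs) rather than simulating the quiet tail, which keeps the headline
experiment (100 replicates x 2 arms) to about half a minute on one CPU.

Problem sizes used by the shipped checks, chosen as desk-scale defaults:
the headline comparison at 100 replicates per arm on the full 50 x 50
lattice; the baseline-attitude sweep on a 25-point grid over [-5, 1]
(6 replicates per point in the test suite; 100 is the production default);
sensitivity sweeps on coarse p and q grids; parameter recovery on 20
synthetic cohorts of 230 participants x 4 games with log-normal game lengths
centred on 14 steps; pipeline recovery through the full gameplay generator
on a 60-participant x 5-game cohort.

## Known limitations

* The lattice is bounded and square; no other topologies are provided.
* No latent period, reinfection, or vaccination; recovery is memoryless.
* The attitude components are normal on the log scale with no temporal
  autocorrelation in `eps`.
* Simulated outcomes near the cautious/relaxed transition in the baseline
  attitude are highly variable; means there depend visibly on the replicate
  budget.
* The generator cannot, by design, reproduce human-cohort statistics that
  reflect off-model behaviour (e.g. the heavy MAPE tail, or the exact
  attitude moments of a real cohort).
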