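# epidistance

Spontaneous social distancing in lattice epidemics, driven by individual
risk attitude.

`epidistance` is an individual-based SIR simulator in which susceptible
individuals *choose* how much contact to make. A population of N = side²
individuals sits on a bounded square lattice. Each individual observes the
infection load in its awareness neighbourhood of radius r₀ — the fraction
I ∈ [0, 1] of infected among its (at most 48, for r₀ = 4) neighbours — and
sets its contact radius for the next step by the response curve

    r = r₀ √(1 − I^α),        α > 0,

where α is the individual's **risk attitude**: small α is cautious (contacts
collapse at the first sign of infection), large α is relaxed (near-full
contact until the neighbourhood saturates). Contacts within the chosen
radius transmit infection with probability p per contact; infected
individuals recover with probability q per step and stay immune.

Observed behaviour can be mapped back to an **effective risk attitude** by
inverting the curve wherever infection is present and contact was reduced
(0 < I < 1, r < r₀):

    α = log(1 − (r/r₀)²) / log(I).

Population heterogeneity enters through a nested random-effects model of the
log risk attitude,

    log α_{i,k,t} = μ + λᵢ + η_{i,k} + ε_{i,k,t},

with participant, game (run), and time components, each zero-mean normal.
The package ships the fitted variants as presets (Models A–D; Model A:
μ = −1.934, σ_λ = 0.7354, σ_η = 0.2730, σ_ε = 0.5833) and can refit all
four to data by maximum likelihood with AIC comparison.

The package is for modellers studying behavioural epidemiology on spatial
networks: it reproduces, at desk scale, the simulation finding that
realistically moderate spontaneous distancing leaves epidemics invasive
(attack rate ≈ 0.82 vs 1.00 without response) while strongly suppressing the
peak attack rate (≈ 0.23 vs 0.67), at the cost of longer epidemics and fewer
social contacts.

## What's inside

* `build_geometry()`, `count_pairs()` — bounded-lattice Euclidean
  neighbourhoods and symmetric contact-pair counting.
* `response_radius()`, `infer_alpha()` — the response curve and its exact
  inversion (undefined steps return `NA`).
* `risk_model_preset()`, `sample_log_alpha()` — nested population models of
  log risk attitude.
* `simulate_epidemic()` — the behavioural SIR dynamics with attack rate,
  peak attack rate, duration, contact volume, and S/I/R series.
* `generate_game()`, `generate_cohort()`, `write_traces()`/`read_traces()` —
  a synthetic participatory-game generator (a focal "player" inside the
  simulation, 60-day games, points for contacts, survivor bonus).
* `filter_games()`, `extract_alphas()`, `game_fit()`, `summarize_alphas()` —
  the trace-inference pipeline (practice/late/one-step game filtering,
  inversion, geometric-mean attitude per game, MAPE fit quality).
* `fit_risk_model()`, `compare_risk_models()` — ML fits of Models A–D with
  `tidy()`/`glance()` methods.
* `run_sweep()`, `sensitivity_sweep()`, `headline_comparison()`,
  `autoplot()` — replicated experiment drivers and their plots.
* `inst/cli/epidistance.R` — a thin command-line front end
  (`simulate`, `headline`, `sweep-mu`, `generate-games`, `infer`,
  `fit-models`, ...).

## Worked example

```r
library(epidistance)

geom <- build_geometry(50, 4)
geom
#> <lattice_geometry> 50x50 bounded lattice, r0 = 4
#>   2500 nodes, 56054 undirected neighbour pairs (max 48 neighbours/node)

sim <- simulate_epidemic(geom, epidemic_params(), risk_model_preset("A"),
                         seed = 42)
glance(sim)
#> # A tibble: 1 x 6
#>   attack_rate peak_attack_rate duration contact_volume completed n_agents
#>         <dbl>            <dbl>    <int>          <dbl> <lgl>        <int>
#> 1       0.812            0.239       58       55206052 TRUE          2500
```

One run under Model A behaviour: 81.2% of the 2500 individuals were ever
infected, at most 23.9% simultaneously; the epidemic lasted 58 steps, and
55.2M undirected contacts took place over the 1000-step horizon (full
contact resumes once the epidemic is over; the no-response count would be
56054 × 1000 = 56.05M).

The gameplay–inference loop recovers behaviour from traces:

```r
traces <- generate_cohort(geom, n_participants = 20, n_games = 5, seed = 7)
records <- traces |> filter_games() |> extract_alphas()
summarize_alphas(records)
#> # A tibble: 2 x 5
#>   scale         n   mean    sd skewness
#>   <chr>     <int>  <dbl> <dbl>    <dbl>
#> 1 alpha      1114  0.165 0.209    5.43
#> 2 log_alpha  1114 -2.20  0.842    0.372

fit_risk_model(records, "A")
#> <risk_model_fit> model A (ML), n = 1114
#>   mu = -1.758, sd(participant) = 0.6957, sd(game) = 0.3757, sd(time) = 0.5925
#>   logLik = -1082.59, AIC = 2173.2
```

The effective risk attitudes are strongly right-skewed on the natural scale
and near normal on the log scale, and the nested fit recovers the generating
baseline μ = −1.934 to within sampling error of a 20-participant cohort.

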