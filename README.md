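# sizedist

Bayesian observer models for size-aided distance perception.

A monocular view of an object constrains only the ratio of its physical
size to its distance: by the small-angle identity, visual angle =
size / distance. Touching the object and feeling its size resolves the
ambiguity — the Bayes-net *explaining-away* pattern. `sizedist` is for
computational psychophysicists who want to ask, from interception-style
response data, *how* that resolution happens: whether the haptic cue is
integrated at all, whether the observer knows the cues' reliabilities,
and whether responses look like MAP estimates or like averages of a few
posterior samples.

## The model

Everything is linear-Gaussian in natural-log coordinates. With $d$, $s$
the log-distance and log-size of a trial, the cues are
$\phi \sim N(s-d, \tilde\sigma_\phi^2)$ (log visual angle) and, on haptic
trials, $h \sim N(s, \tilde\sigma_h^2)$; the observer holds priors
$d \sim N(\mu_d, \sigma_d^2)$, $s \sim N(\mu_s, \sigma_s^2)$ and assumed
noise SDs $\sigma_\phi, \sigma_h$. Marginalizing $s$ gives a Gaussian
posterior over $d$,

$$\mu_{post} = -w_\phi \phi + w_h h + w_s \mu_s + w_d \mu_d, \qquad
  \sigma^2_{post} = \sigma_d^2\, w_d,$$

with weights $w_\phi = (v_d v_s + v_d v_h)/D$, $w_h = v_d v_s / D$,
$w_s = v_d v_h / D$, $w_d = (v_\phi v_s + v_\phi v_h + v_s v_h)/D$,
$D = v_d v_s + v_d v_h + v_\phi v_s + v_\phi v_h + v_s v_h$ (the
no-haptic form is the $v_h \to \infty$ limit). A MAP observer reports
$\mu_{post}$; a sample-averaging observer the mean of $K$ posterior
draws; both add motor noise $N(0, \sigma_m^2)$. Crossing the four
structural questions (haptic use, haptic knowledge, image knowledge,
decision rule) yields 12 candidate models with 6–10 free parameters each.
The chain is linear-Gaussian throughout, so each trial's judged
log-distance has a closed-form Normal likelihood; parameters are fitted
by random-walk Metropolis-Hastings under wide uniform priors and models
are ranked by DIC (gaps > 10 significant, > 15 highly significant).

The closed-form posterior is certified in the test suite against an
independent 2-D grid-integration oracle, and the closed-form response
likelihood against large-scale forward simulation.

## Worked example

Simulate the default experiment (1280 trials, day 1 excluded → 960) from
a known observer, fit three structural rivals, compare by DIC:

```r
library(sizedist)

cfg <- schedule_config()                  # 4 days x 4 blocks x 80 trials
sched <- generate_schedule(cfg, seed = 8)
analysis <- apply_training_exclusion(sched, cfg)
st <- stimulus_log_stats(analysis)

m7 <- observer_model(7)   # haptic, overestimated haptic noise, sampling
theta <- c(sigma_phi = 0.08, sigma_h_true = 0.06, sigma_h = 0.12,
           mu_d = st$mean_log_distance, sigma_d = st$sd_log_distance,
           mu_s = st$mean_log_size, sigma_s = st$sd_log_size,
           sigma_m = 0.02, K = 2)
records <- simulate_responses(analysis, theta, m7, seed = 9)

fits <- list()
for (id in c(3, 7, 8)) {            # 3: no-haptic twin, 8: MAP twin
  fits[[sprintf("model_%d", id)]] <- fit_model(
    records, observer_model(id),
    sampler = sampler_config(chains = 4, burnin = 1500, samples = 1000),
    seed = 10 + id)
}
reports <- suppressWarnings(lapply(fits, dic, records = records))
tab <- rank_models(reports)
print(tab[, c("model_id", "DIC", "delta_vs_best", "significance")], digits = 6)
```

```
  model_id      DIC delta_vs_best       significance
1        7 -1491.52        0.0000               best
2        8 -1452.40       39.1209 highly significant
3        3 -1150.29      341.2282 highly significant
```

The generating structure wins: ignoring the haptic cue (model 3) costs
341 DIC points, and the MAP twin (model 8) — which cannot reproduce the
extra no-haptic response variability a sample-averaging observer shows —
costs 39. Fitted sensory SDs convert to Weber fractions via
`weber_fraction()` (here `exp(sigma) - 1` of the fitted image-noise SD
prints `0.040`, i.e. a 4% just-noticeable size change), and
`parameter_report()` juxtaposes fitted priors with
`stimulus_log_stats()`.

The same loop is available as a pipeline (`run_simulate()`, `run_fit()`,
`run_compare()`, `run_recover()` with a YAML config) and as a CLI:

```sh
inst/cli/sizedist recover --config run.yaml --seed 1 --out out/
```

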