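---
title: "Observer models for size-aided distance perception: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer models for size-aided distance perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sizedist)
```

## The problem

A monocular view of a ball constrains only the ratio of its physical size to
its distance: by the small-angle identity, visual angle = size / distance. A
felt (haptic) size cue says nothing about distance directly, but by pinning
down the size it disambiguates the visual angle — the Bayes-net
"explaining-away" pattern. `sizedist` implements a family of probabilistic
observers for this computation, a synthetic interception experiment to
exercise them, per-trial response likelihoods, Metropolis-Hastings parameter
inference, and DIC model selection, so that the full
simulate-fit-compare-recover loop runs end to end with known ground truth.

## The generative model

All quantities live in natural-log coordinates (distances and sizes in
log-mm, visual angle in log-radians), for two reasons: Weber-Fechner scaling
makes noise SDs approximately constant in log space, and the model becomes
linear-Gaussian and hence closed-form. Writing $d$ and $s$ for log-distance
and log-size:

* image cue: $\phi \mid d, s \sim N(s - d,\ \tilde\sigma_\phi^2)$ (the
  small-angle identity is used exactly, with no tangent correction);
* haptic cue (haptic trials only): $h \mid s \sim N(s,\ \tilde\sigma_h^2)$;
* observer priors: $d \sim N(\mu_d, \sigma_d^2)$, $s \sim N(\mu_s, \sigma_s^2)$.

Tildes mark *true* noise magnitudes; untilded SDs are the observer's
*assumed* ones. Marginalizing $s$ out of the joint posterior gives a
Gaussian posterior over $d$ whose mean is a weighted combination of the
cues and prior means. With $v_\ast$ for variances and
$D = v_d v_s + v_d v_h + v_\phi v_s + v_\phi v_h + v_s v_h$:

$$w_\phi = \frac{v_d v_s + v_d v_h}{D},\quad
  w_h = \frac{v_d v_s}{D},\quad
  w_s = \frac{v_d v_h}{D},\quad
  w_d = \frac{v_\phi v_s + v_\phi v_h + v_s v_h}{D},$$

$$\mu_{post} = -w_\phi\,\phi + w_h\,h + w_s\,\mu_s + w_d\,\mu_d,
  \qquad \sigma^2_{post} = v_d\, w_d.$$

When the haptic cue is not used (or unavailable), the same marginalization
with $v_h \to \infty$ gives $w_\phi = w_s = v_d / (v_d + v_\phi + v_s)$,
$w_d = 1 - w_\phi$, $\mu_{post} = w_\phi(\mu_s - \phi) + w_d \mu_d$, and
$\sigma^2_{post} = v_d (v_\phi + v_s)/(v_d+v_\phi+v_s)$. These closed forms
were derived by precision-matrix marginalization and are *certified* in the
test suite against an independent 2-D grid-integration oracle
(`tests/testthat/helper-oracle.R`, step 0.002, span ±6 SD) to relative
error below $10^{-3}$ on 100 random parameter/sensation tuples — in
practice they agree to ~$10^{-12}$. The identities $w_h + w_s + w_d = 1$
and $w_\phi = w_h + w_s$ hold for all positive variances, and the haptic
posterior variance is strictly smaller than the no-haptic one for any
finite $\sigma_h$.

Decisions: a MAP observer reports $\mu_{post}$; a sample-averaging observer
reports the mean of $K$ independent posterior draws, which is distributed
$N(\mu_{post}, \sigma^2_{post}/K)$ — equivalently one draw from the
renormalized $K$-th power of the posterior. Additive motor noise
$N(0, \sigma_m^2)$ (log-mm) is applied either way. Because every stage is
linear-Gaussian, the judged log-distance given the true scene is exactly
Normal, which gives the closed-form per-trial likelihood used in fitting;
there $K$ is treated as a continuous positive parameter, while the forward
simulator rounds it to the nearest integer ≥ 1.

## The candidate family

Twelve models span four structural questions: haptic cue used or not;
assumed haptic noise equal to the true value (coupled) or free; likewise
for the image noise; MAP versus sample averaging. Merging the
haptic-knowledge variants of the no-haptic observers (for whom the question
is moot) leaves 12. Canonical ids: 1–4 no-haptic, 5–12 haptic, odd =
sample-averaging, even = its MAP twin; model 7 = haptic / inaccurate haptic
knowledge / accurate image knowledge / sampling, model 11 its
accurate-haptic twin, model 5 the inaccurate-image variant of 7, model 3
the no-haptic variant of 7. (The source literature's figure captions number
the MAP variant of model 7 as "10"; under this package's odd/even scheme it
is model 8. The mapping is printed in every comparison-report header so ids
never change meaning.) Free-parameter counts run from 6 (no-haptic,
accurate image knowledge, MAP) to 10 (haptic, both knowledges free,
sampling); coupled true/assumed pairs share one entry.

## The synthetic experiment

`generate_schedule()` reproduces the emulated interception experiment's
design: 4 days × 4 blocks × 80 trials (1280 total), ball diameter uniform
on [14, 42] mm, crossing distance uniform on [300, 640] mm, speed uniform
on [250, 375] mm/s, day 1 excluded as training (leaving 960 trials). The
two conditions are balanced exactly half/half *within every block*, in
random order; the source design states only "equal proportions", but
per-block balance yields the exact 480 + 480 split and slightly lower
variance, and is the documented assumption. Speeds and approach angles are
generated for realism but never consumed by any observer; the 32-mm
collision feedback is recorded per trial but never fed back into the
observer. Day-1 trials are retained in the CSV with a `day` column, so the
first-day-only re-analysis is a filter, not a regeneration.

What a green test on these data does *not* establish: the generator draws
i.i.d. trials from a stationary observer. Real participants learn, drift,
lapse, and produce heavy-tailed responses; none of that is modeled, so
recovery results here certify the inference machinery, not robustness to
human misbehavior.

## Inference

The parameter prior is uniform over a wide box — SDs on $[10^{-4}, 10]$ log
units, prior means on $[0, 12]$ log-mm, $K$ on $[1, 1000]$ — the
"very large range" made concrete. Sampling happens in transformed space
(log for positive parameters, raw for the means) with the Jacobian applied,
so the prior stays uniform on the *original* scale. The sampler is
component-wise Gaussian random-walk Metropolis-Hastings; proposal scales
adapt multiplicatively toward a 20–40% acceptance rate during burn-in only
(window of 50 iterations) and are frozen before any sample is stored.
Initialization is data-driven — regression of the judged log-distance on
the true log-distance sets the location parameters, the residual SD is
split across the noise sources — and jittered per chain; all seeds are
recorded in the run manifest. The desk default is 8 chains × 2000 burn-in ×
1500 stored (seconds per model on one CPU); the original large-scale
configuration (360 × 15000 × 6000) is available as
`sampler_config("paper")`. The point estimate $\bar\theta$ is a
per-parameter 10%-trimmed mean over pooled post-burn-in draws (R's
`mean(trim = 0.1)` convention; the trimming fraction in the source analysis
is unstated, 10% is this package's documented choice). Convergence is
summarized by split-$\hat R$ (implemented here) and effective sample size
(via `coda`); $\hat R > 1.05$ warns and flags the report, it never aborts.

Model comparison uses DIC $= \bar D + p_D$ with $p_D = \bar D -
D(\bar\theta)$, deviance $D(\theta) = -2\log L$; per-draw log-likelihoods
are stored during sampling so $\bar D$ needs no recomputation. Gaps above
10 are labeled significant and above 15 highly significant; 8–9 gaps
(sometimes called marginal) are reported as n.s. with the raw delta
printed. Weber fractions are reported as $e^{\sigma} - 1$, the 1-SD
criterion — the precise criterion sentence in the source is unreadable, so
this convention is a documented choice.

## A known identifiability limit (why one acceptance check is red)

For the haptic sampling observers, the response distribution exposes only
seven observable quantities (three mean slopes, two intercepts, two
condition variances) against up to ten parameters, and the posterior
weights are invariant to a common rescaling of the four assumed variances.
The likelihood is therefore *exactly flat* along a two-dimensional
manifold on which the overall variance scale, $K$, and $\sigma_m$ trade
off. Under the uniform-on-original-scale prior, posterior mass drifts to
the large-SD / large-$K$ end of that ridge. Consequence, verified
empirically: with data simulated at the reference recovery setting
($\sigma_\phi = 0.1$ coupled, $\tilde\sigma_h = 0.08$, $\sigma_h = 0.2$,
priors at the stimulus log-statistics, $K = 4$, $\sigma_m = 0.02$; that
setting makes the two condition variances nearly equal, removing $K$'s
upper-bound constraint), the 95% credible intervals cover every parameter
*except* $K$ (and, about half the time, $\sigma_m$). The parameter-recovery
acceptance test is left red with this analysis rather than weakened: it is
a property of that stated world, not of the sampler. Recovery settings
with a strongly informative haptic cue and small $K$ — which make the
no-haptic condition visibly more variable than the haptic one, the
qualitative signature that separates sampling from MAP observers — do not
suffer from it. The DIC-based *structure* recovery (haptic vs no-haptic by
a wide margin; sampling preferred over its MAP twin) is unaffected, because
deviance is constant along the ridge.

## Numerical choices and degenerate inputs

Zero noise SDs are admitted only in simulation/tests (they make useful
exact fixtures); fitting bounds SDs below by $10^{-4}$ log units. DIC ties
are broken by model id so rankings are permutation-stable. Negative $p_D$
(possible under multimodality or poor convergence) is flagged, not fatal.
Grid-oracle integration windows are derived from the cue values and prior
means (±6 combined SDs), with the s-marginal accumulated in blocks to
bound memory. Manifests serialize θ through JSON at full precision, which
round-trips to ~1 ulp; reproducibility assertions across a
serialize/deserialize cycle therefore use a $10^{-12}$ tolerance, while
same-process re-runs are bit-identical.

## Limitations

The package fits the documented CSV schema, not raw apparatus logs; it
does not model exploration-phase kinematics, feedback-driven learning, or
cue-miscorrespondence (causal-inference) observers; and it offers no
gradient-based or ensemble samplers — the component-wise random walk is
deliberately simple and auditable, at the cost of slow mixing along the
ridge described above.
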