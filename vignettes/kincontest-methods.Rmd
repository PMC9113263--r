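---
title: "Methods: contest games and synthetic dyadic trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contest games and synthetic dyadic trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kincontest)
```

kincontest has two halves that mirror the two ways one can study aggression
between potentially cannibalistic larvae that may be each other's kin: an
inclusive-fitness contest game that predicts how aggressive each member of a
dyad should be given their relative sizes and relatedness, and a simulation +
refitting pipeline that asks whether the statistical models used on real
dyadic trials can recover known effects from data with the same design and
covariance structure.

## The contest game

Two tadpoles, labelled 1 and 2, share a pool; only one survives the contest.
Each contestant has a relative size $s_i > 0$ and chooses an aggressiveness
$a_i \ge 0$. Competitive strength is multiplicative,

$$\theta_i = s_i \, a_i,$$

so one unit of aggressiveness buys a large tadpole more strength than a small
one. Contestant 1 wins with probability equal to its relative strength,

$$\omega_1 = \frac{\theta_1}{\theta_1 + \theta_2}, \qquad
  \omega_1 + \omega_2 = 1.$$

The winner's direct fitness $\upsilon_i$ pays an accelerating cost of
aggression, under three alternative assumptions about how size enters:

| formulation | $\upsilon_i$ | admissible $a$ |
|---|---|---|
| `size_independent` | $1 - a_i^2$ | $[0, 1]$ |
| `size_proportional` | $s_i - a_i^2$ | $[0, \sqrt{s_i}]$ |
| `size_scaled_cost` | $1 - (a_i/s_i)^2$ | $[0, s_i]$ |

Because the winner kills a relative that would otherwise have had fitness
$\upsilon_2$, the surviving contestant's inclusive payoff is
$\upsilon_1 - r\,\upsilon_2$ with relatedness $r$ (0.5 full siblings, 0.25
paternal half siblings, 0 unrelated), and the expected inclusive fitness of
contestant 1 is

$$F_1 = \omega_1\,(\upsilon_1 - r\,\upsilon_2).$$

The loser's payoff is zero — it neither reproduces nor affects the winner's
reproduction.

### Domain choices

Aggressiveness is restricted to the interval on which the winner's direct
fitness is non-negative (`max_aggressiveness()`): a winner with negative
reproductive success is meaningless, and allowing it would reward the
optimiser for pathological strategies. Values beyond the bound are rejected,
never clamped. Sizes are dimensionless relative quantities and are not
required to be below 1.

When both contestants are fully passive ($a_1 = a_2 = 0$) the win
probability $0/0$ is undefined; the package uses the continuity convention
$\omega_1 = s_1/(s_1+s_2)$, the limit along any path $a_1 = a_2 \to 0^+$.
The alternative convention $\tfrac12$ would introduce a size-independent
discontinuity into an otherwise size-driven model.

## Best responses and equilibria

`best_response()` maximises $F$ over the admissible interval by a coarse
grid (default 1001 points) followed by bounded derivative-free refinement
(`optimize()`) in the bracket around the best grid point. Both boundaries
are always evaluated, because corner maxima are real phenomena in this game
(see below). Ties are resolved toward the smallest aggressiveness —
deterministic and biologically conservative.

One discontinuity needs honest handling: when the opponent plays exactly 0,
any $a > 0$ wins outright and $F$ then decreases in $a$, so the optimum is a
supremum at $a \to 0^+$ that is never attained. The solver returns the
smallest positive grid value flagged `supremum_not_attained` rather than
pretending a maximiser exists.

`nash_equilibrium()` runs undamped iterated best response (optionally damped
if oscillation is flagged) from 8 quasi-random starting pairs (a golden-ratio
low-discrepancy sequence) plus the two corner pairs, stopping when the
largest coordinate update falls below $10^{-8}$. Distinct fixed points found
across restarts are recorded in `multiplicity` rather than silently merged;
the paper's single equilibrium curves do not prove uniqueness, so the solver
should not assume it. Symmetric games are symmetrised (the two coordinates
averaged) since the symmetric solution is the meaningful one there.

For equal sizes the stationarity condition $\partial F_1/\partial a_1 = 0$
at $a_1 = a_2$ has closed-form solutions used as oracles,

$$a^*_{\text{ind}} = \sqrt{\tfrac{1-r}{5-r}}, \qquad
  a^*_{\text{prop}} = \sqrt{\tfrac{s(1-r)}{5-r}}, \qquad
  a^*_{\text{scaled}} = s\sqrt{\tfrac{1-r}{5-r}},$$

re-derived here from $(1-r)\,\upsilon = 4a^2 \cdot (\text{scale})$ and
confirmed in the test suite against brute-force grid search on $10^6$
points. `verify_mutual_best_response()` is the run-time oracle: it recomputes
both best responses on an independent $10^5$-point grid and accepts a pair
only if each coordinate is within tolerance. A side facing a passive
opponent has no attained best response, so that side passes only if its own
value is effectively zero-plus (at most $100\times$ the tolerance).

`equilibrium_sweep()` maps the equilibrium surface with the smaller
contestant fixed at $s = 0.1$ and the larger swept from 0.1 to 1.0 in steps
of 0.01, for $r \in \{0, 0.25, 0.5\}$ and all three formulations (819
rows). Three qualitative patterns are asserted in the tests:
size-independent fitness makes the *smaller* contestant at least as
aggressive (compensation); size-proportional fitness produces a corner
($a_{\text{small}} = 0$: letting the larger relative win) beyond a size
threshold when $r > 0$; size-scaled costs make the *larger* contestant
consistently at least as aggressive, with its aggressiveness non-increasing
in relatedness.

```{r sweep, eval = FALSE}
sw <- equilibrium_sweep()
write_sweep(sw, "sweep.csv", seed = 1)
```

## The synthetic trial generator

The generator emulates the design of the behavioral experiment the
statistical models were built for: 15 dyads per relatedness level (45
trials, 90 tadpoles), masses 0.04–0.38 g with within-dyad differences
0.03–0.30 g (rejection sampling, heavier tadpole labelled "large"), scan
sampling every 15 s through a 10-min separated post-acclimation phase (40
scans) and a 60-min experimental phase (240 scans). Families are drawn from
a finite breeding pool (default 8 sires × 12 dams) so that the family
random effect has replication: full siblings share the breeding pair,
paternal half siblings share only the sire, non-siblings share neither.

Three outcome models generate the data, mirroring the analyses they are
meant to feed:

* **Aggression** (bites + chases per tadpole): Poisson, log link, linear
  predictor relatedness × relative size plus pair and family random
  intercepts, offset $\log(\text{duration in seconds})$.
* **Activity** (swimming scans per tadpole): negative binomial (quadratic
  mean–variance), same predictor structure; the acclimation phase's default
  coefficient set has no size or relatedness effects, matching that phase's
  null results.
* **Latency to first bite** (dyad level): exponential event times with
  proportional hazard
  $\lambda = \lambda_0 \exp(\text{relatedness} + \text{mass difference} +
  \text{interactions} + \text{family effect})$, censored at the trial end;
  given an event, the large tadpole is the first biter with probability
  29/38 (the pooled observed fraction; per-level values configurable).

Default coefficients are the published fitted sets of the corresponding
models. Three reporting conventions had to be decided:

* **Offset units.** The aggression table's intercept ($-8.03$) implies
  $3600\,e^{-8.03} \approx 1.2$ baseline events per hour-long trial with a
  seconds offset — a plausible magnitude — so seconds are used for the
  experimental phase. The acclimation activity intercept (0.72) is only
  plausible with a minutes offset ($10\,e^{0.72} \approx 20$ of 40 scans
  active), so the acclimation phase offsets by minutes.
* **Scale of the experimental-activity table.** Its intercept
  "0.00 (CI 0.00–0.01)" is only coherent on the rate-ratio scale, so that
  coefficient set is read as rate ratios and converted to logs internally.
  The log intercept itself is unrecoverable from the rounded report; $-5.3$
  (about 18 active scans/h baseline) is consistent with the printed CI and
  $z$.
* **Negative-binomial dispersion.** The reports give latent residual
  variances $\sigma^2$; the generator maps them to NB size parameters via
  $k = 1/(e^{\sigma^2}-1)$, which matches a lognormal mixture's
  mean–variance inflation. This is an approximation, documented as such:
  $k \approx 1.86$ (experimental, $\sigma^2 = 0.43$) and $k \approx 0.23$
  (acclimation, $\sigma^2 = 1.68$).

Random-effect variances are taken from the matching table panels
(aggression: pair 1.04, family 0.13; activity: phase-specific, near zero in
the experimental phase). One standard-normal draw per pair and per family
per model family is shared across phases and tadpoles, since the fitted
models assume exactly that covariance. The latency frailty variance is
unreported; 0.25 (moderate clustering) is the default. The baseline hazard
default ($5.31 \times 10^{-4}\,\mathrm{s}^{-1}$) is calibrated by
`calibrate_baseline_hazard()` so that about 38/45 of default-design dyads
have an uncensored first bite, the observed event fraction.

Scan sampling cannot record more events than scans, so generated counts are
capped at the phase's scan budget and a cap-hit counter kept — the
generative GLMM is unbounded, and hiding the truncation would silently bias
recovery checks. Early termination of trials (observed in 3/45 real trials)
is off by default; when enabled it truncates the trial duration uniformly
and shortens all exposures.

What the generator does *not* emulate — and what passing recovery tests
therefore cannot show — includes scan-by-scan behavioral sequences (only
phase totals are generated, which is all the models consume), behavioral
feedback between outcomes (aggression counts, activity and latency are
conditionally independent given the dyad and its random effects, whereas
real attacking and swimming are causally entangled), any dependence of the
first-biter identity on the latency time, and kin-recognition mechanisms.
Recovery results validate the *statistical pipeline*, not the biology.

## The recovery pipeline

`fit_aggression_model()`, `fit_activity_model()` and `fit_latency_model()`
refit the three model structures with glmmTMB (Poisson and NB2 GLMMs) and
survival::coxph (with a Gaussian frailty standing in for the family random
effect). Coefficients are renamed to the canonical table rows
(`size_large`, `siblings:size_large`, `siblings:mass_diff`, …) with the
non-sibling / small-tadpole reference. At the experiment's own size (15
dyads per level) random-intercept variance estimates frequently hit the
boundary at zero — consistent with the near-zero variances the original
models themselves report — so boundary fits are recorded in `notes`, never
treated as failures.

`recovery_experiment()` generates replicate datasets from seeds split
deterministically off one master seed, refits, and summarises
per-coefficient bias, spread and 95%-interval coverage. Two design choices
matter when reading its output:

* Recovery checks of the generating coefficients are run at enlarged
  designs (100 dyads per level for the count models, 150 for the latency
  model, 200 replicates) so that estimator small-sample bias does not
  masquerade as implementation error; paper-scale runs are available by
  leaving the design at its default.
* The null-calibration check (all non-intercept effects zero) uses 500
  replicates of 30 dyads per level — large enough for Wald intervals to be
  in their asymptotic regime while keeping the full calibration affordable.
  Wald intervals from mixed models are known to undercover slightly for
  interaction terms at small samples; the calibration criterion of 0.90–0.99
  coverage reflects that.

```{r recovery, eval = FALSE}
rs <- recovery_experiment(generating_params(),
                          trial_design(n_per_level = 100),
                          n_replicates = 200, seed = 1,
                          models = c("aggression", "activity"))
rs[rs$term == "size_large", ]
```

## Configuration and reproducibility

All randomness descends from one integer seed via `split_seed()`
(per-stage deterministic sub-seeds), so any dataset, sweep or recovery run
is reproducible from one number. `parse_config()` reads a YAML file merged
over the full documented defaults, rejecting unknown keys by name;
`config_hash()` stamps outputs so they can be matched to their
configuration. All CSV outputs carry `#`-prefixed provenance headers and
round-trip through `read_commented_csv()`.

## Known limitations

* The game is strictly two-player; pools with more than two tadpoles, and
  dynamic (repeated-contest) formulations, are out of scope.
* Equilibrium multiplicity is recorded, not resolved: no stability
  classification beyond mutual best response is attempted.
* The `size_proportional` corner equilibria involve a best response to a
  passive opponent, which is a supremum rather than a maximum; the reported
  positive value for the larger contestant is the smallest grid value and
  is flagged, not exact.
* The dispersion mapping from reported residual variances is approximate,
  and the experimental-activity log intercept is a reconstruction
  consistent with, but not determined by, the published report.
* Cox refits use a Gaussian frailty via penalised partial likelihood, a
  different random-effect computation than the mixed-effects Cox
  implementation used on the real data; at the sizes used here the fixed
  effects agree, but frailty-variance estimates are not comparable.
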