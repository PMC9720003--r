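---
title: "Modelling segregational stability of multicopy plasmids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling segregational stability of multicopy plasmids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(plasmidstab)
library(dplyr)
```

## The model

`plasmidstab` models a serial-dilution experiment with two bacterial
subpopulations: plasmid-bearing (PB) cells carrying $n$ copies of a
nontransmissible plasmid, and plasmid-free (PF) cells. Each day the culture
grows from a bottleneck of $N$ cells to saturation at $\gamma N$ cells and is
then diluted $1/\gamma$ into fresh medium. Because the plasmid lacks active
partitioning, each division sends every copy independently to one of the two
daughters; a PB division therefore produces a PF daughter with probability
$2^{-n}$. Carrying plasmids costs: in drug-free medium PF cells outgrow PB
cells.

Two descriptions of this system are linked by the package.

**The interday map.** On the day scale, the PB fraction $X_i$ at the start of
day $i$ evolves as

$$X_{i+1} = f(X_i) = \frac{(1-\kappa_n)\,X_i\,(1-\mu_n)}
{(1-\kappa_n)\,X_i + (1-X_i)},$$

where $\kappa_n$ is the total per-day fitness cost of carriage and $\mu_n$
the per-day probability that a PB lineage yields plasmid-free descendants at
transfer. An antibiotic pulse at the start of a day kills each PF cell with
probability $\alpha$, moving the fraction to
$g(X) = X/(X + (1-\alpha)(1-X))$ before growth, so a drug day applies
$f(g(X))$, with closed form
$(1-\kappa_n)X(1-\mu_n)/\big((1-\alpha) + (\alpha-\kappa_n)X\big)$
(`pulsed_day_map()` evaluates both routes; they are algebraically identical).
The bottleneck is treated deterministically: at $N \sim 10^5$ cells,
binomial sampling noise in the transferred fraction is negligible relative to
the selection and loss terms, so the map is iterated exactly
(finite-$N$ multinomial transfer is out of scope).

**The within-day branching process.** On the hour scale, growth is a
continuous-time two-type branching process: PF cells divide at Malthusian
rate $r + \rho_n$ and PB cells at $r$, each PB division producing a PF
daughter with probability $2^{-n}$. Its mean matrix is $M(t) = e^{tA}$ with

$$A = \begin{pmatrix} r+\rho_n & 0 \\ r2^{-n} & r(1-2^{-n}) \end{pmatrix},$$

indices ordered PF then PB (`rate_matrix()`, `mean_matrix()`; the index
convention is pinned by tests because a silent transposition would be
invisible in symmetric cases). Growth lasts $\sigma$ hours — approximately
$\log(\gamma)/r$, or the exact saturation time solved by
`growth_duration(mode = "exact")` from the expectation reaching $\gamma$ per
founder; the exact-mode saturation equation is our reconstruction of that
stopping rule, not a quoted formula. Writing $s = r2^{-n} + \rho_n$, the
expected end-of-day PB fraction equals the interday map with

$$\mu_n = \frac{r2^{-n}\left(e^{s\sigma}-1\right)}{r2^{-n}e^{s\sigma} + \rho_n},
\qquad
\kappa_n = \frac{\rho_n\left(1 - e^{-s\sigma}\right)}{s}.$$

This bridge (`derive_interday_params()`) is the quantitative heart of the
package: it turns three measurable quantities — two maximal growth rates and
the exponential-phase duration — plus the copy number into the parameters of
the day-scale model. It holds to machine precision for every admissible
parameter set (a property the test suite checks against the independently
coded end-of-day expectation and against a numerical matrix exponential).

With the measured reference values ($r = 0.435435$/h, $\rho = 0.052334$/h,
$\sigma = 6.074089$ h, $n = 19$):

```{r bridge}
derive_interday_params(pbgt_growth_params())
```

**Numerical note.** $\mu_n$ is evaluated as
$r2^{-n}\,\mathrm{expm1}(s\sigma) / (r2^{-n}e^{s\sigma}+\rho_n)$ rather than
$1 - s/(\dots)$: the two are algebraically identical, but the subtraction
underflows to zero around $n \gtrsim 55$, where $\mu_n \sim 10^{-18}$ is
still meaningful for ordering copy numbers. Similarly the off-diagonal
mean-matrix entry uses `expm1` so that the degenerate direction
$s \to 0$ reduces smoothly to its analytic limit $r2^{-n}\,t\,e^{rt}$ without
an epsilon guard.

## Selection thresholds and equilibria

Under daily pulses, an interior equilibrium
$x^* = 1 - \mu_n(1-\kappa_n)/(\alpha-\kappa_n)$ exists and attracts every
interior starting fraction exactly when $\alpha$ exceeds the minimum
selective pressure

$$MS\alpha = \kappa_n + \mu_n(1-\kappa_n),$$

the model analogue of a minimum selective concentration (the PF strain's MIC
corresponds to $\alpha = 1$, so $MS\alpha$ plays the role of an MSC/MIC
ratio). Below the threshold the plasmid is purged; at the threshold the
dynamics are neutral to first order, with a residual second-order drift
$x_{i+1}-x_i \approx -\mu_n x^2$ per day — about $1.5\times10^{-6}$/day at
the reference parameters from $x = 0.5$, orders of magnitude slower than the
off-threshold dynamics but not zero. $\alpha$ is allowed to be negative:
competition data at sub-inhibitory doses genuinely fit small PF advantages,
and rejecting them would silently bias dose-response panels.

```{r msalpha}
p <- pbgt_params(alpha = 0.6)
c(ms_alpha = min_selective_alpha(p), x_star = steady_state(p))
```

## Copy-number sweeps

Sweeps over copy number hold the host physiology ($r$, $\sigma$) fixed and
drive everything from a single per-copy daily cost $\kappa$: the total cost
is $\kappa_n = \kappa n$ (cost proportional to copy number), the implied PF
growth advantage is $\rho_n = -\log(1-\kappa n)/\sigma$ (the inverse of the
cost bridge when segregational loss is negligible), and $\mu_n$ follows from
the forward bridge. One knob thus moves both opposing forces consistently:
$\mu_n$ falls exponentially in $n$ while $\kappa_n$ rises linearly, which is
exactly the trade-off that makes intermediate copy numbers optimal.

```{r sweep, fig.alt = "Minimum selective pressure versus copy number"}
msalpha_curve(1:60, per_copy_cost = 0.0143) |> plot_msalpha_curve()
```

Stability metrics (`stability_sweep()`, `time_to_extinction()`,
`auc_stability()`, `classify_outcome()`):

* **Extinction threshold** $10^{-5}$: with $N \sim 10^5$ cells at the
  bottleneck, a fraction below $1/N$ means fewer than one PB cell. The
  threshold is a config argument everywhere it is used.
* **Time to extinction** is the first day the fraction crosses the
  threshold; it is reported in whole days, so rankings finer than one day
  are below its resolution.
* **AUC** (trapezoidal area under the fraction-versus-day curve, in
  day-units) is the persistence score used for optimisation, because it
  remains informative when trajectories equilibrate or oscillate; any log10
  scaling is cosmetic and left to plotting.
* **Stabilisation** is detected on stride-compared values with tolerance
  $10^{-6}$ (stride = the period in periodic environments); trajectories
  that have not settled at the horizon are reported `undetermined` rather
  than forced into a class.
* **Absorption**: in environment studies (`pcn_auc_sweep()`,
  `random_environment_study()`) a variant whose fraction crosses the
  extinction threshold is held at zero (`absorb = TRUE`), since fewer than
  one cell cannot be rescued by a later pulse; `simulate_trajectory()`
  itself iterates the pure map, which cannot reach zero from the interior,
  so the two behaviours are kept explicitly distinct.
* **Ties** in the optimal copy number go to the smallest $n$ — conservative
  and reproducible.

In periodic environments, `max_rescue_time()` reports the longest drug-free
run a population survives while remaining rescuable (a near-certain kill
pulse rescues any population still above the extinction threshold, so the
binding constraint is the threshold crossing), and `min_period()` reports
the *critical period*: persistence holds for all pulsing periods up to its
value and fails beyond. We read the "minimal period required to avoid
extinction" as this minimal pulsing *frequency* — the alternative reading
(smallest feasible period) is trivially 1 whenever daily pulses work and
contradicts the observation that stronger selection permits longer periods.

Random environments are i.i.d. Bernoulli day sequences at a given antibiotic
rate (AR). "Randomly switching" environments could also be modelled with
two-state persistence; a Markov generator (`markov_schedule()`) is provided
for sensitivity analysis but is not the default, because the day-scale model
carries no memory that would privilege one switching structure. Environments
are summarised by AR and by the binary Shannon entropy of AR (per-day
entropy, not block entropy — the two-to-one correspondence
$H(AR) = H(1-AR)$ only holds for the binary form), and classed High/Low by
AR strictly greater than 0.5 (exactly 0.5 is Low).

## Estimation from experimental-format data

`estimate_growth_params()` recovers $r$ (PB maximal growth rate), $\rho$
(PF excess) and $\sigma$ from plate-reader curves:

* **Maximal growth rate** is the steepest ordinary-least-squares slope of a
  sliding window over log OD, the standard "maximum of local slopes"
  readout. The window default is 15 points (2.3 h at 10-minute sampling).
  Short windows (e.g. 5 points) track the instantaneous slope more closely
  but their slope standard error at realistic noise (log-sd 0.02, three
  replicates) is ~0.02/h, which swamps a PF–PB difference of 0.05/h; 15
  points bring the standard error to ~0.004/h while the curvature bias from
  averaging a logistic's slope across the window stays below 2% at the
  default generator geometry. Replicates are averaged on the log scale
  before fitting.
* **Blank handling** defaults to none, with readings floored at $10^{-4}$
  before logging. Subtracting the per-curve minimum (a common habit)
  destroys log-linearity whenever the minimum is a genuine datum rather
  than background — on an exact exponential it corrupts the early slope
  entirely — so background subtraction is opt-in via `blank`.
* **Exponential-phase duration** is the span between the first and last
  window whose slope reaches `slope_fraction` (default 0.5) of the maximum.
  The criterion in words — "start of exponential phase to reaching carrying
  capacity" — needs an operational form; half-maximal local slope marks
  both ends symmetrically and, for a logistic curve, lands the upper end at
  half carrying capacity. A candidate phase must contain at least one
  e-fold of growth, which is what rejects linear or flat series.
* **Competition fits** (`fit_kappa()`, `fit_alpha()`) are ordinary least
  squares on endpoint fractions, one parameter at a time with the others
  held fixed ($\mu_n$ is orders below endpoint noise and is never
  identifiable from one day of competition; it comes from the bridge).
  OLS on the fraction scale is the simplest defensible objective; a logit
  loss would up-weight the extreme fractions where fluorescence conversion
  is least reliable. Fits at a single dose are joint across starting
  fractions. Standard errors come from the curvature of the least-squares
  objective at the optimum.

## The synthetic-data generator

`gen_growth_curves()` emulates a 96-well growth experiment: lagged-logistic
OD trajectories with multiplicative log-normal noise. Defaults — chosen once
as a realistic protocol — are a 1:100 LB inoculum (OD 0.01 into carrying
capacity 1.0), 2 h lag, 10-minute sampling for 24 h, three replicates,
noise log-sd 0.02, and the measured reference rates for the two strains.
The recorded truth includes the implied exponential-phase duration
$\log(K/\mathrm{od}_0)/r$. A configuration calibrated to the reference
experiment's fold-growth ($e^{r\sigma} \approx 14$, e.g. OD 0.05 into 0.70)
reproduces its $\sigma \approx 6.07$ h.

`gen_competition_table()` produces one-day competition endpoints from the
interday model plus truncated Gaussian noise on the fraction scale (sd 0.02,
consistent with the tight fluorescence calibration such experiments achieve),
with the dose-to-$\alpha$ profile of the reference ampicillin panel as the
default. The generator's noise is deliberately *not* the estimator's loss
model (log-normal on OD versus OLS on log OD; truncated Gaussian on fractions
versus plain OLS), so parameter-recovery tests are not an inverse crime.

What the generator does **not** emulate: instrument drift and edge effects
across a plate, non-logistic growth shapes (diauxie, death phase),
density-dependent drug action, cross-well contamination, and cytometry-level
observation models. Passing recovery tests therefore demonstrates estimator
correctness under a realistic noise magnitude, not robustness to every
failure mode of real plates.

## Problem sizes and reproducibility

The shipped analyses use drug-free horizons of 500 days, random-environment
horizons of 1000 days with 50-environment batteries, copy-number grids of
1–100 (truncated where $\kappa n \ge 1$), and 100-seed recovery studies —
sizes at which every qualitative structure of interest (interior optima,
threshold splits, rank orderings) is already stable. All randomness flows
through explicit seeds (`withr::with_seed`), so schedules, batteries and
synthetic bundles are bit-reproducible and never disturb the caller's RNG
stream; the pipeline runners echo the full configuration, its hash and the
seed into every output.

## Known limitations

* The model is deterministic at the bottleneck; finite-$N$ fluctuation
  effects near the extinction threshold (where a fraction of $10^{-5}$ *is*
  one cell) are represented only by the absorption rule.
* Copy number is a fixed parameter per run: the package finds the copy
  number that maximises persistence, it does not evolve copy number.
* No horizontal transfer, no compensatory adaptation (costs constant in
  time), no sub-day pharmacokinetics: pulses are instantaneous kills at the
  start of a day.
* Fitted $\alpha$ values map doses to kill probabilities through the model;
  they are not independent pharmacodynamic measurements.
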