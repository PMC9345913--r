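---
title: "Drying kinetics and neuro-fuzzy modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drying kinetics and neuro-fuzzy modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anfisdry)
```

This vignette documents the models implemented in `anfisdry`, the
assumptions behind them, the tunable parameters and their defaults, and the
design choices made where the methodology left room for judgement.

## The drying-kinetics model

Thin-layer convective drying of a roughly spherical fruit is treated as
diffusion-limited moisture transport. The moisture ratio
$MR = (M_t - M_e)/(M_o - M_e)$ normalizes the dry-basis moisture content to
1 at the start of drying and 0 at equilibrium. Fick's second law for a
sphere with uniform initial moisture and a constant surface condition has
the series solution

$$MR(t) = \frac{6}{\pi^2} \sum_{n \ge 1} \frac{1}{n^2}
  \exp\!\left(-\frac{n^2 \pi^2 D_{eff}\, t}{r^2}\right),$$

which `mr_series()` evaluates by direct truncated summation. At long times
only the $n = 1$ term survives, so $\ln MR$ is linear in $t$ with slope
$K_L = -\pi^2 D_{eff}/r^2$; `fit_ln_mr()` performs the ordinary
least-squares fit and `deff_from_slope()` inverts the slope to the
effective moisture diffusivity. Across drying temperatures the diffusivity
follows the Arrhenius law $D_{eff} = D_0 \exp(-E_a/RT)$; `arrhenius_fit()`
regresses $\ln D_{eff}$ on $1/(T + 273.15)$ and reports
$E_a = -\mathrm{slope} \times R$ in kJ/mol with $R = 8.314$ J/(mol K).
The activation energy is invariant to any constant rescaling of the
diffusivities, so it is insensitive to the unit convention chosen below.

Key parameter choices:

* **Characteristic radius** `radius_m = 0.02` m. This is the only radius
  under which the published per-sample diffusivity table is consistent with
  its own printed regression slopes (the ratio $D_{eff}/|K_L|$ is constant
  at $r^2/\pi^2$ with $r = 0.02$ across all rows), and it matches the
  reported fruit length of 0.0200–0.0205 m. It is configurable everywhere.
* **Slope unit modes.** `mode = "table"` converts a slope to
  $D_{eff} = |K_L| r^2/\pi^2$ with no time-unit conversion; this reproduces
  the published table, whose slopes are consistent with regressions against
  time in seconds. `mode = "si"` additionally divides by 60, which is the
  correct conversion when the slope was fitted against time in minutes (as
  this package's own pipeline does on minute-based records). The two modes
  differ by exactly the factor 60.
* **Equilibrium moisture content** defaults to $M_e = 0$, the standard
  thin-layer simplification when the equilibrium value is unmeasured; it is
  an argument of `moisture_ratio()`.
* **Regression window.** By default every point with $MR > 0.01$ enters the
  ln-MR fit (`min_mr = 0.01`; non-positive values are excluded with a
  message since their logarithm is undefined). When the goal is to recover
  a diffusivity from a full multi-term curve, the early-time points bias
  the slope because the higher series terms have not yet decayed; the
  optional `max_mr` bound restricts the fit to the one-term regime. At
  $MR \le 0.2$ the $n = 2$ term contributes under about 3% locally and its
  effect on the fitted slope is well below 1%, so recovery checks in this
  package use `max_mr = 0.2`. Because the window is defined in MR space,
  any residual multi-term bias is common to all temperatures and cancels
  almost exactly in the activation energy.
* **Energy accounting.** $E_t = A v \rho_a c_a \Delta T D_t$: the factor
  $A v \rho_a c_a \Delta T$ is the heater power in kW (air mass flow times
  sensible heat, with $c_a$ in kJ/kg°C), so multiplying by the drying time
  in hours gives kWh directly, with no further conversion factor.
  $E_s = E_t / W_0$.

## The ANFIS model

`anfis()` implements a first-order Takagi–Sugeno fuzzy inference system.
Each crisp input $x_j$ carries $m$ membership functions; the rule base is
the full Cartesian product, $m^k$ rules for $k$ inputs (8, 27 and 125 rules
for the 3-factor drying problem at $m = 2, 3, 5$). For rule $i$ with
membership degrees $\mu_{ij}(x_j)$:

* firing strength $w_i = \prod_j \mu_{ij}(x_j)$ (product t-norm),
* normalized strength $\bar w_i = w_i / \sum_l w_l$,
* consequent $f_i = p_{i1} x_1 + \dots + p_{ik} x_k + r_i$,
* output $\hat y = \sum_i \bar w_i f_i$.

The four membership families use their standard definitions —
$\mathrm{gbell}(x; a,b,c) = 1/(1 + |(x-c)/a|^{2b})$,
$\mathrm{gauss}(x; \sigma, c) = \exp(-(x-c)^2/2\sigma^2)$, the
piecewise-linear triangle, and the spline-based Π curve (product of S- and
Z-splines). Initialization is a deterministic uniform grid partition:
centers equally spaced over the observed input range, widths set so
adjacent curves cross at degree 0.5.

### Hybrid training

Each epoch performs (1) an exact least-squares solve for all consequents
with the premise frozen, then (2) one full-batch gradient step on the
membership parameters with the consequents frozen. Training and checking
RMSE are recorded after the least-squares pass; the returned model is the
snapshot at the epoch with the lowest checking RMSE (first epoch on ties),
the usual guard against over-fitting, and test metrics are computed only on
the held-out test partition with that snapshot. The split is a uniform
random shuffle under the configuration seed followed by contiguous
60/15/25 slices; it is not stratified. Everything downstream of the seed is
deterministic, so a rerun reproduces the trajectories bit for bit.

Numerical design choices that matter:

* **Consequent solve.** The design matrix (normalized strengths times
  augmented inputs) is assembled in *rule-centered, domain-scaled*
  coordinates: each rule's linear term is measured from its own membership
  centers and scaled by the input's domain width. This is an exact
  reparameterization of the same model class, chosen for conditioning. The
  solve uses the singular value decomposition; with no penalty it returns
  the minimum-norm least-squares solution (with a warning under rank
  deficiency). Training uses small Tikhonov penalties by default
  (`ridge_slope = ridge_intercept = 1e-3`): slopes shrink toward zero and
  each rule's intercept toward its exposure-weighted local mean of the
  response. The motivation is concrete: the three drying factors take few
  distinct values (12 temperature × pretreatment cells), so many rules have
  nearly collinear firing patterns and some have almost no training
  exposure. Unpenalized, those coefficients are free along near-null
  directions of the design — the training fit is unaffected, but
  predictions between training points can be off by orders of magnitude.
  The local-mean shrinkage target keeps barely-fired rules pinned to a
  sensible local level rather than dragged toward the global mean, which
  would bias the decayed tail of the drying curves upward.
* **Premise gradient.** Fully analytic for all four families, with the zero
  one-sided subgradient at the kinks of the triangular and Π families and
  non-finite elements zeroed. The step is taken along the negative
  gradient, normalized, in *domain-scaled* parameter coordinates, so the
  step length (`initial_step = 0.02`) means "2% of the input domain per
  epoch" for every input regardless of units — drying time spans hundreds
  of minutes while blanching spans ten, and an unscaled step would leave
  the time memberships effectively frozen. After each step, parameter
  validity ($\sigma > 0$, ordering constraints) is restored by projection.
* **Step schedule.** The step grows ×1.1 after four consecutive
  training-error decreases and shrinks ×0.9 after two error oscillations,
  the classic heuristic for this architecture.
* **Underflow.** Firing-strength sums are floored at
  `min_firing = 1e-12` before normalization inside training and
  prediction, avoiding 0/0 at extreme extrapolation; the standalone
  `normalize_firing()` raises a degenerate-input error instead, naming the
  offending rows.
* **R² convention.** Test R² is $1 - SSE/SST$; the squared-correlation
  variant is also reported (`test_r2_corr`) since conventions differ across
  the drying literature.

### Structure search and sensitivity

`run_grid()` trains all 12 family × count structures with an identical seed
(hence identical partitions), so performance differences reflect structure
only. The winner maximizes test R², with ties broken toward fewer rules and
then earlier best epochs. The epoch cap is configurable; the examples and
validation runs in this package use 100 epochs, which is past the
checking-error minimum for every structure on the bundled generator while
keeping a full grid run under two minutes on one core.

`run_sensitivity()` retrains the winning structure on each factor singleton
and pair (rule count shrinking to $m^{|S|}$), under the same seed and
configuration. A subset reaching a *lower* prediction RMSE is the one the
moisture ratio is more sensitive to. The headline RMSE is the full-dataset
prediction error of the best-epoch model — the per-partition RMSEs are also
reported, since conventions vary — and rankings are reported separately for
singletons and pairs. Constant factors are flagged and excluded.

## The synthetic generator

`generate_drying_data()` emulates the study design: 4 blanching
pretreatments (0/3/5/10 min at 60 °C) × 3 drying temperatures (50/60/70 °C),
weights every 10 min up to 120 min and every 30 min after, until
$MR < 0.01$ (`stop_mr`). Per cell, $D_{eff} = D_0 \exp(-E_a/RT)$ with
per-pretreatment $(E_a, D_0)$ defaulting to the Arrhenius regression of the
published diffusivity table, so the generated curves reproduce the study's
qualitative structure: hotter and shorter-blanched samples dry faster, the
slowest cell takes roughly 540 min (the study reports 530), and the default
dataset holds 222 records against the study's 255. Moisture ratios come
from the 50-term Fick series (truncation error below $10^{-12}$ for
$t \ge 10$ min; at $t = 0$ the truncated sum is 0.988 rather than 1);
optional multiplicative Gaussian noise ($\sigma = 0.01$ by default,
weighing error scaling with mass) is clipped to $[0, 1]$ with the $t = 0$
normalization point pinned at 1.

What the generator does *not* emulate: surface (skin) resistance, case
hardening, shrinkage, or a constant-rate period. Pure Fick curves have an
infinitely steep $\sqrt{t}$ onset, so the synthetic knee at early times is
sharper than real drying curves; passing tests on this generator
demonstrate that the pipeline recovers its own generating physics and that
the neuro-fuzzy machinery learns a hard, realistic-scale function — not
that any particular real fruit behaves identically.

## Validation strategy and known limitations

The kinetics side is validated two ways: desk recomputation of the
published tables (slope→diffusivity to 0.1%, Arrhenius energies to 0.3%,
specific energy to 0.05%) and closed-loop parameter recovery on noiseless
synthetic curves (diffusivities within 5%, activation energies within
0.5%). Two published table rows (the 50 °C rows of the unblanched and
10-min samples) are 5–6% inconsistent with their own printed slopes —
likely slope rounding — and are excluded from desk checks.

The neuro-fuzzy engine is validated by properties rather than by the
study's exact error figures, which depend on an unreleased experimental
dataset: forward-pass equivalence with a brute-force layer-by-layer oracle
to $10^{-12}$; normalized strengths summing to 1 over $10^4$ random cases;
finite-difference agreement of the analytic premise gradient to $10^{-5}$;
exact noiseless consequent recovery; and, end to end on the default
generator, a 12-row structure grid whose winner exceeds test R² 0.98 with
drying time ranked the most sensitive single factor — the same qualitative
finding as the study.

Limitations worth knowing: the Fick solution assumes an isotropic sphere
with constant diffusivity and no external resistance; the grid-partition
rule base grows exponentially in the number of inputs (5 membership
functions × 3 inputs is already 125 rules for ~130 training points, making
the ridge penalties essential); and with few distinct factor levels the
split seed noticeably affects which structure wins, although the winner's
test R² is stable (0.99 ± 0.005 across seeds on the bundled generator).
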