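---
title: "Methods: uniform-design optimization and structured growth kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uniform-design optimization and structured growth kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epferm)
```

This vignette is the package's account of the statistics and kinetics it
implements: the models and their assumptions, the tunable parameters with
their units and defaults, the numerical choices, and what the synthetic
generators do and do not emulate.

## The design stage

### U-type uniform designs

A U-design spreads `n` runs over `s` factors with `n` levels each so that
every factor column uses each level exactly once and the points fill the
factor space as uniformly as possible. `uniform_design()` builds candidate
columns by the good-lattice-point method: column `h` is
`u[i] = (i * h) mod m` with `h` coprime to the modulus `m`. When `n` has
too few coprime generators for the requested number of factors (for
`n = 10`, Euler's totient is 4 but six factors are needed) the leave-one-out
variant is used: the lattice is built mod `n + 1` and only rows `1..n`
kept, which yields `n` candidate columns whenever `n + 1` is prime.

Among admissible column subsets the one minimizing the centered
L2 discrepancy (Hickernell's CD2) of the induced point set
`x = (u - 0.5)/n` is selected. For small designs the subset search is
exhaustive (`C(10, 6) = 210` subsets at `n = 10`); above
`max_exhaustive` subsets a greedy forward selection is used instead.
Mirrored generator pairs `h` and `m - h` give reflected columns with
identical CD2, so ties are real; the first minimum in enumeration order is
kept, making construction deterministic.

The packaged ten-run design (`load_design_fixture()`) carries six medium
factors in their native g/100 mL units and the measured EP responses
(μg/L) at 28, 56, 84 and 112 h. The loader validates an MD5 checksum and
the balance invariant on every load. Conversion to g/L for reporting a
recipe is always the explicit `as_g_per_L()` step, never implicit.

### The response model

With sampling time `T` as the control variable, the yield is modelled as

$$Y = C + \alpha_1 T + \beta_1 T^2 + \alpha_2 F_2 + \beta_2 F_2^2 +
      \sum_{i=3}^{7}\alpha_i F_i$$

quadratic in time and glycerol and linear in the other five factors. The
model form is fixed — no stepwise selection — because the design's 40
observations (10 runs × 4 harvests) support exactly this term set with 30
residual degrees of freedom. The fit is ordinary least squares with the
classical variance estimate for per-term SE/t/p; the overall F is
regression MS over residual MS on (9, 30) degrees of freedom.

A quadratic factor with negative curvature has its maximum at the
stationary point $-\alpha/(2\beta)$; `recommend_optimum()` clamps it into
the tested range, sends each linear factor to the range end matching its
coefficient sign, and evaluates the fitted polynomial at the
recommendation. A positive-curvature quadratic factor is a boundary case:
both endpoints are evaluated and the better one kept, with a warning. The
practical medium recipe additionally snaps interior optima to the nearest
tested level — a recipe is only actionable on the grid that was actually
tested, and bounds are themselves levels — while the exact stationary
values stay available in the `settings` table. Predictions are not clipped
at zero; a negative prediction is reported with a warning, preserving
linear-model semantics.

### Mono-factor screening

Screening results are typically available only as group mean ± SE of
triplicates. `anova_dunnett()` reconstructs the one-way ANOVA from those
summaries (group variance `n * SE^2`, pooled mean square, the usual F) and
tests each treatment against the control. The Dunnett reference
distribution — the maximum absolute many-to-one t under the joint null,
with its control-shared correlation and common studentization — has no
closed form; it is sampled by Monte Carlo (default 100,000 draws) under an
explicit seed, so identical seeds give identical adjusted p values. The
Monte-Carlo estimate is floored at the unadjusted p, since a familywise
adjustment can never be anti-conservative. The ± values are treated as
standard errors with `n = 3`; if they were standard deviations instead,
every reconstructed variance would be 3× smaller, so this assumption is
conservative.

## The kinetic stage

### Models and couplings

The four specific growth rates are

| kind | $\mu(C_s, X, C_p)$ | extra parameter |
|---|---|---|
| monod | $\mu_m C_s/(k_s + C_s)$ | — |
| contois | $\mu_m C_s/(k_s X + C_s)$ | $k_s$ in g/g |
| andrews | $\mu_m C_s/(k_s + C_s + C_s^2/k_i)$ | $k_i$ (g/L) |
| aibe | $\mu_m \frac{C_s}{k_s+C_s}\cdot\frac{k_p}{k_p+C_p}$ | $k_p$ (product units) |

The Aibe model is implemented in multiplicative form: it is the only form
whose integral is linear in the $\{\ln C_s, \ln(C_0-C_s), C_s\}$ transforms
used by the fitting stage (an additive inhibition term admits no such
linearization), and the numerical oracle test confirms the consistency.

Biomass and product couple to substrate through constant yields:
$X = X_0 + Y_b (C_0 - C_s)$ and $C_p = Y_p (C_0 - C_s)$. With these
couplings the batch reduces to a single ODE,
$dC_s/dt = -\mu X / Y_b$, integrated by `deSolve::ode` (lsoda) at rtol
1e-8 / atol 1e-10 with the substrate floored at 1e-9 g/L. Product units
follow $Y_p$: when the product is EP, $Y_p$ is μg product per g substrate
and $C_p$ comes out in μg/L with no hidden conversion. Oxygen limitation,
death phase and temperature/pH dependence are out of scope.

A nonzero inoculum conflicts with the bare coupling $X = Y_b(C_0 - C_s)$,
which would force $X(0) = 0$ and hence no growth at all. The simulator
therefore carries an explicit $X_0$, and the integrated-form fits use an
*effective* initial substrate $C_{0,\mathrm{eff}} = C_0 + X_0/Y_b$, the
substrate level at which the biomass extrapolates to zero; with it the
closed forms remain exact.

### Integrated linearized forms and fitting

Separating variables and integrating gives, for each model, time as a
linear function of transformed substrate readings, e.g. for Monod

$$t = -\frac{k_s}{C_0\mu_m}\ln\frac{C_s}{C_0-C_s} +
      \frac{1}{\mu_m}\ln(C_0-C_s) + C.$$

`fit_integrated()` follows the linearization's own direction — *t* is the
response, the transforms are regressors, the integration constant is the
intercept — and recovers parameters from the coefficients:
$\mu_m = 1/b_{\ln(C_0-C_s)}$, $k_s = -b_{\mathrm{ratio}} C_0 \mu_m$
(Monod), $k_s = -b_{\ln C_s}\mu_m/Y_b$ (Contois), and for Andrews
$\mu_m = 1/(b_{\ln(C_0-C_s)} - C_0 b_{C_s})$, $k_i = 1/(b_{C_s}\mu_m)$.
Re-derivation of the Andrews integral gives the $C_s$ term with a
**positive** sign, $+C_s/(k_i\mu_m)$, and the ODE oracle confirms that
sign; the implementation uses the re-derived form.

Two numerical details matter:

* *The Aibe regressor set is rank-deficient by construction*: the log-ratio
  equals $\ln C_s - \ln(C_0-C_s)$, so the four transforms span a
  three-dimensional space. The identifiable basis
  $\{\ln C_s, \ln(C_0-C_s), C_s\}$ is fitted; the coefficient table still
  reports all four structural rows, with the log-ratio row aliased, and
  $(\mu_m, k_s, Y_p/k_p)$ are recovered exactly by solving the quadratic
  that the three estimable coefficients imply. Only the ratio $Y_p/k_p$ is
  identifiable from data; $k_p$ itself is reported when $Y_p$ is supplied.
  The internal consistency diagnostic `ks_consistency`
  ($b_{\ln C_s}/b_{C_s}$ of the structural split) is reported alongside.
* *Product and biomass reference different initial substrates in a seeded
  batch* ($C_p$ couples to $C_0$, biomass to $C_{0,\mathrm{eff}}$). The
  same three-regressor basis stays exact; passing the inoculum offset
  `X0_over_Yb` to `fit_integrated()` corrects the Aibe parameter mapping.
  Without it (offset 0) the mapping is the ideal-case formula.

Points at the log singularity $C_s = C_{0,\mathrm{eff}}$ (the $t = 0$
sample of a noiseless batch) are excluded with a logged count; substrate
readings above $C_{0,\mathrm{eff}}$ by more than a relative tolerance
(default 2%, matching the generator's default noise scale) raise a domain
error suggesting a larger effective initial substrate. A fit needs at
least two more points than regressors. The regressor-matrix condition
number is reported, with a warning above 1e6 and a collinearity error
above 1e10. `compare_models()` fits all four kinds and ranks by adjusted
R² *compared at six decimals* (so that models spanning the same transform
space on clean data count as tied — Monod's and Contois's two-regressor
sets span the identical space, and Andrews/Aibe extend it), with F and
then parsimony ordering the display.

### Fed-batch

`simulate_fed_batch()` integrates the three-state system (substrate,
biomass, product; constant volume) between feed events and applies each
event as an instantaneous balance: $V' = V + \Delta V$,
$C_s' = (C_s V + m)/V'$, $X' = X V/V'$, $C_p' = C_p V/V'$ — biomass and
product masses conserved exactly, substrate mass incremented by the fed
glycerol. The event time appears twice in the output (pre/post state).

## The synthetic generators

`generate_design_responses()` adds independent Gaussian noise to the true
polynomial — exactly the error model ordinary least squares assumes — with
no clipping. `generate_batch_series()` multiplies each measured channel by
independent log-normal factors $e^{\sigma Z}$ ($\sigma$ = the channel CV):
concentrations are positive, so multiplicative noise is the minimal
choice consistent with the data. The $t = 0$ substrate reading is left
exact (the charge is weighed in, not assayed). No replicate-level variance
is available for the design responses, so the design-noise SD default used
in examples (10 μg/L) is a free, documented choice. All generators draw
from a private seeded RNG stream and leave the caller's `.Random.seed`
untouched.

### Calibrated defaults

The default batch spec (`default_trajectory_spec()`, stored versioned in
`extdata/default_kinetics.yaml` and reproduced by
`inst/scripts/calibrate_defaults.R`) emulates the measured 15-L fermentor
run: substrate from 34.34 g/L to ≈21 g/L over 80 h and product reaching
≈261 μg/L, sampled every 4 h to 112 h with 2% CV per channel. Contois
kinetics were chosen for the default because, with half the substrate
remaining at 80 h, the consumption rate under Monod or Andrews kinetics is
still rising — biomass keeps growing and saturation barely falls — so no
first-order product decay can produce a late-run product *maximum*; under
Contois the late-time rate is proportional to the falling substrate, and
the viscosity-inhibition mechanism is also the phenomenologically
appropriate one for a thickening fungal broth. Held at field-typical
values: $k_s = 8$ g/g, $Y_b = 0.45$ g/g, $X_0 = 0.8$ g/L; $\mu_m = 0.0488$
h⁻¹ was root-solved for the 80-h substrate target and
$Y_p = 261.47/(34.34-21.02) = 19.63$ μg/g fixed by the product mass
balance. Product decay defaults to $k_d = 0$ (the exact coupled model);
the documented `kd_shape` = 0.08 h⁻¹ reproduces the late-run product peak
when shape emulation is wanted — the decay is an explicit extension, since
the pure yield coupling cannot make the product decline.

The fed-batch verification fixture (`make_group_fixtures()`) shares one
kinetic spec across the three groups so supplementation is the only
difference: Aibe kinetics ($\mu_m = 0.08$ h⁻¹, $k_s = 15$ g/L, $k_p = 50$
μg/L) in 15 L charged with 300 g glycerol (20 g/L). Product inhibition is
the mechanism water addition acts through in-model — diluting the
inhibitory product raises μ — which is what makes the water-only group
outperform the unsupplemented one; the glycerol group additionally gains
substrate. Group 3's feed is 300 g in 1 L per event at 40 h and 60 h
(600 g fed, 900 g total including the charge).

### What passing tests do and do not show

The generators share the fitting stage's own structural assumptions
(exact yield coupling, independent multiplicative noise, no death phase,
no oxygen effects, no autocorrelated sensor drift). Tests against them
demonstrate correctness of the algebra, the integration, the regression
and the recovery maps — i.e. that the pipeline does what it claims on data
from its assumed model class. They cannot show that real broth follows
that class: on real data the model-comparison ranking, not any single fit,
carries the inference, and the recovered parameters inherit whatever bias
the structural mismatch introduces.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale by choice:
40-observation response fits (with 200–500-replicate Monte-Carlo checks
for unbiasedness and confidence-interval coverage), 20–29-point batch
trajectories, 20 random parameter draws per model kind for the
oracle-equivalence property, 100 noise replicates for recovery medians,
and 100,000 draws for Dunnett adjustment (20,000 in tests). Every
stochastic path takes an explicit integer seed; repeated calls with the
same configuration produce identical primary artifacts, and the pipeline
log records package version, seed and input checksums.

## Known limitations

* The linearized fits are errors-in-variables regressions (noise sits in
  the transformed regressors, not the response); parameter recovery is
  consistent in practice at 2% noise but increasingly biased as noise
  grows or as $C_{0,\mathrm{eff}} - C_s$ approaches zero, where the log
  transform amplifies measurement error.
* $k_p$ and $Y_p$ are not separately identifiable from a single batch
  under the Aibe model; only their ratio is estimated.
* The Dunnett adjustment assumes equal replicate counts and a common
  within-group variance, as the summary-statistic reconstruction cannot
  recover heteroscedasticity beyond the per-group SEs.
* Greedy column selection for large designs is a heuristic; optimality is
  only guaranteed within the exhaustive-search regime.
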