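# epferm

Medium optimization and batch-growth modelling for submerged fermentation
of an ergosterol peroxide (EP) producing fungus.

EP (5α,8α-epidioxy-ergosta-6,22-dien-3β-ol) is a bioactive sterol produced
at trace levels (μg/L) by medicinal fungi. Raising its fermentation yield
is a two-part statistical/kinetic problem, and this package implements both
parts as a tested, reusable pipeline with seeded synthetic-data generators
standing in for the wet lab:

1. **Design of experiments and response surface.** Six medium factors
   (glycerol, yeast powder, peptone, ZnSO₄, MgSO₄, KH₂PO₄; g/100 mL) are
   arranged on a U₁₀(10⁶) uniform design — each factor at ten levels, every
   level used exactly once per column — built by the good-lattice-point
   method with centered L2-discrepancy column selection. With sampling time
   T as control variable, the yield is fitted by ordinary least squares to
   the mixed quadratic/linear response model

   Y = C + α₁T + β₁T² + α₂F₂ + β₂F₂² + Σᵢ₌₃..₇ αᵢFᵢ

   (quadratic in time and glycerol, linear in the rest). Factors with
   negative curvature take their interior stationary point −α/(2β); linear
   factors are clamped to the tested range end matching their coefficient
   sign. Mono-factor screening summaries (mean ± SE) are compared by
   one-way ANOVA with Monte-Carlo Dunnett many-to-one adjustment.

2. **Structured growth kinetics.** Four specific-growth-rate models —
   Monod μ = μₘCs/(ks+Cs), Contois μ = μₘCs/(ksX+Cs) (viscosity proxy),
   Andrews μ = μₘCs/(ks+Cs+Cs²/kᵢ) (substrate inhibition) and Aibe
   μ = μₘ[Cs/(ks+Cs)][kₚ/(kₚ+Cₚ)] (product inhibition) — are coupled to
   substrate through the yields X = X₀ + Y_b(C₀−Cs) and Cₚ = Y_p(C₀−Cs).
   Batches and fed-batches (instantaneous dilution + substrate mass at feed
   events) are integrated with `deSolve`; the integrated linearized forms
   t = f(ln Cs, ln(C₀−Cs), Cs) + C are fitted by regressing *t* on the
   transformed substrate readings, and μₘ, ks, kᵢ and Y_p/kₚ are recovered
   from the regression coefficients.

## Worked example

```r
library(epferm)

design <- load_design_fixture()          # packaged 10-run design + EP responses
fit <- fit_response_surface(assemble_long_table(design))
fit
#>          term estimate      se      t     p
#>     intercept -270.021  77.724 -3.474 0.002
#>      time_h^2   -0.059   0.008 -7.570 0.000
#>        time_h    8.617   1.111  7.760 0.000
#>    glycerol^2   -6.234   3.709 -1.681 0.103
#>      glycerol   50.605  31.967  1.583 0.124
#>  yeast_powder   15.755  44.514  0.354 0.726
#>       peptone  -43.796  44.316 -0.988 0.331
#>         znso4 -466.113 474.077 -0.983 0.333
#>         mgso4  135.518 112.529  1.204 0.238
#>        kh2po4  177.269 108.019  1.641 0.111
#> R2 = 0.691, F(9, 30) = 7.454, p = 1.234e-05

recommend_optimum(fit, design)
#>        factor   value          provenance
#>        time_h 72.8920 interior-stationary
#>      glycerol  4.0587 interior-stationary
#>  yeast_powder  0.6500       clamped-upper
#>       peptone  0.2000       clamped-lower
#>         znso4  0.0050       clamped-lower
#>         mgso4  0.2400       clamped-upper
#>        kh2po4  0.2400       clamped-upper
#> optimum time: 72.9 h; predicted response: 220.97 ug/L
#> medium recipe (g/L, interior optima snapped to the tested grid):
#>     glycerol yeast_powder      peptone        znso4        mgso4       kh2po4
#>        40.00         6.50         2.00         0.05         2.40         2.40
```

The fit says: yield is concave in time and glycerol (negative squared
terms), peaking near 73 h and 4% glycerol; yeast powder, MgSO₄ and KH₂PO₄
help (positive coefficients, pushed to their upper tested levels), peptone
and ZnSO₄ hurt (clamped low). The recipe column is the practical medium in
g/L.

Kinetics, on a synthetic batch calibrated to the measured fermentor run
(substrate 34.34 → 21.0 g/L over 80 h):

```r
series <- generate_batch_series(default_trajectory_spec(seed = 1))
cmp <- compare_models(series, C0_eff = attr(series, "C0_eff"),
                      Yb = 0.45, Yp = 19.63)
cmp$ranking[, c("kind", "adj_r2", "f")]
#>     kind    adj_r2        f
#>  andrews 0.9907674 1002.579
#>     aibe 0.9907674 1002.579
#>    monod 0.9904938 1459.718
#>  contois 0.9904938 1459.718
```

All four linearized fits exceed R² = 0.98 on 2%-noise data, the fit-quality
class the linearization is designed to reach on real broth.

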