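---
title: "Methods: yield models, uncertainty propagation, and feasibility statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: yield models, uncertainty propagation, and feasibility statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltoil)
```

This vignette documents the modelling choices behind `saltoil`: what each
model is, where its default parameters come from, how the synthetic-data
generators are designed, and which numerical decisions matter for
reproducing results.

## 1. Yield response models

### Full polynomial model

The central model predicts oilseed (white mustard) yield on fine-textured,
salt-affected cropland from four root-zone variables:

$$Y = 30.1 + 146.4\,B - 18.3\,B^2 + 83.0\,EC_e - 6.1\,EC_e^2
      + 1301\,LF + 319.8\,\theta_g \quad (\text{kg/ha})$$

with boron $B$ in mg/L, salinity $EC_e$ in dS/m (saturated-paste extract),
leaching fraction $LF$, and gravimetric water content $\theta_g$. Negative
polynomial values are truncated to zero: a regression surface extrapolated
into strongly toxic conditions has no physical meaning below zero yield.

The quadratic terms make the surface concave in $B$ and $EC_e$, with maxima
at $B^\* = 146.4/(2 \times 18.3) = 4.0$ mg/L and
$EC_e^\* = 83.0/(2 \times 6.1) \approx 6.8$ dS/m — mild salinity is
beneficial for this halophyte-adjacent crop, and boron is required in small
amounts but toxic beyond them. The model object carries applicability
ranges (the convex box of the calibration data: $EC_e$ 1.84–29.97, $B$
2.14–24.24, $LF$ 0.08–0.61, $\theta_g$ 0.12–0.25); `select_model()` refuses
to apply the polynomial outside them.

```{r}
sensitivity_analysis()
```

The one-standard-deviation sensitivity table above (SDs 6.06 mg/L for B,
6.29 dS/m for $EC_e$, 0.15 for LF, 0.05 for $\theta_g$) identifies boron as
the dominant yield control: a +1 SD boron shift costs 66% of baseline
yield, against 24% for salinity.

### Tolerance curves

Where only salinity (or salinity and boron) is known, relative-yield
tolerance curves replace the polynomial.

* **Two-piece salt tolerance**: relative yield is 100% up to a threshold
  $a = 8.3$ dS/m, then declines at $b = 17$% per dS/m, reaching zero near
  14.2 dS/m. This threshold–slope form is the standard agronomic salt
  tolerance model.
* **Three-piece boron tolerance**: 100% between 4.2 and 8 mg/L, declining
  28% per mg/L above 8 (zero yield at $8 + 100/28 \approx 11.6$ mg/L).
  Below 4.2 mg/L a deficiency decline applies; its slope is weakly
  constrained by data, and we default to $100/4.2$ %/(mg/L) — a straight
  line from zero yield at $B = 0$ to full yield at the optimum. This is a
  package decision: it makes the curve continuous and total without
  asserting more than is known.
* **Quadratic curves**: smooth alternatives
  $y = 74.0 + 254.6\,EC_e - 18.8\,EC_e^2$ and
  $y = -418.0 + 555.2\,B - 42.4\,B^2$ (kg/ha), with vertices at 6.8 dS/m
  and 6.5 mg/L.

When both stressors are known but the polynomial is inapplicable,
`predict_field_yield()` applies the **most-limiting-factor rule**: yield is
$y_{max} \times \min(\text{relative salt yield}, \text{relative boron
yield})/100$. The default $y_{max} = 936$ kg/ha is the vertex value of the
quadratic salt curve — the best yield the tolerance data themselves
support. A missing stressor is treated as non-limiting (100% relative
yield), so the rule degrades gracefully to salt-only prediction.

```{r}
plot_tolerance_curves()
```

## 2. Model fitting

`fit_yield_regression()` is ordinary least squares (`stats::lm`) of yield
on $B, B^2, EC_e, EC_e^2, LF, \theta_g$, excluding zero-yield sites (a
failed stand carries no information about the response surface slope) and
requiring at least 10 sites. An optional spatially correlated fit
(`nlme::gls` with an exponential correlation structure) is available when
site coordinates are present. `tidy()` and `glance()` methods return
broom-style tibbles.

`backward_select()` implements backward t-score screening: starting from a
candidate set, repeatedly drop the term with the smallest $|t|$ while any
$|t| < 1.8$, refitting each round. The 1.8 default corresponds to roughly
the 90% confidence level at moderate degrees of freedom — deliberately
permissive, since the goal is a parsimonious predictive surface rather than
strict inference.

Breakpoint models are fitted by deterministic grid search
(`fit_two_piece_salt()`, `fit_three_piece_boron()`): the plateau is pinned
at 100%, candidate thresholds step through the observed range (default
0.05 units), and segment slopes have closed-form least-squares solutions
conditional on the threshold. Grid search is slower than smooth optimisers
but cannot silently land in a local optimum on small, noisy trials, and its
resolution (one grid step) is an explicit, testable error bound.

## 3. Field inputs and uncertainty

Regional salinity maps carry prediction error. The package represents it
as a **residual table**: for each mapped salinity category (1-dS/m bins
from 0 to 16, open-ended above 16), the mean and SD of
(predicted − observed) residuals, with data counts. Sampling a field's
"true" salinity draws a Gaussian residual for its category (or for the
whole dataset, mean 0.14, SD 3.11 — the default mode) and subtracts it
from the predicted value, truncating at zero.

Unmapped inputs (B, LF, $\theta_g$) get **lognormal PDFs moment-matched on
the natural scale**: $\sigma^2 = \log(1 + (s/m)^2)$,
$\mu = \log m - \sigma^2/2$, so the generated mean and SD converge to the
configured targets. Lognormality enforces positivity and the right
skewness for edaphic variables. Optional bounds are respected by rejection
resampling (with a clipping fallback after 1000 rounds); LF and $\theta_g$
are additionally clipped to [0, 1].

Leaching fraction can also be estimated from depth ratios of
electromagnetic conductivity or chloride concentration;
`reconcile_lf()` accepts both and flags disagreement beyond a 5% relative
tolerance.

`filter_salt_affected()` defines the study population: fields with
predicted $EC_e \ge 4$ dS/m, excluding orchard and vineyard land covers
(tree and vine crops are not candidates for annual oilseed rotation).

## 4. Monte Carlo engine

`run_simulation()` propagates all input distributions to regional biofuel
production $Q$ (ML/yr). Each iteration draws, per field, a true salinity
(residual model), and B/LF/$\theta_g$ where the field has them; predicts
yield with the model-selection hierarchy; converts to biodiesel volume
(oil content 26%, extraction efficiency 64%, 1.053 L/kg); and area-weights
to the regional total.

Randomness uses **per-field, per-variable sub-streams**: each stream seed
is a deterministic hash (djb2, reduced mod $2^{31}-1$) of
`"<field_id>|<variable>"` combined with the master seed. This gives three
properties the tests rely on, simultaneously:

* **Bitwise reproducibility** — same seed, same draws;
* **Common random numbers** — adding a field, or changing one field's
  inputs, leaves every other field's draws untouched, so regional totals
  respond monotonically to monotone parameter changes; and
* **Area linearity** — areas enter only as multipliers, so doubling areas
  exactly doubles every draw of $Q$.

The engine saves and restores `.Random.seed`, so it does not disturb the
caller's RNG state. Default iteration count is 10,000.

## 5. Feasibility statistics

Simulated $Q$ is summarised by a three-parameter **shifted gamma law**
$Q = \text{shift} + \Gamma(\text{shape}, \text{scale})$, fitted by method
of moments (shape $= 4/\text{skew}^2$, scale $= s\,\text{skew}/2$, shift
$= m - \text{shape}\times\text{scale}$) or by profiled maximum likelihood
(Newton iteration on the digamma equation at each candidate shift). The
gamma family captures the mild positive skew of a sum of many truncated,
skewed field contributions while remaining analytically tractable.

The feasibility metric is the analytic exceedance probability
$P(Q \ge q) = 1 - F_\Gamma\!\big((q - \text{shift})/\text{scale};\,
\text{shape}\big)$ against a facility demand target (default 115 ML/yr).
The built-in reference law `shifted_gamma()` (shift 68.986, shape 6.134,
scale 5.285) has mean 101.4 ML/yr and $P(Q \ge 115) \approx 0.146$:

```{r}
gamma_moments(shifted_gamma())
exceedance_probability(shifted_gamma(), 115)
```

A caveat worth stating: the reference law's analytic SD, skewness and
kurtosis are 13.09, 0.81 and 3.98 (kurtosis non-excess). Any published
summary statistics that differ from these cannot all be consistent with
the same (shift, shape, scale) triple; the package treats only the mean
and the exceedance probability as pinned quantities.

## 6. Synthetic-data generators

The generators exist so every fitting and simulation routine has a ground
truth to be tested against; they emulate the *statistical shape* of a
field trial and a regional database, not any particular dataset.

`generate_trial()` places sites on a jittered grid, draws edaphic
variables from moment-matched lognormal (or truncated normal) marginals,
computes yield from the polynomial plus Gaussian noise (truncated at
zero), and forces a configured number of zero-yield sites at the highest
salinities — where a real trial loses its stand. Nuisance covariates
(pH, saturation percentage, SAR) with no effect on yield are included so
screening tests have something to reject. Defaults (40 sites, 6 zero
yields, marginal means/SDs matching the tolerance-trial summary
statistics) make the default trial behave like the calibration study;
tests that need unbiased recovery narrow the marginals to the region where
truncation is rare.

`generate_region()` draws field areas from a lognormal distribution
rescaled to an exact regional total, salinity-category labels from a
mixture weighted by the residual-table data counts ($\ge 4$ dS/m), uniform
predicted salinities within each category (the open-ended top bin gets a
configurable width, default 4 dS/m), and texture/land-cover flags by
configured fractions (25% coarse, 10% orchard/vineyard by default). The
default size — 1000 fields over 9,700 ha — is a deliberate 1/100-scale
stand-in chosen by this package for fast tests; pass
`total_area_ha = 9.7e5` for a full-scale region.

`generate_gamma_reference_region()` inverts the feasibility analysis: it
constructs a salt-only region whose expected production equals the mean of
a target shifted-gamma law, giving an end-to-end oracle for the simulation
engine (in degenerate mode the pipeline must reproduce the expectation
exactly).

## 7. Numerical decisions

* Yield truncation at zero happens *after* polynomial evaluation and
  *after* noise addition, in that order.
* Residual convention is (predicted − observed); a sampled true salinity
  is predicted minus a residual draw, truncated at zero.
* Breakpoint grids default to 0.05-unit steps; fitted thresholds are
  accurate to one step on noiseless data (tested).
* Skewness and kurtosis are the moment ratios $m_3/m_2^{3/2}$ and
  $m_4/m_2^2$ (kurtosis non-excess, normal = 3).
* Regional totals use 1 ML = $10^6$ L exactly.

## 8. Limitations

* The polynomial model is a calibration-range regression, not a process
  model; outside its box it is undefined by design, and the fallback
  tolerance curves ignore LF and $\theta_g$ entirely.
* The most-limiting-factor rule ignores salt–boron interaction, which is
  known to exist (high salinity can suppress boron uptake); the package
  has no interaction term because none is identifiable from
  single-stressor tolerance data.
* The boron deficiency slope default is a continuity assumption, not a
  fitted value.
* Input PDFs are drawn independently per field and per variable; real
  edaphic variables are spatially and mutually correlated, so regional
  variance is likely understated.
* The shifted-gamma fit by moments is sensitive to sample skewness; for
  near-symmetric simulation output the shift parameter becomes strongly
  negative and only the implied mean, SD and tail probability — not the
  shift itself — should be interpreted.
* Intercropping scenarios (`apply_intercropping_scenario()`) are a simple
  multiplicative uplift on $Q$, not a land-allocation model.
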