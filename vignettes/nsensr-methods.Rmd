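---
title: "Calibrating a canopy N-sensor and deriving the recommendation algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating a canopy N-sensor and deriving the recommendation algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsensr)
```

# The problem

A tractor-mounted N-sensor measures canopy reflectance obliquely on both
sides of the vehicle and summarizes it as a sensor value (SN), a biomass
value and NDVI. To turn these readings into an in-season nitrogen rate for
wheat, the sensor must be calibrated against an established reference for
crop N status — here the SPAD chlorophyll meter — using a plot trial with a
gradient of applied N. `nsensr` implements that calibration chain and the
closed-form recommendation algorithm it produces.

# Footprint geometry

The lenses view the crop at two fixed oblique angles, so the inner and
outer edges of the scanned strip are linear in mounting height $h$ (m) for
a rig of length $d$ (m):

$$X_1 = 0.5\,d + 1.13\,h, \qquad X_2 = 0.5\,d + 1.94\,h .$$

Each side contributes a strip of width $y = X_2 - X_1 = 0.81\,h$, and the
coverage fraction is $2y / (2X_2) = 0.81h/(0.5d + 1.94h)$ — increasing in
$h$, decreasing in $d$, and invariant under scaling both. For the standard
configuration ($d = 2.0$ m, $h = 1.6$ m) the formula gives
$X_1 = 2.808$ m, $X_2 = 4.104$ m and 32% coverage (nearest percent).
Published tabulations of this geometry quote $X_1 = 2.831$ m,
$X_2 = 4.143$ m — about 2–4 cm more than the simplified linear
coefficients yield, presumably from rounding the view-angle tangents; we
report the formula values, and the coverage percentage is 32 either way.
`sensor_footprint()` reports both the fraction and the rounded percentage.

# Sufficiency indices

All readings are normalized as sufficiency indices against a
well-fertilized, non-N-limited reference:
$SI = \text{target}/\text{reference}$, with $SI = 1$ meaning N-sufficient
and lower values meaning more N is needed. Two design choices were open:

* **Which plots form the reference.** Trials rarely have a dedicated
  reference strip, so `calibrate_nsensor()` defaults to the per-stage mean
  of the plots at the highest applied N rate (150 kg N/ha in the default
  design) — the closest in-trial analogue of a "well fertilized reference
  plot". A `reference = "fixed"` mode accepts externally known reference
  values instead; this is also what exact-recovery tests use, since the
  in-trial mean depends on the noise realization.
* **SI above 1.** A target greener than the reference is physically
  meaningful and passes through unchanged; values above a configurable cap
  (default 2) are flagged with a warning, never clamped silently.

# The calibration models

Per growth stage, two ordinary least-squares fits:

$$SI_{SPAD} = a_0 + a_1 N + a_2 N^2 \quad (a_2 < 0), \qquad
  SI_{SPAD} = b_0 + b_1\, SI_{sensor} \quad (b_1 > 0).$$

Plain OLS, no weights or robust loss — these are the regression analyses
the method family uses. The fitting unit is the individual plot by
default; `aggregate = "means"` first averages per N level, since either
convention is defensible and the choice is not settled in the method's
literature. Violations of the shape constraints ($a_2 \ge 0$, $b_1 \le 0$)
warn at fit time so exploratory fits remain inspectable, and become hard
errors only when the fit is passed to algorithm derivation.

# From calibration to recommendation

Solving the quadratic for $N$ at a given $SI_{SPAD}$ has two roots; the
recommendation logic needs the **ascending branch** (the root at or below
the vertex $N_{max} = -a_1/(2a_2)$), so that plots with lower sufficiency
get rates further below the vertex and
$N_{app} = N_{max} - N(SI_{SPAD}) \ge 0$. As printed in the method's
source equations the radical carries a sign that selects the descending
branch; composing the equations forces the ascending choice, which is what
`nrate_for_si()` implements. Two clamps handle field data outside the
calibration envelope: SI above the attainable maximum returns $N_{max}$
with an `at_max` flag (negative discriminant), and SI below the zero-N
response clamps the rate at 0 with a `clamped` flag.

Substituting the bridge into the inverted quadratic collapses the chain to

$$N_{app} = R\,\sqrt{SI_R - SI_{sensor}}, \qquad R = \sqrt{-b_1/a_2},
\qquad SI_R = \frac{4a_2a_0 - a_1^2 - 4a_2b_0}{4a_2b_1}.$$

The radical is essential: $R = \sqrt{-b_1/a_2}$ is algebraically forced by
the composition, and the published booting constant confirms it —
$\sqrt{1.616/0.0006} = 51.90$ against the printed 51.89 (the printed form
of the recommendation equation lost the radical in typesetting). The
identity
$N_{app} = \sqrt{(SI_{max} - SI_{SPAD})/|a_2|}$ with
$SI_{max} = a_0 - a_1^2/(4a_2)$ gives an independent closed-form check,
and the test suite verifies path equivalence — stepwise inversion versus
the parametric form — to $10^{-9}$ relative on 1000 random concave
calibrations. Two numerical caveats shape that test: the equivalence holds
on the ascending branch's natural domain ($SI_{SPAD} \in [a_0, SI_{max}]$;
below $a_0$ the stepwise route clamps at zero while the parametric form
keeps growing), and the zero crossing at $SI_R$ is ill-conditioned in
double precision (the deficit $SI_R - SI_{sensor}$ loses all significant
digits there), so random evaluation points keep 1% of the SI range away
from the crossing and the random quadratics keep $a_1 \ge 10^{-3}$ so the
branch spans a resolvable SI range.

## Published constants and their inconsistencies

The published per-stage coefficient sets are shipped verbatim as fixtures
(`published_coefficients()`, `published_algorithm()`), including their
internal inconsistencies, which the package does not silently repair:

* the booting quadratic $(0.542, 0.003, -0.0006)$ has its vertex at
  2.5 kg N/ha and the tillering one at ~1019 kg N/ha, although the method
  description states the SPAD response peaks at 150 kg N/ha — the printed
  coefficients cannot both be on the stated scale;
* the tillering quadratic implies $SI_{SPAD} \approx 37$ at 150 kg N/ha,
  not a plausible sufficiency index (most likely a misprinted scale), so
  the tillering algorithm constants $(R = 87.17, SI_R = 1.35)$ are not
  recoverable from them ($\sqrt{1.0461/0.00013} = 89.70$);
* the published $SI_R$ values (1.35, 1.33) do not follow from the
  closed form with the printed coefficients (booting gives 0.714).

Derived algorithms therefore carry `provenance = "derived"` and published
ones `provenance = "published"`; they are never mixed.

## SN lookup mode

The second recommendation mode maps raw SN ranges to rates. Only the
extreme anchors of the published per-stage tables are available
(tillering: SN 7–11 → 75, SN 33.1–37 → 45 kg N/ha; booting: SN 17–24 →
40, SN 76.1–84 → 25 kg N/ha); inside an anchor range the rate is exact,
between ranges `recommend_from_sn()` interpolates linearly between the
flanking (range midpoint, rate) pairs and flags the result as
interpolated, and outside the table the nearest anchor's rate is returned
with an extrapolation warning. The resulting map is monotone
non-increasing in SN.

# The synthetic trial generator

`simulate_trial()` emulates the calibration's assumed design: a
randomized complete block trial with N levels 0–150 kg N/ha in six steps,
three replicate blocks, observed at tillering, booting and ear emergence,
with the seasonal total split 50% basal / 25% / 25% at the first two
irrigations (`dose_schedule()`). Per plot and stage it generates
SI-consistent attributes rather than raw spectra — the algorithm chain
never consumes wavebands, so simulating the full spectral scan would add
surface without testable benefit:

* $SI_{SPAD}$ from the stage quadratic at the plot's N rate plus Gaussian
  noise; SPAD is the index times a reference SPAD (default 50, an
  arbitrary plausible meter value that cancels in every SI computation);
* $SI_{sensor}$ from the inverted stage bridge plus noise; NDVI is the
  index times the stage's reference NDVI;
* SN and biomass as increasing linear transforms of the sensor index plus
  noise, with stage-specific scales chosen so SN spans roughly the ranges
  the lookup tables cover;
* leaf N (% w/w) and chlorophyll (mg/g) affine in the true SPAD index,
  chlorophyll with relatively larger noise (it is the more weakly
  correlated lab measurement);
* grain yield (t/ha) once per plot, stage-invariant — a linear-plateau
  function of applied N (plateau at 130 kg N/ha) plus a replicate block
  effect — since stage attributes are correlated against a single final
  yield.

Noise is counter-based: each draw is keyed on (seed, plot, stage,
attribute), so runs are reproducible for a fixed design seed, adding an
attribute never perturbs existing draws, and the global RNG stream is
untouched.

**Default truth parameters.** The default stage quadratics place the
response vertex at 150 kg N/ha (consistent with the stated peak of the
SPAD response) with amplitude shrinking and noise growing across stages
(multipliers 1 / 1.8 / 3), so that sensor–laboratory–yield correlations
are strongest at tillering — the qualitative stage ordering the analysis
module must reproduce. The published coefficient sets are deliberately
**not** the default generative truth: their quadratics turn over within a
few kg N/ha of zero and would drive sufficiency indices (and hence NDVI)
far outside the physical range over a 0–150 trial. They remain available
as `truth_presets("paper_tillering")` / `"paper_booting"` for exact
coefficient-recovery tests, which bypass NDVI range validation and use
fixed references. Because the vertex-at-150 choice makes $|a_2|$ small,
calibrations fitted to the default truth yield a large multiplier
$R = \sqrt{b_1/|a_2|}$ (hundreds rather than ~52); this is a property of
any response that peaks at the top trial rate, not a defect of the fit.

What passing tests on this generator do **not** show: robustness to real
canopy reflectance artifacts (soil background, row orientation, sun
angle), non-Gaussian or heteroscedastic field noise, spatial
autocorrelation between plots, or growth-stage timing errors. The
generator validates the statistical machinery, not the sensor physics.

# Analysis machinery

`pearson()` reports the product-moment correlation with a two-sided
p-value from the $t$ transform on $n-2$ degrees of freedom;
`correlation_table()` produces one cell per sensor attribute × target ×
stage plus "overall" rows that **pool raw observations across stages**
(not averages of per-stage $r$ — pooling is the natural construction of
an overall column and is documented as an assumption). No
multiple-testing correction is applied; raw p-values are reported.
Published correlation tables from field trials are not reproduction
targets — the field data are unavailable — so the module's contract is
structural (oracle-verified statistics, stable table shape) plus the
qualitative tillering-strongest ordering under the default generator.
`trend_fit()` fits OLS polynomials (default quadratic) of an attribute
against N rate; a constant response is reported as $R^2 = 0$.

# Problem sizes and tolerances

The test suite uses the 54-row default trial throughout; Monte-Carlo
checks use 500 seeded replicates for coefficient-recovery bias (fitted
$a_2$ within 10% of truth on average, at SI noise 0.02), 200 seeds for
the correlation stage-ordering property (required in ≥ 90% of seeds), and
1000 random coefficient sets for path equivalence at $10^{-9}$ relative.
Exact-recovery assertions use $10^{-9}$; closed-form identities
$10^{-12}$. Recommendations are reported to 0.1 kg N/ha; all internal
arithmetic is double precision.

# Known limitations

* Calibrations are per stage and per trial; no pooling across stages,
  sites or seasons, and no mixed-effects structure for blocks.
* No economic optimum, soil-test or yield-goal adjustment of the
  recommended rate — the algorithm is pure sufficiency deficit.
* The SN lookup between published anchors is an interpolation convention,
  not a published mapping.
* The published coefficient fixtures carry the inconsistencies listed
  above; quantities that depend on them (tillering $R$, published $SI_R$)
  are treated as authoritative constants, not derivable results.
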