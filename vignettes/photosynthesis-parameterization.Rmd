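---
title: "Parameterizing C3 and C4 photosynthesis models with species-specific kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameterizing C3 and C4 photosynthesis models with species-specific kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photokin)
```

## The problem

Biochemical models of leaf photosynthesis — the FvCB model for C3 leaves
and the enzyme-limited von Caemmerer model for C4 leaves — turn a measured
CO2-response curve into capacity parameters: the maximum Rubisco
carboxylation velocity $V_{cmax}$, the electron transport rate $J_{max}$,
and (for C4) the maximum PEPC carboxylation velocity $V_{pmax}$.  Those
estimates are only as good as the enzyme kinetic constants fed into the
model.  It is common practice to parameterize every species with the
"standard" tobacco constants of Bernacchi, yet Rubisco kinetics differ
measurably between species, and the difference propagates into biased
capacity estimates.  `photokin` packages species-specific in vitro
constants for rice, wheat and maize at 25 and 38 °C, the full fitting
chain from raw gas exchange to capacities, and the paired-refit machinery
that quantifies the bias of using standard rather than species-specific
constants.

## Kinetic constants and their temperature scaling

The bundled table (`kinetics_table()`) holds, per species and measurement
temperature, the Michaelis–Menten constants of Rubisco for CO2 ($K_c$, Pa)
and O2 ($K_o$, kPa), the CO2 compensation point without mitochondrial
respiration ($\Gamma^*$, Pa) and, for maize, the PEPC constant ($K_p$,
Pa).  Three conventions hold everywhere:

* **Partial-pressure basis.**  In vitro assays yield concentrations; they
  were converted with Henry's law using the bundled solubilities (CO2:
  0.0334 and 0.0243 mol L$^{-1}$ bar$^{-1}$ at 25 and 38 °C; O2: 0.00126
  and 0.00102).  `conc_to_partial_pressure()` exposes the conversion.
* **One oxygen reference.**  $\Gamma^* = 0.5\,O/S_{c/o}$ with $O$ = 21 kPa.
  The C4 model's oxygen partial pressure, usually quoted as 210 mbar, is
  the same number; keeping a single constant removes a classic source of
  mbar/kPa unit drift.  The specificity factor $S_{c/o}$ is not stored: it
  is back-derived from $\Gamma^*$, so the two can never disagree.
* **Apparent vs. true $K_c$.**  Assays run at 0% and 21% O2 identify
  $K_o$ through competitive inhibition,
  $K_c^{21} = K_c^{0}(1 + O/K_o)$ (`kc_apparent()` and its inverse
  `ko_from_kc_pair()`).

Constants are known at exactly two temperatures, so temperature scaling
uses the exactly-constrained two-point Arrhenius form
$k(T) = \exp(c - E_a / (R T_K))$ with $c$ and $E_a$ solved from the
25/38 °C pair (`kinetics_at_temperature()`).  This adds no free
parameters, reproduces both measured endpoints exactly, and is strictly
monotone between them.  A Q10 form is available as an alternative flag;
the two differ by well under 1% inside the measured bracket.  The
standard sources are `standard_kinetics("bernacchi")` — the tobacco
constants with their published exponential temperature responses, in both
published variants (the mesophyll-corrected chloroplastic-basis constants,
the default here because all fitting is on a $C_c$ basis, and the earlier
intercellular-basis set) — and `standard_kinetics("voncaemmerer")`, the C4
defaults ($K_c$ = 65 Pa, $K_o$ = 45 kPa, $K_p$ = 8 Pa, dimensionless
$\gamma^*$ = 0.000193) with $K_p$ held invariant with temperature.

## The C3 chain

For rice and wheat each curve passes through four stages
(`fit_aci_c3()` runs them all):

1. **Day respiration**: $R_L = R_{dark}/2$ from the pre-dawn dark
   respiration measured at the same leaf temperature (an optional
   `rl_mode = "free"` estimates $R_L$ instead).
2. **Electron transport** from pulse-modulated fluorescence:
   $\Phi_{PSII} = (F_m' - F_s)/F_m'$ and
   $ETR = \Phi_{PSII}\cdot PPFD\cdot\alpha\cdot\beta$ with defaults
   $\alpha = 0.865$ (midpoint of the 0.86–0.87 absorptance range measured
   for these crops, which did not differ between treatments) and
   $\beta = 0.5$.
3. **Mesophyll conductance** by the variable-J method,
   $$g_m = \frac{A_N}{C_i - \Gamma^*\,\dfrac{ETR + 8(A_N+R_L)}
     {ETR - 4(A_N+R_L)}},$$
   computed per point.  Points violating admissibility
   ($ETR \le 4(A_N+R_L)$, non-positive denominator or conductance) are
   excluded with a recorded reason, never a hard failure: real curves
   always contain a few near the compensation point or at CO2 saturation.
   The curve-level scalar used for the $C_c$ conversion is the **median**
   of admissible points inside a default $C_i$ window of 150–1500
   µmol mol$^{-1}$; the median rather than the mean because the estimator's
   denominator becomes small at both ends of the curve, making extreme
   points heavy-tailed under measurement noise.  A `gm_mode = "per-point"`
   alternative keeps the pointwise values.
4. **FvCB fit on the $C_c$ basis**: $C_c = C_i - A_N/g_m$, then least
   squares of
   $$A_N = \min\!\left(V_{cmax}\frac{C_c-\Gamma^*}{C_c+K_c(1+O/K_o)},\;
     \frac{J}{4}\frac{C_c-\Gamma^*}{C_c+2\Gamma^*}\right) - R_L$$
   with the NADPH-basis electron coefficients 4 and 8.

The hard minimum gives reproducible limitation labels but leaves a kink
in the least-squares surface, and — more treacherously — a flat ridge: once
$V_{cmax}$ is large enough that no point is Rubisco-limited, the SSE no
longer depends on it.  Plain multi-start descent can stall on that ridge,
returning an arbitrary large $V_{cmax}$.  The fitter therefore profiles
the SSE over a fine logarithmic $V_{cmax}$ grid (the inner 1-D $J_{max}$
problem is solved by a grid scan plus local refinement, because the SSE
is also flat in $J_{max}$ beyond the point where Rubisco limitation binds
everywhere, which defeats a naive golden-section search), selects polish
starts in SSE order with enforced diversity in $V_{cmax}$, and finishes
with L-BFGS-B plus a Nelder–Mead pass.  Everything is deterministic given
the data.  Standard errors come from the residual covariance
($\sigma^2 (J^\top J)^{-1}$ with a numerical residual Jacobian).

`gm_ethier()` provides the standard alternative in which $g_m$ is a single
parameter shared along the curve, fitted jointly with $V_{cmax}$ and
$J_{max}$ through the quadratic (finite-$g_m$) form of each limitation.
On data generated with constant $g_m$, the variable-J and single-$g_m$
routes agree; the package treats the agreement as a cross-check, not a
substitute.

Units: gas-exchange variables stay in instrument units (µmol mol$^{-1}$,
mol m$^{-2}$ s$^{-1}$), conductances are on a mole-fraction basis, and
kinetic constants convert from Pa through the per-record atmospheric
pressure (default 101.325 kPa — the pressure is not part of the bundled
tables, so it is a per-record field).  The stomatal water-to-CO2
diffusivity divisor is 1.6 wherever total conductance
($1/g_t = 1.6/g_s + 1/g_m$) is formed.

## The C4 model

For maize, `fit_aci_c4()` inverts the enzyme-limited von Caemmerer
system,
$$A = g_m(C_i - C_m), \qquad
  A = \frac{C_s V_{cmax}}{C_s + K_c(1+O/K_o)}
      \left(1-\frac{\gamma^* O}{C_s}\right) - R_L, \qquad
  A = \frac{C_m V_{pmax}}{C_m + K_p} - g_{bs}(C_s - C_m) - R_m,$$
with fixed $O$ = 210 mbar, $g_{bs}$ = 3 mmol m$^{-2}$ s$^{-1}$ and $g_m$ =
2 mol m$^{-2}$ s$^{-1}$ held constant across treatments.  $\gamma^*$ is
dimensionless ($\Gamma^*/O$; the 0.000193 convention) — the only reading
under which the $(1-\gamma^* O/C_s)$ term is dimensionally consistent —
and own-kinetics $\Gamma^*$ (Pa) is divided by $O$ at the module boundary.
$R_m = 0.5 R_L$ (i.e. $R_{dark}/4$) follows the usual convention; the
value is configurable since nothing in the data constrains it.  CO2 state
variables stay in µmol mol$^{-1}$ (matching the conductance bases);
conversion to Pa happens only inside the kinetic terms.

Given $(V_{cmax}, V_{pmax})$ and a point's $C_i$, the three equations
collapse to one residual in $A$ that is strictly decreasing (raising $A$
lowers $C_m$, the pump rate and $C_s$ simultaneously), so the solver uses
monotone bisection on the physical bracket $[-R_L - R_m - 5, V_{cmax}]$,
vectorized across points (70 halvings, resolution far below 1e-9).  The
tests verify it against an independent dense-scan oracle to 1e-6 over
1000 random parameter draws.  Fitting follows the smoothed-curve
convention: a non-rectangular hyperbola is fitted to the observed points
and evaluated on a 5 µmol mol$^{-1}$ grid, and $(V_{cmax}, V_{pmax})$ are
estimated by least squares against the gridded curve (`smooth = FALSE`
fits the raw points; on noiseless data the two agree to well under 1%).
The exact sequencing of the published estimation recipes (which $C_i$
windows feed which parameter) is not reconstructible, so the joint
least-squares formulation is this package's explicit choice; $V_{pmax}$
identifiability is guarded by requiring points at
$C_i \le 100$ µmol mol$^{-1}$.

## The bias analysis

`refit_with_kinetics()` reruns the *entire* pipeline — including the
$g_m$ re-estimation with the alternative $\Gamma^*$ — under a standard
kinetics source and pairs the estimates, and `bias_summary()` regresses
own on standard (that orientation reproduces the reference statistics
from the bundled treatment-mean tables) and reports the mean percent
overestimation $100(\mathrm{standard}/\mathrm{own}-1)$.  The regression
uses treatment means, with intercept; both choices were validated against
the bundled tables, where they reproduce slopes of 0.98 (rice) and 0.86
(wheat) with $r^2 > 0.99$ and a pooled overestimation of ~15%.  The
bundled table rows are data, not recomputed quantities: the raw curves
behind them are not public, which is exactly why the synthetic generator
exists.

## What the synthetic generator emulates — and what it does not

`simulate_experiment()` emits the full 3 species × 2 growth temperatures
(25/38 °C) × 2 irrigation levels × 2 measurement temperatures factorial,
default 4 replicates, 13-point $C_a$ sweep spanning 50–2000 µmol mol$^{-1}$
(96 curves).  Design choices:

* **Cell means** for $V_{cmax}$/$J_{max}$/$V_{pmax}$ are seeded from the
  bundled own-kinetics treatment means, so every simulated treatment is
  physiologically scaled.  These are scenario presets for validation, not
  ground truth for any empirical claim.
* **Water deficit** is expressed exactly as the study defines it
  operationally: $g_{s,WD} = 0.6\,g_{s,WW}$ (a 40% stomatal reduction).
  Baselines: $g_s$ = 0.35 (C3) / 0.25 (maize) mol m$^{-2}$ s$^{-1}$;
  $g_m$ = 0.30 (WW) / 0.18 (WD); $R_{dark}$ rises from 1.0 to
  3.5 µmol m$^{-2}$ s$^{-1}$ with measurement temperature in control-grown
  plants and less steeply (1.8 → 2.5) in heat-acclimated ones — all
  mid-range values for irrigated cereal crops.
* **Noise** is Gaussian on $A_N$ only (default sd 0.5 µmol m$^{-2}$
  s$^{-1}$, the primary measured channel); replicate plants vary by a 5%
  lognormal CV on capacities and conductances.
* **Steady states** are solved exactly: each point balances stomatal
  supply, mesophyll transfer and biochemical demand, and the emitted
  fluorescence is consistent with the operating electron transport
  ($J = (A+R_L)(4C_c+8\Gamma^*)/(C_c-\Gamma^*)$), which makes the
  variable-J inversion exact on noiseless data — the basis of the
  round-trip oracles in the test suite.
* **Determinism**: one sub-seed per (cell, replicate) drawn from the
  design seed drives both parameter jitter and noise, so cells are
  independent streams and a seed reproduces the dataset bit for bit.

The generator does **not** simulate instrument drift, chamber leaks,
multi-flash fluorescence corrections, stomatal patchiness, or any
temperature dependence of $g_m$ beyond what the preset tables encode.
Passing recovery tests therefore demonstrate that the estimation chain is
consistent and unbiased *under the model's own assumptions* at realistic
noise — they do not certify accuracy against the additional error sources
of real gas-exchange data.

## Numerical choices and degenerate inputs

* Fits need ≥ 5 surviving points; fewer is an error, and a curve whose
  points sit entirely on one side of the limitation transition triggers a
  degraded-fit warning and an identifiability flag rather than a silent
  estimate.
* The variable-J admissibility filter excludes (with a logged reason)
  points below the compensation point and saturated points where
  $ETR \approx 4(A_N+R_L)$.
* Non-positive $C_c$ flags the point invalid; zero flux maps to zero
  conductance.
* The A-Ci smoother falls back to monotone linear interpolation, with a
  warning, if the hyperbola fit fails.
* Problem sizes used by the validation runs — a 13-point curve per fit,
  200 replicate curves for the noise-bias check, the 96-curve factorial
  for recovery scoring, 1000 random draws for the C4 solver cross-check —
  were chosen so the whole suite completes in a few minutes on a laptop
  while leaving the Monte-Carlo error an order of magnitude below every
  tolerance tested.

## Known limitations

* Triose-phosphate-utilization limitation is not modeled (never invoked
  in the underlying analysis); curves saturating through TPU would be
  misattributed to RuBP limitation.
* The light-limited (J-based) regime of the full C4 model is out of
  scope: all curves are assumed measured at saturating light.
* Index standard errors use the delta method for ratios of independent
  means, and "differs from 1" tests use a two-sided t on the log ratio —
  deliberate, documented choices where the original procedure is
  unstated.
* Whether capacity fitting should exclude the highest-$C_i$ points is
  left to the user (no automatic truncation).
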