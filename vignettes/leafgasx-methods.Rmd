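---
title: "Models and methods behind leafgasx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leafgasx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafgasx)
```

`leafgasx` analyses leaf-level gas-exchange and chlorophyll-fluorescence
measurements of C3 photosynthesis: rapid A--Ci response (RACiR) correction,
two-limitation FvCB fitting, the Laisk construction for the CO2 compensation
point and day respiration, variable-J mesophyll conductance, light-response
and photorespiration analysis, and quenching/photoprotection diagnostics.
Every estimator in the package is validated against a forward simulator with
known ground truth; this vignette documents the models, the conventions and
defaults, the genuinely open design choices, and the limitations that users
should keep in mind when moving from simulated to real data.

## The forward model

Net assimilation follows the Farquhar--von Caemmerer--Berry model. Gross
carboxylation is the minimum of the Rubisco-limited rate and the
RuBP-regeneration-limited rate at the chloroplast CO2 mole fraction $C_c$:

$$W_c = \frac{V_{cmax} C_c}{C_c + K_c(1 + O/K_o)}, \qquad
  W_j = \frac{J C_c}{4C_c + 8\Gamma^*}, \qquad
  A = \left(1 - \frac{\Gamma^*}{C_c}\right)\min(W_c, W_j) - R_{day}.$$

Electron transport saturates with light as a non-rectangular hyperbola,
$\theta J^2 - (\alpha I + J_{max})J + \alpha I J_{max} = 0$ (smaller root,
evaluated in the cancellation-free form $2\alpha I J_{max}/(s + \sqrt{s^2 -
4\theta \alpha I J_{max}})$). With finite mesophyll conductance, $C_c = C_i -
A/g_m$ is solved analytically per limitation branch (a quadratic in $A$; the
smaller admissible root is taken, and ties between branches are reported as
Rubisco-limited). Comparing *gross* rates rather than net rates keeps the
limitation flag meaningful below the compensation point, where the net-rate
`min()` would invert.

Kinetic constants are fixed at the standard 25 degC tobacco-derived values,
$K_c = 404.9$ umol mol$^{-1}$, $K_o = 278.4$ mmol mol$^{-1}$ and $\Gamma^* =
42.75$ umol mol$^{-1}$ at ambient oxygen (210 mmol mol$^{-1}$). No
temperature response is applied: the emulated protocols measure at a single
cuvette temperature, and adding kinetic temperature corrections without data
to constrain them would only pretend precision. $\Gamma^*$ scales linearly
with oxygen; the effective Michaelis constant $K_c(1+O/K_o)$ follows the
oxygen level too, so a low-O2 simulation is internally consistent.

Fluorescence is emitted per light step from a Stern--Volmer NPQ response,
$NPQ(I) = NPQ_{max}\, I/(I + K_{50})$, with $F_m' = F_m/(1+NPQ)$ and $F_s =
F_m'(1-\Phi_{PSII})$ where $\Phi_{PSII} = J/(I \cdot \alpha_{leaf} \cdot
f_{PSII})$. This makes the loop exact by construction: fluorescence-derived
ETR inverts to the model's $J$, which is what lets the variable-J estimator
be validated to machine precision. Photoinhibition is modelled only through
its qPd signature: after each illumination step the dark minimal
fluorescence is $F_o'^{calc}(1 + k_{inh}\max(0, I - I_{crit}))$.

## What the simulator emulates, and what it does not

The generator reproduces the study protocols verbatim: a 20 to 1520 ppm "up"
CO2 ramp at 100 ppm min$^{-1}$ recorded every 2 s (451 records over 900 s)
with a polynomial empty-chamber artifact in reference CO2; light-response
steps 1500, 1200, 900, 600, 300, 150, 50 umol photons m$^{-2}$ s$^{-1}$ at
400 umol mol$^{-1}$ chamber CO2 under normal air and under a nitrogen mix
(10 mmol mol$^{-1}$ O2 -- the protocol states only "below 1%"); the
eight-step qPd script 60, 100, 250, 400, 600, 850, 1150, 1500; and three
low-light Laisk segments at PAR 421/210/42 or 421/210/63 over the 50--150
umol mol$^{-1}$ CO2 window. Stomatal conductance defaults to 0.1 mol m$^{-2}$
s$^{-1}$, anchored on the study populations' reported means (about 0.106
well-watered, 0.056 under water deficit); intercellular CO2 follows $C_i =
C_a - 1.6A/g_{sw}$. Noise is additive Gaussian on assimilation and
multiplicative Gaussian on fluorescence, with one seed governing a whole
trace.

It does **not** emulate chamber mixing dynamics, diffusion leaks (beyond the
empirical artifact polynomial), stomatal kinetics, match-offset drift,
triose-phosphate-utilisation limitation, the Kok effect, or biological
replicate variance. Passing round-trip tests therefore demonstrates that the
estimators invert the stated model correctly at the stated noise levels --
not that real instrument data are free of artefacts the model lacks.

## RACiR cleaning and correction

The delta filter keeps a record only when its assimilation is within the
threshold of the *last kept* record (the first record is always kept). This
anchored rule is a single deterministic pass and is idempotent. Its
threshold must be read against the ramp's intrinsic per-record increment:
at 100 ppm min$^{-1}$ sampled every 2 s, a leaf with $V_{cmax} = 60$ and
$g_{sw} = 0.1$ traverses up to ~0.1 umol m$^{-2}$ s$^{-1}$ per record in the
steep region, so the instrument-protocol value of 0.05 -- appropriate for
low-conductance leaves where increments stay below it -- would discard a
clean simulated ramp wholesale. `delta_filter()` defaults to the protocol's
0.05; the pipeline default is 0.15, above the intrinsic increment, so that
the filter removes transients and outliers rather than the ramp itself.

The empty-chamber artifact is modelled as a polynomial in reference CO2 of
degree 1--5, selected by small-sample corrected AIC with a parsimony rule
(smallest degree within 2 AICc units of the minimum). The corrected
assimilation is $A - \hat f(CO_{2,ref})$, $C_i$ is recomputed from the
corrected flux and stomatal conductance, and the output is restricted to the
CO2 window where the two ramps overlap (at least 80% of the leaf ramp is
required). The protocol's "system residual time delay" correction is not
parameterised in the source instrument documentation; an optional constant
shift, estimated by maximising the cross-correlation of the two traces'
first differences, is provided behind `align_lag = TRUE` and off by default.

## Bilinear A--Ci fitting

Both FvCB branches are linear in their rate parameter once $\Gamma^*$, the
kinetic constants and $R_{day}$ are fixed, so for each candidate transition
(the grid is the observed $C_i$ values; SSE ties break toward the lower
transition) the two segments are fitted by least squares and the pooled SSE
is minimised. The fit is on a $C_i$ basis with $g_m$ treated as infinite --
the protocol estimates $g_m$ separately by variable-J, and folding a finite
$g_m$ in here would double-count it. $R_{day}$ is fixed to the Laisk
estimate when available, otherwise co-fitted with a lower bound of zero.

The fitted RuBP coefficient is $J$ at the measurement PAR. Whether the
study's "$J_{max}$ at PAR = 1261" convention means the hyperbola's asymptote
or $J$ evaluated at 1261 umol photons m$^{-2}$ s$^{-1}$ is ambiguous, so the
fit reports all three: `J_at_par` (measurement PAR), `Jmax_asymptote`
(inverted through the $J$--PAR hyperbola, $J_{max} = J(\alpha I - \theta
J)/(\alpha I - J)$), and `J_at_ref` (the asymptote re-evaluated at 1261).
Unidentifiability is declared when a single limitation explains the curve as
well as the bilinear model does (SSE comparison), naming the missing regime.

## The Laisk construction and its curvature bias

Each low-light segment gets an OLS line; the three pairwise intersections
form a triangle whose barycentre estimates $(C_i^*, -R_{day})$. The
$x$ coordinate is the *apparent*, $C_i$-basis compensation point: it equals
$\Gamma^*$ only for infinite $g_m$ (in general $C_i^* = \Gamma^* -
R_{day}/g_m$), and the result object keeps the name `GammaStar_app` to
preserve that distinction. Exactly concurrent lines are a degenerate
triangle and are recovered exactly; two segments with equal slopes (within
$10^{-10}$) raise a parallel-lines error; a barycentre above the $C_i$ axis
is returned with an out-of-range flag rather than suppressed.

The segment generator's default model is the construction's own working
assumption: locally linear segments through the true point $(C_i^*,
-R_{day})$ with the slope the FvCB model has there, $s = \sigma/(1 +
\sigma/g_m)$, $\sigma = J(I)/(12\Gamma^*)$. That is the appropriate
data-generating process for validating a linear estimator, exactly as OLS is
validated on data from the linear model. The full curvilinear forward model
is available with `model = "fvcb"`, and applying the linear construction to
it exposes a genuine, structural limitation of the method worth knowing
about:

```{r curvature-bias}
p <- fvcb_params()  # GammaStar = 42.75, Rday = 1
fit_tan <- fit_laisk(simulate_laisk_segments(p, model = "tangent"))
fit_fvcb <- fit_laisk(simulate_laisk_segments(p, model = "fvcb"))
c(tangent = fit_tan$GammaStar_app, fvcb = fit_fvcb$GammaStar_app)
c(tangent = fit_tan$Rday, fvcb = fit_fvcb$Rday)
```

Over the protocol's 50--150 umol mol$^{-1}$ window the RuBP-limited response
$(C_i - \Gamma^*)/(4C_i + 8\Gamma^*)$ is strongly concave (its denominator
is comparable to $C_i$), so straight lines fitted to exact FvCB data miss
the true intersection by some 10--30% in $C_i^*$ and far more in $R_{day}$
-- with zero measurement noise. The bias shrinks only as the window tightens
around the compensation point. Users applying the construction to real data
should treat the window choice as consequential, not cosmetic.

## Variable-J mesophyll conductance

$$g_m = \frac{A_N}{C_i - \Gamma^* \dfrac{ETR + 8(A_N + R_{day})}
{ETR - 4(A_N + R_{day})}}$$

The $\Gamma^*$ term is the $C_c$ implied by the RuBP-limited model, so the
estimator is only meaningful at steps where electron transport limits
assimilation; at Rubisco-limited steps the implied $C_c$ is wrong and the
result is biased even when it looks plausible. The pipeline therefore
selects RuBP-limited steps (from simulator metadata when present, otherwise
a mid-light PAR window) and summarises with the median of the unflagged
values. Non-physical entries ($g_m \le 0$, $C_c \ge C_i$, $C_c \le 0$) are
flagged, never silently dropped. The ETR conversion $\Phi_{PSII} \cdot I
\cdot 0.84 \cdot 0.5$ uses the community-standard absorptance and PSII
fraction; the source protocol does not state them, and both are arguments.

## Light response and photorespiration

The four-parameter non-rectangular hyperbola
$A_n = \left[\Phi I + A_{max} - \sqrt{(\Phi I + A_{max})^2 - 4\Theta \Phi I
A_{max}}\right]/(2\Theta) - R_d$ is fitted by bounded Levenberg--Marquardt
least squares, multi-started over $\Theta \in \{0.3, 0.5, 0.7, 0.9\}$. The
root is evaluated in the cancellation-free form, which handles $\Theta = 0$
as the rectangular hyperbola without a special case. A fit with a parameter
pinned at a bound carries a boundary flag; a flat curve is returned as
unidentifiable rather than fitted. Note one exact small-$\Theta$ fact: the
deviation of the NRH from the rectangular hyperbola is $\Theta p^2/s^3$ to
first order ($p = \Phi I A_{max}$, $s = \Phi I + A_{max}$), about $3\times
10^{-6}$ at $\Theta = 10^{-6}$ for typical magnitudes -- a property of the
function, not of the implementation.

Photorespiration is the operational difference $P_{hresp} = A_G - A_N$
between the low-O2 and normal-air curves, aligned on the intersection of
their PAR grids; negative values are retained and flagged as
noise-transparent. Two opposing systematic errors separate this difference
from the true photorespiratory release $0.5V_o$: suppressing oxygenation
redirects electron transport and relieves the $K_m(O)$ competition (a
3--3.8-fold inflation at matched $C_c$), while the higher assimilation under
low O2 draws $C_i$ down through the stomata (a deflation that grows as
$g_{sw}$ falls). At the simulator defaults ($g_{sw} = 0.1$, saturating PAR)
the net effect is $P_{hresp} \approx 1.6 \times 0.5V_o$; at the water-deficit
conductance (0.056) the two errors nearly cancel ($\approx 0.88\times$); at
high conductance the inflation dominates ($>2.5\times$). The simulator embeds
both $0.5V_o$ and the noiseless $A_G - A_N$ per step so users can see this
directly; the package reports the difference as measured and does not
"correct" it.

The saturation-PAR statistic formalises a visual judgement: the plateau is
the mean of the two largest values and saturation is the smallest PAR
reaching 95% of it (the fraction is an exposed convention, with optional
linear interpolation between bracketing steps).

## Quenching and the photoprotection threshold

$qP = (F_m' - F_s)/(F_m' - F_o')$ and, following the source protocol's
printed form, $qN = (F_m - F_m')/(F_m - F_o')$ with the light-adapted
$F_o'$ in the denominator. The classical convention divides by $F_m - F_o$;
both are available, the printed form is the default, and the discrepancy is
deliberate and documented rather than silently "fixed". $F_o'$ is calculated
as $F_o / (F_v/F_m + F_o/F_m')$ when not measured; measured $F_o'$ is
preferred for qP when present, while qPd always uses the calculated form,
per the protocol it implements: $qPd = (F_{m,dark}' - F_{o,actual}) /
(F_{m,dark}' - F_o'^{calc})$. qPd equals 1 while NPQ remains fully
protective and falls below 1 when post-illumination minimal fluorescence
rises above the calculated $F_o'$ -- the early signature of photoinhibition.

The photoprotection threshold is the smallest scripted PAR with qPd below
0.98. The criterion is a convention (the protocol literature says "deviates
from the maximum" without a cutoff) and is exposed as an argument; its
resolution is inherently one scripted light step, which is why validation
asserts agreement with the simulator's $I_{crit}$ to within one step.

## Pigment and light-interception indices

De-epoxidation state $(Z+A)/(V+A+Z)$, chlorophyll $a/b$, the
xanthophyll-cycle pool and lutein per unit chlorophyll, and incident-leaf
PAR as a percentage of above-canopy PAR. "Chlorophyll" defaults to $chl\,a +
chl\,b$; the source protocol does not specify the denominator, so a
chl-a-only basis is selectable. All are unit-free given consistent inputs.

## The pipeline and problem sizes

`run_pipeline()` mirrors the study layout -- four varieties by two
irrigation treatments -- with treatment-level truth anchored on the study's
reported means and fixed variety multipliers. Stages run in dependency
order: Laisk first (its $R_{day}$ feeds the A--Ci fit and its compensation
point the variable-J step), then RACiR correction and bilinear fitting, the
paired light curves with NRH fits and photorespiration, variable-J $g_m$,
the qPd protocol and threshold, and the indices. Each sample derives its own
sub-seed from the master seed, failures are isolated per sample and recorded
in the bundle, and the config hash (of every override) is embedded in every
report so reruns are verifiable.

Default problem sizes keep a full validation run light: 40-point A--Ci
curves, 451-record ramps, 7-step light curves, 18-point Laisk sets, 8-step
qPd scripts; Monte-Carlo checks use 200 seeds (Laisk) and 100 seeds (A--Ci).
The complete 8-sample pipeline runs in well under a minute on one core.

## Known limitations

* All estimates inherit the fixed kinetic constants; no temperature
  normalisation is provided.
* The Laisk curvature bias above applies to any linear implementation of the
  construction on curvilinear data, including this one.
* The low-O2 photorespiration difference is an operational quantity with the
  quantified biases above, not an estimate of $0.5V_o$.
* TPU limitation is not modelled; curves showing it would be misattributed
  to the RuBP branch.
* The printed qN convention differs from the classical one; comparisons
  across studies must check which is in use.
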