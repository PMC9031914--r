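# leafgasx

Analysis of leaf-level photosynthesis measurements for plant
ecophysiologists working with portable gas-exchange/fluorescence systems
(LI-6800-class instruments): rapid A–Ci response (RACiR) cleaning and
empty-chamber correction, Farquhar–von Caemmerer–Berry (FvCB) curve
fitting, the Laisk construction for the CO₂ compensation point and day
respiration, variable-J mesophyll conductance, light-response and
photorespiration analysis, and chlorophyll-fluorescence quenching
diagnostics including the dark-assessed qPd photoprotection threshold.

Every estimator is validated against a bundled forward simulator with known
ground truth, so the package doubles as a test bench for these methods.

## The models in brief

Net assimilation follows the FvCB model: gross carboxylation is
min(W_c, W_j) with

    W_c = Vcmax·Cc / (Cc + Kc(1 + O/Ko))      (Rubisco-limited)
    W_j = J·Cc / (4Cc + 8Γ*)                  (RuBP-regeneration-limited)
    A   = (1 − Γ*/Cc)·min(W_c, W_j) − Rday,   Cc = Ci − A/gm

with electron transport J(PAR) a non-rectangular hyperbola (initial slope
α, curvature θ, asymptote Jmax). Mesophyll conductance comes from the
variable-J equation

    gm = A_N / ( Ci − Γ*·(ETR + 8(A_N + Rday)) / (ETR − 4(A_N + Rday)) )

and Γ*/Rday from the barycentre of the triangle formed by three low-light
A–Ci regression lines (Laisk). Light responses are fitted with the
four-parameter non-rectangular hyperbola (Φ, Amax, Θ, Rd); photorespiration
is the operational difference A_G − A_N between low-O₂ and normal-air
curves; quenching uses qP = (Fm′−Fs)/(Fm′−Fo′),
qN = (Fm−Fm′)/(Fm−Fo′) (as printed in the emulated protocol),
NPQ = (Fm−Fm′)/Fm′, the Oxborough–Baker calculated Fo′, and
qPd = (Fm′_dark − Fo_actual)/(Fm′_dark − Fo′_calc).

See the methods vignette (`vignettes/leafgasx-methods.Rmd`) for
conventions, defaults, design choices and known limitations — including
the curvature bias of the linear Laisk construction on exact FvCB data and
the systematic biases of the low-O₂ photorespiration difference.

## Worked example

Simulate a RACiR pair with a known instrument artifact, clean and correct
it, and fit the FvCB parameters:

```r
library(leafgasx)

p <- fvcb_params(Vcmax = 60, Jmax = 120)          # ground truth
spec <- sim_spec(noise_sd_A = 0, noise_sd_F = 0)  # noiseless protocol
pair <- simulate_racir_pair(p, spec, artifact = c(0.3, -2e-4))
aci  <- correct_racir(delta_filter(pair$leaf, 0.15),
                      delta_filter(pair$empty, 0.15))
fit_aci_bilinear(aci, constants = p, Rday = 1)
#> Bilinear FvCB A-Ci fit (Ci basis)
#>   Vcmax          =   60.000 umol m-2 s-1
#>   J at PAR 1500  =  109.448 umol m-2 s-1
#>   Jmax asymptote =  120.000 umol m-2 s-1
#>   J at PAR 1261  =  107.265 umol m-2 s-1
#>   Rday used      =    1.000 umol m-2 s-1
#>   transition Ci  =    436.4 umol mol-1 (220 + 231 points), SSE 1.373e-26
```

The artifact (0.3 − 2·10⁻⁴·CO₂_ref) is removed exactly and both truth
parameters are recovered; the transition Ci of ~436 µmol mol⁻¹ is where the
fitted Rubisco and RuBP branches cross. The Laisk construction on the same
leaf:

```r
fit_laisk(simulate_laisk_segments(p))
#> Laisk slope-intersection estimate
#>   Ci* (apparent GammaStar) = 42.750 umol mol-1
#>   Rday                     = 1.0000 umol m-2 s-1
#>   intersection triangle area = 1.893e-29
```

And a qPd protocol with photoinhibition beginning at Icrit = 600:

```r
qs <- compute_qpd_series(simulate_qpd_protocol(fluor_params(Icrit = 600)))
round(qs[, c("par", "qP", "qN", "NPQ", "qPd")], 3)
#>    par    qP    qN   NPQ   qPd
#> 1   60 0.893 0.300 0.321 1.000
#> ...
#> 6  850 0.370 0.765 1.889 0.819
#> 8 1500 0.250 0.803 2.250 0.269
photoprotection_threshold(qs)$threshold
#> [1] 850
```

qPd stays at 1 while NPQ is fully protective and drops at the first
scripted step above Icrit — 850 µmol photons m⁻² s⁻¹ — which is the
detected photoprotection threshold.

`run_pipeline(pipeline_config())` chains all of the above over a simulated
4-variety × 2-treatment layout and returns a tidy per-sample parameter
table plus a JSON-serialisable report bundle.

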