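# eatmotion

Quantitative, noninvasive assessment of **pericardial adhesions** from 4D
(ECG-gated, multi-phase) cardiac CT.

Pericardial adhesions — fibrous fusion of the two pericardial layers —
abolish the normal sliding of the heart inside its sac. They complicate
redo cardiac surgery and epicardial ablation, and static CT signs cannot
reliably detect them. `eatmotion` implements a motion-based detector: the
epicardial adipose tissue (EAT, the fat lying on the heart at −190…−30 HU)
moves with the heart, so the *relative displacement* between each EAT point
and its nearest pericardial point over the cardiac cycle is near zero when
the layers are fused and large when they slide freely.

## Method

For nine cardiac phases (10–90% R-R) registered to the 50% reference phase
with diffeomorphic mappings φ<sub>t</sub>:

* inter-phase displacements **D**(p, t) = P(p, t) − P(p, t−Δt), cyclic at
  the first phase;
* nearest-point pairing q(p, t) = argmin<sub>s∈Ω<sub>peri</sub></sub> ‖p − s‖₂;
* motion disparity **D**<sub>diff</sub>(p, q, t) = **D**<sub>EAT</sub>(p, t) −
  **D**<sub>peri</sub>(q, t), normalized by the study maximum
  D<sub>max</sub> so D̂ ∈ [0, 1];
* a cylindrical region of interest of radius 6 mm around the mid-to-distal
  LAD centerline; per-phase totals M<sub>t</sub> = Σ<sub>ROI</sub> D̂ and
  the optimal phase t\* = argmax M<sub>t</sub> (empirically early systole);
* two histogram statistics of the t\* ROI distribution (100 bins on [0, 1]):
  **peak ratio** PR = H<sub>max</sub>/H<sub>α</sub> (α = 25th-position bin)
  and **distribution width index** DWI = N<sub>nonzero</sub>/N<sub>total</sub>;
* classification: *adhesion* if PR > 100 and DWI < 0.3; *non-adhesion* if
  PR < 50 and DWI > 0.4; otherwise *indeterminate*.

The registration fallback is a self-contained multi-resolution demons with
edge-aware (Perona–Malik) regularization that preserves motion
discontinuities at sliding tissue interfaces; any external diffeomorphic
backend can be plugged in. A synthetic beating-heart phantom with a tunable
EAT–pericardium coupling κ (0 = free sliding, 1 = locked) provides ground
truth for validation.

## Worked example

```r
library(eatmotion)

# a freely sliding (non-adhesion) synthetic study: 9 phases, pericardial
# mask, LAD-like centerline, ground truth included
ph <- generate_phantom(phantom_spec(coupling = 0, rng_seed = 1))
scan <- adhesion_scan(ph$series, ph$peri_mask, ph$centerline)
scan
#> Pericardial adhesion motion-disparity analysis
#>   EAT points: 60403; ROI members at t*: 1404
#>   optimal phase t*: 10% (M_t = 395.0)
#>   peak ratio (PR):               1.25
#>   distribution width index (DWI): 0.470
#>   classification: non-adhesion

# the locked (adhesion) counterpart
ph1 <- generate_phantom(phantom_spec(coupling = 1, rng_seed = 1))
scan1 <- adhesion_scan(ph1$series, ph1$peri_mask, ph1$centerline)
coef(scan1)
#>     PR    DWI
#> 154.00   0.25
scan1$classification
#> [1] "adhesion"
```

The disparity distribution of the sliding heart is broad with a mid-range
peak (low PR, high DWI); locking the fat to the pericardium concentrates it
near zero (high PR, low DWI) — the two published metric regimes. `t* = 10%`
reflects that relative motion peaks at the onset of systole.
`plot(scan, "histogram")`, `plot(scan, "ks")` and `plot(scan, "phases")`
draw the distribution curve, the phase-pairwise Kolmogorov–Smirnov heatmap
and the M<sub>t</sub> profile. Real studies enter through
`read_phase_series()` (NIfTI volumes), `read_mask()` and
`read_centerline()` (JSON/CSV, mm), and distribution-level data through
`adhesion_metrics()` / `cohort_metrics()`. A command-line front end lives
in `inst/cli/eatmotion.R` (subcommands `run`, `simulate`, `metrics`).

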