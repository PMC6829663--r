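# tirfgranule

Quantitative analysis of TIRF (total internal reflection fluorescence)
microscopy recordings of secretory granules — insulin granules in
particular — at the plasma membrane. TIRF excites only the ~100–200 nm
above the coverslip, so a granule becomes visible when it approaches the
membrane ("appears in the evanescent field"), stays visible while docked,
and vanishes abruptly when it fuses. `tirfgranule` automates the standard
measurements built on these signatures, and ships a synthetic movie
generator with full ground truth so every stage can be validated by
parameter recovery.

## What it computes

**Spot detection and granule density.** Diffraction-limited granules are
detected per frame as local maxima with a *prominence* (noise-tolerance)
criterion: a maximum counts only if it rises at least `prominence` above
the highest saddle connecting it to a higher maximum (the semantics of the
ImageJ "find maxima" routine, implemented here by topological persistence
with a union–find sweep). Density is spots per footprint area, with the
footprint from a user mask or an Otsu threshold of the temporal-mean
image (pixel size defaults to 100 nm).

**Docking classification.** Detections are linked into tracks by greedy
nearest-neighbour assignment (closest pair first, gated at `link_radius`,
bridging up to `max_gap` missed frames). A track laterally confined for at
least 2 s (maximum excursion from its median position ≤ `confine_radius`,
default 1.5 px = 150 nm) is an *approach*; it is **docked** if it remains
confined ≥ 25 s and a **visitor** if it leaves before that; anything else
is a *transit*. Stable docking for survival plots is scored 40 s after the
approach. All thresholds are explicit `docking_params()` fields.

**Fusion (exocytosis) detection.** A fusion event is the characteristic
abrupt loss of the granule marker: background-corrected track intensity
drops below half of its pre-event mean within at most 2 frames and does
not recover within the following 5. Cumulative event counts and
single-exponential fits `y(t) = A·exp(−t/τ) + C` (log-linear start,
Levenberg–Marquardt refinement) quantify kinetics.

**Enrichment at the granule site.** For colocalization, 30 × 30 px crops
centred on ≥ 15 marker-positive structures are averaged into a projection;
line profiles are taken along the main diagonal. With the granule width
`N_gr` defined as the FWHM of the marker profile and `min` the profile
minimum, the probe's enrichment is

    E = (AUC_gr − N_gr·min) / (AUC_All − N_All·min)

the fraction of above-background probe signal inside the granule region.
If the probe is independent of the granule, `E` approaches the analytic
null `N_gr / N_All`; `E` is bounded in [0, 1] and invariant to affine
intensity rescaling.

**Footprint traces.** Whole-footprint fluorescence responses (e.g.
pHluorin reporters) are background-corrected and normalised to the
pre-stimulus level (F/F₀), with maximal response and post-stimulus
reuptake τ extracted per cell.

**Reporting.** Per-condition means ± SEM, two-tailed paired/unpaired
t tests, percent change with propagated SEM, OLS trends, and a two-way
ANOVA + Tukey wrapper.

## Worked example

Simulate a docking movie in which half the arriving granules are
long-lived, then recover that share blind from the images:

```r
library(tirfgranule)

cfg <- sim_config(image_shape = c(200, 200), n_frames = 180, snr = 10,
                  background_level = 100, frame_interval = 1, seed = 11)
res <- residence_model(n_arrivals = 40, p_dock = 0.5)
sim <- simulate_movie(cfg, res)

spots  <- detect_movie(sim$movie)
tracks <- link_tracks(spots, docking_params(), frame_interval = 1)
events <- classify_all(tracks)
fr     <- docking_fraction(events, tracks)

table(events$class)
#>  docked transit visitor
#>      18       1      20
fr
#> approaches 38, stable at 40 s 18, fraction 0.47
mean(sim$ground_truth$spots$kind == "docked")
#> 0.45
```

The measured stable-docking fraction (0.47) recovers the generator's
long-lived share (0.45 in this draw). Enrichment works the same way —
simulate crop pairs with a known bound fraction and score them:

```r
cr <- simulate_crop_pair(20, bound_fraction = 0.7, seed = 5)
r  <- enrichment_analysis(cr$channel1, cr$channel2)
#> E = 0.695, null = 0.082, excess = 0.613
```

A YAML-driven pipeline wraps the same stages for file-based runs
(`run_pipeline("simulate" | "detect" | "dock" | "fuse" | "enrich" |
"trace" | "report", config)`; thin CLI at `inst/cli/tirfgranule.R`;
demo config at `inst/extdata/demo_config.yaml`). Every stage writes a
JSON manifest with the full parameter set and seed.

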