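# depotmap

Spatially resolved structural analysis of lipid liquid-crystalline
depots — injectable soybean phosphatidylcholine / glycerol dioleate
(SPC/GDO) mixtures that hydrate in buffer into a layered body with a
reverse hexagonal (H2) rim and a reverse micellar cubic (Fd3m)
interior. The package is for formulation and biophysics researchers who
map such depots with scanning small-angle X-ray scattering (SAXS) and
Raman microscopy and want a tested, scriptable pipeline from 1D curves
and spectra to phase maps, composition profiles and transport
simulations.

## What it computes

**SAXS indexing and phase mapping.** Bragg peaks are detected in
baseline-subtracted 1D powder patterns and indexed against reflection
ladders (Fd3m `sqrt((3,8,11,12,16,19,24,27)/3)`, Pm3n
`sqrt((2,4,5,6,8,10)/2)`, H2 `1:sqrt(3):2:sqrt(7)`, lamellar `1:2:3`).
The Fd3m lattice parameter follows from the (111) position,
`a = 2*pi*sqrt(3)/q111`, selected in the window 0.058–0.085 1/Å. Per
pixel, the scattering invariant `Q = \int q^2 I(q) dq` masks depot
against buffer, and the cubic-phase fraction is the invariant-normalised
(111) share of the Bragg signal, rescaled so a pure-Fd3m pattern reads
1. Maps, azimuthally averaged radial profiles and layer segmentation
follow.

**Raman band ratios.** Pseudo-Voigt bands are fitted around library
centres; the height ratios 1264/1301 (composition: 0.95 for pure SPC,
0.56 for pure GDO) and 715/1301 (SPC choline band, hydration-sensitive:
0.61→0.68 over 0–40 % water for the 50/50 mixture) are inverted into
SPC fraction and water content. Difference spectra between depot
positions are built after normalising to the 1439 1/cm internal
standard.

**Generalized-Fick transport.** Water uptake and two-lipid
redistribution in a 1D radial depot follow
`J_i = -(D_i/RT) C_i dmu_i/dx` with regular-solution chemical
potentials anchored at the 16 wt% hydration limit of the 50/50 mixture
(reservoir water activity 0.996). With `D_water = 1e-11` and
`D_lipid = 1e-13` m²/s, the model reproduces rim SPC enrichment, an
interior SPC minimum 2–3 mm from the centre, uphill lipid diffusion,
and composition gradients that persist for weeks because lipid
redistribution — not water transport — is rate-limiting.

**Synthetic data.** Every stage is driven and validated by a generator
with exact ground truth: multi-phase powder patterns, radially layered
raster scans (1-day, 1-week, 4-week depot scenarios), and Raman spectra
pinned to the calibration anchors.

## Worked example

```r
library(depotmap)

# a two-phase pattern: Fd3m at 165 A plus an H2 at 60 A
curve <- generate_curve(tibble::tibble(phase = c("Fd3m", "H2"),
                                       lattice_a = c(165, 60),
                                       weight = c(1, 0.6)))
sub   <- subtract_baseline(curve)
peaks <- detect_peaks(sub)
index_phases(peaks)$assignments
#>   phase lattice_a n_matched     residual
#> 1  Fd3m  164.9888         5 9.587129e-05
#> 2    H2   59.9945         4 4.648157e-05
as.numeric(cubic_fraction(sub, peaks = peaks))
#> [1] 0.326
```

Both phases are recovered with lattice parameters within 0.01 % of the
generated truth; the cubic fraction says about a third of the Bragg
invariant comes from the Fd3m phase.

```r
sp <- generate_raman(spc_fraction = 0.5, water_fraction = 0.2)
r  <- intensity_ratios(fit_bands(sp))
r
#>     r715  r1264
#> 1 0.6455  0.755
estimate_hydration(r$r715, estimate_composition(r$r1264))
#> [1] 0.203
```

The fitted 1264/1301 ratio of 0.755 sits midway between the GDO (0.56)
and SPC (0.95) endmembers, giving a 50:50 composition, and the 715/1301
ratio of 0.6455 inverts to 20 % water — both matching the generated
ground truth.

A full raster → map → profile → layers run (plus the Raman chain) is one
call:

```r
out <- run_pipeline(list(scenario = "one_day", pixel_pitch_mm = 0.25,
                         outdir = "run1", seed = 1))
out$layers   # cubic-free core / cubic annulus / cubic-free rim
autoplot(out$map)
```

See the vignette (`vignettes/depot-mapping-methods.Rmd`) for the models,
conventions and their rationale.

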