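---
title: "Mapping mesophases and lipid redistribution in SPC/GDO depots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mesophases and lipid redistribution in SPC/GDO depots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depotmap)
library(dplyr)
```

## The system and the questions

Injectable mixtures of soybean phosphatidylcholine (SPC) and glycerol
dioleate (GDO) form a macroscopic depot on contact with aqueous medium.
The anhydrous mixture is an isotropic reverse micellar liquid (L2); as
water diffuses in, ordered lyotropic mesophases appear — a reverse
hexagonal (H2) shell at the rim and a reverse micellar cubic phase of
space group Fd3m in the interior, with the micellar cubic Pm3n phase
possible at low hydration and SPC-rich compositions. Because drug
release rates differ strongly between these geometries, three questions
matter for such depots:

1. *Which phase is where?* — answered by indexing Bragg peaks in
   spatially resolved small-angle X-ray scattering (SAXS) curves.
2. *How much cubic phase, and how swollen?* — answered by an
   invariant-normalised cubic-phase fraction and the Fd3m lattice
   parameter per pixel.
3. *Why do gradients persist for weeks?* — answered by a transport model
   in which diffusion follows chemical-potential gradients (generalized
   Fick's law), so the slow redistribution of the two lipids, not water
   motion, limits equilibration.

The package implements all three layers plus a synthetic-data generator
with exact ground truth, so every analysis stage is validated against
known inputs.

## Powder-pattern model and indexing

For a cubic phase, allowed reflections sit at
$q_{hkl} = 2\pi\sqrt{h^2+k^2+l^2}/a$. The library ladders are, relative
to the first reflection: Fd3m $\sqrt{(3,8,11,12,16,19,24,27)/3}$, Pm3n
$\sqrt{(2,4,5,6,8,10)/2}$, H2 $1,\sqrt3,2,\sqrt7$ with
$a = 4\pi/(\sqrt3\,q_{10})$, and lamellar $1,2,3$. The Fd3m lattice
parameter is computed from the (111) position, $a = 2\pi\sqrt3/q_{111}$,
with the (111) selected as the strongest peak in the window
$[0.058, 0.085]\ \text{Å}^{-1}$ (endpoints inclusive): at $a = 172$ Å
the (111) sits at $q = 0.063\ \text{Å}^{-1}$, at $a = 131$ Å at
$0.083\ \text{Å}^{-1}$, so the window covers the full swelling range.

Indexing is a greedy best-first search over (phase, anchor-peak)
hypotheses: each hypothesis predicts its ratio ladder and counts
observed peaks within a relative tolerance (default 1.5 %, comfortably
above the $\sim$0.8 % resolution of the default q-grid). Hypotheses are
ranked by number of matches, then mean relative residual, then *ladder
completeness* — the fraction of predicted in-range reflections actually
observed. The completeness rule is load-bearing: the H2 ladder
$\{1,\sqrt3,2\}$ is a strict subset of the Pm3n ladder, so a
three-reflection hexagonal pattern ties with a partial Pm3n match on
counts and residuals alone; demanding completeness resolves the tie in
favour of the phase that explains its whole predicted ladder. A
coexisting Fd3m is assigned before H2 whenever a (111) candidate lies in
the window, since the Fd3m (220) can overlap the H2 (10). An empty peak
list classifies the pixel as isotropic; this is a fallback label, not a
fit.

## Baseline, peaks and the phase-fraction statistic

The diffuse background of each 1D curve is estimated by asymmetric
least-squares (Whittaker) smoothing. Because the background is close to
a power law over a wide q-range while Bragg peaks are a few grid steps
wide, the smoother operates on a uniform grid in $\log q$ with
$\log I$ values, where the background is nearly linear; the asymmetry
weight ($p = 10^{-3}$) keeps the estimate on the lower envelope so
peaks survive subtraction (height loss below 5 % on synthetic tests; on
background-only curves the residual stays below 1 %). The roughness
penalty default ($\lambda = 10^5$ in log-log coordinates) was chosen on
synthetic curves as the stiffest setting that still tracks the
power-law-plus-constant background to better than 1 %.

Peak detection finds local maxima exceeding both a relative prominence
threshold (5 % of the curve maximum) and a robust noise floor (5 times
a MAD-based noise estimate from second differences), then refines
positions sub-grid with a three-point quadratic fit.

The per-pixel mass proxy is the scattering invariant
$Q = \int q^2 I(q)\,dq$ over the measured range, which is independent of
structure and proportional to the scattering volume; raster pixels are
masked as in-depot when their invariant exceeds five times the buffer
level, estimated from the outermost pixel ring of the scan. The
cubic-phase fraction is the (111) share of the Bragg invariant,
normalised to phase share:

* numerator — $\int q^2 I_{\text{cub}}\,dq$ over the (111) peak region
  (three FWHM to either side of the selected peak), after removing a
  local linear pedestal. Integrating the peak region rather than the
  literal search window avoids truncating a (111) that sits near the
  window edge, as it does at $a \approx 131$ Å.
* denominator — $\int q^2 I\,dq$ over all detected-peak regions of the
  baseline-subtracted curve (restricting to peak regions keeps residual
  baseline error from diluting the ratio).
* normalisation — the measured (111) share is divided by the analytic
  (111) share of a pure-Fd3m pattern at the recovered lattice parameter
  under the package's relative-intensity convention, so a single-phase
  Fd3m curve reads exactly 1 and a mixture reads the Fd3m share of the
  Bragg invariant. The true normalisation used with the beamline data
  lives in unpublished supplementary equations; this convention is an
  explicit, testable stand-in and is flagged as such here.

Radial profiles average fraction and lattice in annuli one pixel-pitch
wide around the mask centroid, and layer segmentation thresholds the
profile (default 0.2) and merges contiguous runs. The threshold only
needs to separate "cubic present" from "cubic absent" annuli; any value
between roughly 0.1 and 0.6 gives the same layer counts on the bundled
scenarios.

## Raman band model

Band "intensity" is fitted peak *height*, not area — the package's
convention, applied consistently between generator and analysis. Bands
are pseudo-Voigt (shared implementation with the SAXS peaks); fitting
groups target centres into overlapping clusters (gap < 70 cm$^{-1}$),
fits each cluster with a linear local baseline by bounded
Levenberg–Marquardt (centres constrained within ±8 cm$^{-1}$ of their
library targets), and falls back to flagged window-maximum heights on
non-convergence.

Two ratios against the 1301 cm$^{-1}$ CH$_2$ twist (present in both
lipids) carry the information: 1264/1301 tracks composition (the
=C–H deformation scales with the higher C=C count of SPC; endmembers
0.95 for SPC, 0.56 for GDO) and 715/1301 tracks the SPC choline group
and its hydration (0.61 dry to 0.68 at 40 % water for the 50/50
mixture). Composition estimation inverts a weighted two-endmember
mixing model; the relative 1301 weights of the two lipids default to
1:1 and are exposed as calibration, because measured mixtures can sit
off the equal-weight line (an anhydrous 50/50 mixture reading 0.81
would imply unequal weights that cannot be derived from endmember data
alone). Hydration estimation inverts the 50/50 calibration after
rescaling the observed ratio by SPC content; away from 50/50 the result
carries an extrapolation flag since no calibration surface across
composition is available. Difference spectra normalise both spectra to
their fitted 1439 cm$^{-1}$ CH$_2$-scissoring height — a
composition-insensitive internal standard — before subtraction. The
residual-ethanol band near 884 cm$^{-1}$ seen in hours-old depots is
deliberately excluded from the band library.

## Transport model

The generalized Fick's law
$J_i = -\frac{D_i}{RT} C_i \frac{d\mu_i}{dx}$ is closed with a ternary
regular-solution (Flory–Huggins-like, unit segment sizes) free energy —
the simplest model with the required qualitative structure, since no
quantitative $\mu_i(\text{composition})$ is available for this system.
Water interacts more strongly with SPC than with GDO
($\chi_{wS} < \chi_{wG}$, default contrast 1 in units of RT); the sum
$\chi_{wS} + \chi_{wG}$ is calibrated so the 50/50 mixture equilibrates
with the reservoir (water activity 0.996, the physiological value for
subcutaneous tissue) at its 16 wt% hydration limit. Defaults
$D_w = 10^{-11}$, $D_{\text{lipid}} = 10^{-13}$ m$^2$/s are the
order-of-magnitude estimates for water transport in the depot and lipid
self-diffusion in reverse micellar cubic phases.

Numerics: 1D spherical finite volumes (radius 4 mm, slab geometry
available for benchmarks), explicit stepping at a 0.25 safety factor on
the diffusive stability bound, fluxes on faces with *log-mean* face
compositions — chosen so the discrete flux reduces exactly to a
central-difference classical Fick flux in the ideal limit
($\chi = 0$), which is what makes the erf-benchmark agreement a test of
the implementation rather than of an interpolation choice. The state
per node is species mass per reference volume on a fixed grid; reported
fractions are normalised per node. Lipid mass is conserved to machine
precision (zero lipid flux through both boundaries); water enters only
through the outer face, where its chemical potential is pinned to the
reservoir value. Fixed-grid densification stands in for macroscopic
swelling — there is no moving boundary, which is the model's main
geometric simplification. Phase labels along a trajectory come from a
simple composition lookup (dry → L2; SPC-rich hydrated → H2; GDO-rich
hydrated → Fd3m, Pm3n at low hydration) mimicking the published phase
diagram's topology; they are a reading aid, not thermodynamics.

Behaviourally the model reproduces the claims it was built to probe:
water influx lowers $\mu_{SPC}$ near the rim, driving SPC outward
(maximum at the rim, transient minimum that passes through 2–3 mm from
the centre during the first two weeks); an imprinted SPC gradient at
full hydration relaxes ~1000× further in two weeks when
$D_{\text{lipid}} = D_w$ than at the default slow-lipid value, which is
the package's quantitative reading of "lipid redistribution is the
rate-limiting step"; and a two-region state with flat SPC concentration
but contrasting hydration produces nonzero SPC flux — uphill diffusion,
impossible under the classical concentration-gradient law.

## The synthetic-data generator

The generator is the package's test bed and defines its study
conditions:

* *Curves*: smooth background $b q^{-p} + c$ (default $p = 2$; the
  exponent and amplitudes are conventions chosen so the invariant is
  finite on the truncated range and the first Bragg peak rises well
  above background) plus one pseudo-Voigt per allowed reflection
  (default FWHM 0.0025 Å$^{-1}$, Lorentzian fraction 0.5), with
  relative reflection intensities decaying geometrically (factor 0.5) —
  real structure factors are unknown, and the decay keeps the first
  reflection dominant as observed. Optional Poisson noise under a fixed
  seed; same seed, same bytes. The default q-grid (0.016–0.85
  Å$^{-1}$, step $5\times10^{-4}$) resolves the default peak width with
  five points per FWHM, and the generator rejects grids that do not.
* *Rasters*: concentric sharp layers (phase, outer radius, Bragg
  weight) with linear within-layer lattice gradients; pixels outside
  the depot carry only a weak buffer background, which is what the
  invariant mask keys on. Bundled scenarios encode the depot states at
  1 day (isotropic core 0–2.2 mm, Fd3m annulus to 3.2 mm in the
  early-hydration lattice range 131–145 Å, H2 rim to 4 mm), 1 week
  (cubic interior, rim thickness increasing with SPC content, a Pm3n
  core at 56:44), and 4 weeks (Fd3m core with lattice 157→172 Å centre
  to edge, H2 rim).
* *Raman spectra*: the band library's centres and assignments with
  heights pinned so the marker ratios equal the calibration anchors
  exactly, minor-band heights weighted by composition, a polynomial
  baseline capped at 5 % of the tallest band, optional Gaussian noise.

What the generator does *not* emulate — instrument smearing, absolute
intensities, detector artefacts, inter-phase peak interference beyond
simple superposition, hydrolysis chemistry — bounds what green tests
mean: they validate the analysis logic under the stated forward model,
not performance on beamline data.

## Problem sizes and runtime choices

Tests and examples run rasters at 0.25–0.5 mm pitch (a few hundred to
~1400 pixels) rather than the 50 µm of the experiment; per-pixel cost
is ~30 ms, dominated by the sparse baseline solve, and the analysis is
pitch-agnostic. Transport runs use 40 radial nodes (0.1 mm), for which
the stability-limited step is 250 s and a 4-week horizon is ~10⁴
steps. The erf benchmark uses 100 slab nodes and a short horizon so the
diffusion front stays clear of both walls.

## Known limitations

* The phase-fraction normalisation is a package convention (see above),
  so absolute fractions are comparable within this pipeline, not across
  instruments.
* The isotropic phase shows no Bragg peaks and is never quantified —
  only inferred from the absence of cubic signal inside the mask.
* Hydration estimates away from 50/50 composition extrapolate a
  single-composition calibration and are flagged accordingly.
* The transport model's quantitative outputs depend on the assumed
  free-energy form; only its analytic limits and qualitative depot
  phenomenology are validated.
* No 2D detector simulation or azimuthal integration: the pipeline
  starts from 1D curves.

## A short worked chain

```{r chain}
curve <- generate_curve(tibble::tibble(phase = "Fd3m", lattice_a = 165,
                                       weight = 1))
sub <- subtract_baseline(curve)
peaks <- detect_peaks(sub)
index_phases(peaks)$assignments |> dplyr::select(phase, lattice_a, n_matched)
as.numeric(cubic_fraction(sub, peaks = peaks))
```

```{r raman}
sp <- generate_raman(spc_fraction = 0.5, water_fraction = 0.2)
r <- intensity_ratios(fit_bands(sp))
r
estimate_hydration(r$r715, estimate_composition(r$r1264))
```
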