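---
title: "Group-level kernel-driven BRDF correction: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level kernel-driven BRDF correction: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brdfcorr)
```

## The problem

Airborne imaging spectrometers acquire a target area as several long,
narrow, overlapping flightlines, often spread over several hours of a day.
Surface reflectance then varies with the sun-sensor-target geometry — the
bidirectional reflectance distribution function (BRDF) — in two visible
ways: a cross-track brightness gradient within each line (the sensor sweeps
its view zenith across track, typically ±17-18°), and brightness offsets
*between* lines acquired under different solar zenith angles. Correcting
each line to nadir view in isolation removes the first effect but not the
second; mosaics and maps derived from per-line corrections keep seams at
line boundaries.

`brdfcorr` fits a single kernel-driven BRDF model to an entire flight box
(a *group* of lines), stratified continuously by NDVI, and standardizes
every pixel to nadir view at one *reference solar zenith angle* shared by
the whole group.

## The model

Per band, modeled reflectance is a linear combination of an isotropic
term and two analytic kernels,

$$\rho(\theta_v, \theta_s, \phi) = f_{iso} + f_{geo}\,
K_{geo}(\theta_v, \theta_s, \phi) + f_{vol}\,
K_{vol}(\theta_v, \theta_s, \phi),$$

where $\theta_v$, $\theta_s$ are view and solar zenith angles and $\phi$
the relative azimuth. $K_{geo}$ is a Li crown-shadowing kernel (sparse by
default; dense selectable) built on shape-adjusted angles
$\theta' = \arctan\!\big(\tfrac{b}{r}\tan\theta\big)$ with crown ratios
$b/r = 10$ and $h/b = 2$; $K_{vol}$ is a Ross leaf-facet scattering kernel
(thick by default; thin selectable) in the phase angle $\xi$ of the
*unprimed* geometry. The Li-Sparse form used here is the non-reciprocal
variant, whose interception term carries $\sec\theta_v'$ only. $\cos t$
inside the overlap term is clamped to $[-1, 1]$, the standard guard for
grazing geometries. Both kernels vanish at $\theta_v = \theta_s = 0$ and
are even in $\phi$, and at nadir view they are independent of azimuth —
which is what makes the "arbitrary" azimuth $\phi_n$ of the corrected
geometry truly arbitrary (the test suite verifies invariance to $\phi_n$
at the $10^{-12}$ level).

The correction multiplies the (topographically corrected) observed
reflectance by the ratio of modeled nadir reflectance at the reference
solar zenith $\theta_{sr}$ to modeled reflectance at the observed
geometry:

$$R_{out} = R_t\,
\frac{\rho(0, \theta_{sr}, \phi_n)}{\rho(\theta_v, \theta_s, \phi)}.$$

With no reference angle ($\theta_{sr}$ unset), each pixel keeps its own
solar zenith and only the view geometry is normalized — the per-line
correction this package exists to improve on.

## Topographic pre-correction

On sloped terrain the sun-canopy-sensor + C correction is applied per
flightline before any BRDF fitting:
$R_t = R\,(\cos\alpha\cos\theta_s + C)/(\cos i + C)$ with the
illumination factor
$\cos i = \cos\alpha\cos\theta_s + \sin\alpha\sin\theta_s\cos\phi_t$.
$C = a/b$ comes from a per-band ordinary least-squares fit
$R = a + b\cos i$ over a seeded random sample of valid, vegetated pixels
(NDVI ≥ 0.05; 1,000 pixels minimum, capped at 50,000 — OLS on two
parameters gains nothing from more). Restricting the fit population to the
BRDF-eligible vegetated pixels keeps $C$ vegetation-driven; the sun-terrain
azimuth $\phi_t$ is the azimuth difference folded into $[0°, 180°]$. Bands
whose slope magnitude $|b|$ falls below $10^{-6}$ reflectance units are
flagged degenerate and pass through unchanged — a band the linear model
cannot explain is never made worse. On flat terrain the correction factor
is identically 1, exactly, for any $C$.

## NDVI stratification and smoothing

The kernel weights $(f_{iso}, f_{geo}, f_{vol})$ describe canopy
structure, so they are fitted separately per NDVI stratum,
$\mathrm{NDVI} = (R_{850} - R_{665})/(R_{850} + R_{665})$, using the band
nearest each target wavelength (within 20 nm). Pixels with NDVI < 0.05
(water, bare surfaces, anomalies) are masked from fitting and retain
their input reflectance in corrected output.

Two binning modes are available. *Static* bins split $[0.05, 1]$ into
equal widths; *dynamic* bins (the default, 18 bins) place edges at
equal-count quantiles of the pooled group NDVI restricted to
$(0.05, 0.9)$, the last bin extended to 1 — robust when a site's NDVI
occupies a narrow range. Sampling is stratified *across the pooled group*:
up to `per_bin` pixels (default 10,000) per bin drawn uniformly from all
lines together, so each line contributes in proportion to its eligible
area and the fit sees the full range of illumination in the box. Each
band-bin cell is then an ordinary least-squares fit of reflectance on
$[1, K_{geo}, K_{vol}]$; bins with fewer than 3 samples or a
rank-deficient design are flagged and covered by smoothing (or by the
nearest fitted bin when smoothing is off).

Constant per-bin coefficients create visible seams at bin boundaries.
Three smoothing modes remove them: linear interpolation in the bin-center
NDVI (the recommended default — continuous by construction and
shape-preserving), and unweighted or bin-count-weighted linear regression
of each coefficient on bin center. Smoothing operates on bins whose
centers lie in $[0.25, 0.85]$; outside that interval the smoothed curve
is extended as a constant, which avoids extrapolating the correction into
the extreme-NDVI ranges where it is least trustworthy while keeping the
coefficient curves continuous everywhere. (Letting extreme bins keep
their raw constants instead would reintroduce jumps at 0.25 and 0.85;
continuity was preferred.) Smoothing knots are bin-edge midpoints for
static bins and per-bin member medians for dynamic bins.

## Reference solar zenith

Five choices of $\theta_{sr}$ are implemented, plus `none`:

| mode | meaning | typical use |
|---|---|---|
| `observed_mean` | pooled mean observed $\theta_s$ over all valid pixels of the group | recommended default for one-day boxes |
| `flight_noon` | solar-noon zenith on the acquisition date | simple baseline |
| `season_noon` | mean of daily solar-noon zeniths over a season window | integrating boxes across dates |
| `solstice_noon` | solar-noon zenith on the summer solstice | extreme-illumination baseline |
| `fixed` | user-supplied angle | reproducing a published setup |

Solar positions use the Spencer fractional-year declination series
(declination accurate to roughly 0.1°, ample here); at solar noon the
zenith reduces to |latitude − declination|. The latitude should be the
mean of the flightline center latitudes. The pooled observed mean weights
every valid pixel equally, so larger lines carry more weight — with
equal-sized, fully valid lines it equals the mean of per-line solar
zeniths.

## What the synthetic flight box emulates — and what it does not

`synth_spec()`/`generate_group()` forward-model a group of overlapping
lines from known truth so every stage is testable without any sensor
download. Defaults: 3 lines of 60 × 80 pixels at 15 m, 30% column overlap
on a shared world grid, a ±17.5° cross-track view-zenith sweep with the
relative azimuth flipping 180° across nadir (whiskbroom geometry),
per-line solar zeniths evenly spaced over 25-45° with azimuths 120-240°
(a morning-to-afternoon acquisition), and a 10-band grid (the standard
assessment wavelengths, bracketing the NDVI bands). A smooth spatial NDVI
field spanning 0.06-0.99 drives per-band truth coefficients built from
soil and vegetation endmember spectra; the two NDVI-defining bands encode
the field exactly ($f_{iso,660} \propto 1-n$, $f_{iso,850} \propto 1+n$)
and share their kernel-weight ratios, which makes the computed NDVI of
the synthetic cube exactly equal to the intended field regardless of
geometry (the BRDF factors cancel in the ratio). Kernel-weight ratios are
$f_{vol}/f_{iso} = 0.3$-$0.7$ and $f_{geo}/f_{iso} = 0.015$-$0.03$ — with
$b/r = 10$ the Li kernel reaches magnitudes near 10, so percent-level
geometric weights produce the realistic 10-20% cross-track brightness
swings while keeping reflectance positive everywhere.

`truth = "binned"` quantizes the NDVI field to bin centers and makes the
truth piecewise-constant per bin, so per-bin least squares can recover it
to machine precision on noiseless data; `truth = "smooth"` keeps the
coefficients continuous in NDVI for smoothing and interpolation tests.
Terrain is flat or sinusoidal hills; on hills the reflectance is
modulated by the *inverse* of the topographic correction with per-band
truth $C$ factors. Noise is additive Gaussian.

Deliberately not emulated: atmospheric residuals, sensor noise structure
beyond i.i.d. Gaussian, co-registration error (synthetic lines are exact
to the grid; real overlaps need pre-registration), adjacency effects, and
any radiative-transfer realism in the coefficient spectra. Passing tests
on these scenes demonstrates the correctness of the estimation and
application machinery and the internal consistency of the method — not
that any particular real site will improve by a given amount.

## Numerical choices and degenerate inputs

* Angles are degrees at every I/O boundary and converted to radians once
  on entry to kernel and correction code.
* $\cos t$, $\cos\xi$ and $D^2$ are clamped before `acos`/`sqrt`.
* The correction divides by modeled reflectance; pixels with
  $|\rho| < 10^{-6}$ are masked and counted rather than corrected, as are
  topographic pixels with $|\cos i + C| < 10^{-8}$.
* Bin assignment uses half-open intervals with the top bin closed at 1;
  NDVI below the mask threshold is a caller error in
  `coefficients_at_ndvi()` (the correction routine masks such pixels
  itself).
* The model sidecar serializes doubles at 17 significant digits, so a
  reread model reproduces corrections bit-identically; no output carries
  a timestamp, so a fixed config and seed give byte-identical sidecars
  and reports.
* All randomness (topographic fit sample, stratified sample, synthetic
  noise) flows from explicit integer seeds.

## Known limitations

* **NDVI stratification under noise.** NDVI computed from noisy bands
  blurs bin assignment: with noise σ = 0.01 the NDVI standard error
  (~0.03) is comparable to an 18-bin half-width, so samples near bin
  edges mix neighboring strata. Bin-mean coefficients remain well defined
  but are no longer the mid-bin truth to within the OLS covariance;
  parameter-recovery guarantees in the tests are therefore stated for
  stratification on the true field, and real-data users should treat
  per-bin coefficients as bin averages, not point values.
* **Empirical C-factor bias.** The SCS+C fit regresses reflectance that
  also varies with canopy and view geometry on $\cos i$; on strongly
  structured scenes the recovered $C$ is a best linear compromise, not
  the generative constant, so topographic correction is only exact when
  the terrain-reflectance relationship is genuinely linear.
* **Same-day grouping is the caller's responsibility.** Nothing prevents
  grouping lines from different dates; the reference-zenith machinery
  mitigates but does not remove illumination differences.
* **Problem sizes.** The shipped tests and examples run on scenes from
  40 × 60 up to 3 × 350 × 350 pixels and 10 bands — sizes chosen so the
  whole suite executes in well under a minute while still exercising
  10,000-sample-per-bin fits across 18 bins; the code paths are the same
  at full 224-band flightline scale, only larger.

## Worked example

```{r example, eval = FALSE}
spec <- synth_spec(seed = 7)              # 3 overlapping lines, defaults
grp <- generate_group(spec)

model <- brdf_fit(grp$lines,
                  bins = ndvi_bins("static", 18),
                  smoothing = "linear_interpolation",
                  per_bin = 2000, seed = 7, topo = FALSE,
                  solar_ref = solar_reference("observed_mean"))
print(model)
plot(model)                                # coefficients vs NDVI

corrected <- lapply(grp$lines, function(ln)
  apply_brdf_correction(ln$cube, ln$obs, model))

before <- assess_group(lapply(grp$lines, `[[`, "cube"))
after  <- assess_group(corrected)
mean(before$group_mean$mad); mean(after$group_mean$mad)
```

The same workflow driven by a config file: `run_synth()` writes a box and
a ready config; `run_fit()`, `run_apply()`, `run_assess()` (or the
`inst/cli/brdfcorr.R` wrapper with subcommands `synth`, `fit`, `apply`,
`assess`, `correct`) execute the estimation and application workflows and
emit the model sidecar, corrected cubes, reports, and a run manifest.
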