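---
title: "Estimating the upper OMZ limit from epipelagic backscatter: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the upper OMZ limit from epipelagic backscatter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Where an oxygen minimum zone (OMZ) is shallow, the epipelagic community —
zooplankton, gelatinous organisms, small pelagic fish — is confined to the
oxygenated surface layer, and the water just below the lower oxycline is
nearly free of organisms. The acoustic backscatter column of one ping is
therefore, to good approximation, a measure concentrated above the
oxycline, and its 98th cumulative percentile depth (`Z_VEEC`) is a robust
estimator of the upper OMZ limit. The package treats the problem as
estimation of that percentile from bi-frequency volume backscattering
strength (Sv, dB re 1 m^-1), with three nuisance processes handled
explicitly: range-dependent background noise, strong but sparse fish
echoes, and the diel vertical migration of mesopelagic organisms.

Assumptions worth stating:

* the community is intolerant of the OMZ core, so the backscatter column
  effectively ends at the lower oxycline (organisms adapted to hypoxia and
  daytime mesopelagic residents inside the OMZ are assumed weak or absent
  at 120 kHz within the analysed depth range);
* backscatter is additive in the linear domain (`sv = 10^(Sv/10)`), the
  standard echo-integration assumption;
* twilight pings cannot be interpreted (migrators are crossing the
  boundary) and are removed rather than modelled.

## Pipeline and parameters

| parameter | default | units | role |
|---|---|---|---|
| noise `alpha` | 0.0098 (38 kHz), 0.0267 (120 kHz) | dB m^-1 | absorption in `N(R) = 20 log10 R + 2 alpha R + offset` |
| noise `offset` | -145, -140 | dB | assumed noise at 1 m range |
| cell height | 0.75 | m | elementary cell after resampling (1 ping long) |
| sum threshold | -135 | dB | fish extraction on `Sv38 + Sv120` |
| diff threshold | +2 | dB | fish refinement on `Sv120 - Sv38` |
| fish weight | 1e-3 | — | down-weighting of fish echoes in the cumulation |
| threshold | 0.98 | fraction | cumulative-echo crossing |
| min pings / radius | 300 / 5 | — / km | station matching |
| DO isovalue | 0.8 | mL L^-1 | proxy depth `Z_0.8` |
| OMZ criteria | 0.5 / -0.02 | mL L^-1, mL L^-1 m^-1 | bottom-oxycline definition |
| transducer depth | 3.4 | m | added once, at echogram construction |
| twilight bands | 0 / -12 | degrees | solar-elevation limits of day/night |

Notes on the less obvious choices.

**Cumulation domain.** Percentiles of a cumulated sum are only
measure-like in the linear domain, so the cumulative profile is built on
`sv`, not on dB values; the dB-domain is used only where contrast
enhancement is the point (the `Sv38 + Sv120 > -135 dB` fish threshold,
which would be meaningless for a linear sum of two ~-70 dB channels).

**Channel assignment.** The "other" channel of the weighted column is the
120 kHz no-fish Sv (zooplankton backscatters more strongly at 120 kHz);
the "fish" channel is the 38 kHz fish Sv (near swimbladder resonance).
Both are arguments of `zveec_series()`; on school-free scenes the 120 kHz
channel alone reproduces the combined estimate within one cell, which is
also verified by a test.

**Strict inequalities.** A cell exactly at the -135 dB sum or at +2 dB
difference is *not* fish; boundary cases follow the rule as written
("above threshold", "< +2 dB").

**Twilight definition.** Day/night/twilight are computed from solar
elevation (NOAA low-precision ephemeris; no refraction) with configurable
bands, 0° and -12° by default. The method text this package follows never
defines "twilight" numerically; the nautical-twilight band is the
package's own choice.

**Gradient criterion units.** The bottom-oxycline gradient criterion is
-0.9 µmol kg^-1 m^-1, which converts (nominal density 1.025 kg L^-1,
O2 molar volume 22.392 L mol^-1) to -0.0207 ≈ -0.02 mL L^-1 m^-1. A
commonly seen variant prints -0.2 mL L^-1 m^-1; that value is
inconsistent with the µmol-based criterion it cites and is not used here.
"Weaker than" is implemented as gradient ≤ criterion (more negative);
the opposite reading would make "the deepest such level" the profile
bottom for every profile.

**Station matching.** Great-circle distances on a spherical Earth
(R = 6371 km), adequate at the 5 km matching scale. The mean uses the
`min_pings` closest valid pings; ordering ties are broken by ping index,
and the result is invariant to ping ordering and to duplicates beyond the
closest set (tested). A per-station `exact_z` input reproduces the
"probe track visible on the echogram" mode; detecting the track by image
processing is out of scope.

**Gridding and volume.** Boundary maps use linear interpolation on a
Delaunay triangulation (`interp`), invalid outside the convex hull; the
mapping method behind published boundary maps is not specified, and
kriging is deliberately out of scope to keep the statistical surface
testable. Habitat volume sums `z × cell area` over masked cells with
spherical cell areas; cells straddling the mask boundary contribute their
fractional area, estimated on a 4×4 subgrid (the error this introduces is
bounded by the refinement-convergence and Monte-Carlo tests at ≤1%).
Bathymetry clipping is available but off by default — whether shallow
cells should be clipped is survey-specific.

**Wavelet analysis.** The Morlet CWT (ω0 = 6) is implemented in the
Fourier domain with `sqrt(2π s/dx)` normalisation, zero-padding to at
least twice the series length so the transform equals a linear
convolution (verified against direct convolution to ~1e-9 relative).
Scales are dyadic with δj = 0.125 from s0 = 2 dx; the adjusted spectrum
is `|W|²/s`; the cone of influence is the edge distance divided by √2
(the e-folding distance of the Morlet atom). Series are resampled to
uniform 100 m spacing and demeaned (detrending by flag). The
red-noise significance test is the conventional AR(1)/χ²(2) comparison at
each scale's equivalent Fourier wavelength; the underlying survey method
does not describe its significance test, so this is a documented package
choice, calibrated by simulation to its nominal level (±2%).

## What the synthetic generator emulates

`scene_spec()`/`generate_scene()` render a coastal survey with known
ground truth: an oxycline field Z*(x) (large-scale trend 20–120 m plus
mesoscale/submesoscale sinusoids, optional Gaussian filament), a
zooplankton layer above Z* at -85/-75 dB (38/120 kHz) with lognormal
speckle (3 dB), an organism accumulation hugging the base from above
(relative excess 8, e-folding 3 m) and a sharp 2 m cut-off below it, fish
schools at -50 dB with `Sv120 - Sv38` in [-3, 0] dB, per-ping layer-base
jitter of 4 m (internal waves and patchiness), range-dependent noise, and
CTD-O2 (or Niskin-bottle) stations whose DO profiles are logistic with
the 0.8 mL L^-1 isoline anchored exactly at Z*. Generation is seeded and
bitwise-deterministic, and the RNG state of the session is restored.

The near-base accumulation is what pins the 98% crossing to the layer
base: without it the percentile would sit ~2% of the layer thickness
above the base. The taper below the base continues from the background
density (the aggregation hugs the oxycline from above), which keeps the
noise-free closure property |Z_VEEC − Z*| ≤ 1 cell over the full 20–120 m
oxycline range. At night, merged migrators are rendered as a density
multiplier on the epipelagic profile — the communities share the same
vertical range, which is precisely the observation that makes the
boundary diel-invariant; the day/night test then verifies the *pipeline*
(diel classification, twilight removal, processing) introduces no
artefact. Sparse deep scatterers (0.5–1.8% of column energy, half the
pings) reproduce the regime in which a 99% threshold becomes erratic
while 98% stays stable — the documented rationale for 98%.

What the generator does **not** emulate: sonar-equation physics (beam
patterns, TVG artefacts, multiple scattering), impulse/transient noise,
seabed echoes (scenes are bottomless), species mixtures with
frequency-dependent scattering models, and horizontally correlated
speckle. Passing tests therefore demonstrate the estimator's correctness
and its contract with the stated scene model, not performance on every
instrument pathology found in real surveys.

## Numerical choices

* Resampling averages member samples in the linear domain; output cell
  tops align to the sea surface and partial cells are dropped. An
  all-no-data cell stays no-data; a partly missing cell averages its
  valid members only.
* The crossing depth interpolates linearly inside the crossing cell
  (cell-precision reporting by flag). Pings whose total weighted energy
  is at or below `min_energy` (default 0) are invalid rather than given a
  meaningless depth; a physically motivated floor is 10× the
  column-integrated noise energy.
* DO gradients: profiles are linearly interpolated to a 1 m grid and
  differentiated with centred differences (one-sided at the ends).
  Niskin profiles run through the same machinery; their coarser levels
  degrade `Z_0.8` within a closed-form curvature bound that is asserted
  in a test.
* On-disk formats: a CSV dialect (header comments + one column per bin)
  and a NetCDF dialect; both round-trip bit-exactly, including no-data
  cells. DO profiles and boundary series are long-format CSV; masks are
  GeoJSON; configuration is a single TOML document with unknown keys
  rejected.

## Problem sizes

The reference survey used by the checks is 5000 pings (≈26 km at 10
knots) × 586 native 0.25 m samples per frequency with 96 stations; the
wavelet-recovery check uses a 12 000-ping flat-trend scene so that the
10 km component lies inside the cone of influence; unit tests use
300-ping scenes. These sizes keep every property estimable while the
full suite runs in well under a minute.

## Known limitations

* A dense fish aggregation spanning a large share of a ping's column can
  still displace the crossing (the fish weight mitigates, and the
  robustness check allows up to 5% of pings to be affected — consistent
  with the behaviour the method is known for).
* `Z_VEEC` is undefined during twilight by construction; surveys that are
  mostly twilight yield empty series.
* The inshore/offshore zone label of a station is an input, not computed
  (no bathymetry or water-mass classification in scope).
* Gridding a single straight transect is degenerate (collinear points);
  boundary maps require crossing or zigzag coverage.
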