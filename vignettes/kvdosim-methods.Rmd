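---
title: "kvdosim: models, numerical choices and validity bounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kvdosim: models, numerical choices and validity bounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kvdosim is a desk-scale dosimetry simulator for kilovoltage x-ray cabinet
irradiators of the kind used for preclinical radiobiology (and for Cs-137
gamma cabinets they increasingly replace). It goes from a machine
description — tube potential, anode angle, filtration, source-to-shelf
distance, field size, tube current — and one or a few measured air-kerma
reference points to an absolute 3D dose distribution through a voxelized
sample. This vignette is the package's own account of its models, the
constants inside them, the numerical choices, and what the shipped tests do
and do not demonstrate.

## Geometry conventions

The world frame is right-handed with its origin (the "isocenter") at the
centre of the shelf top surface. The x-ray focal spot sits on the +z axis at
the source-to-isocenter distance (SID, default 500 mm); the beam travels
along −z. Phantoms are stacked upward from the shelf, so a point at height
z above the shelf is at distance SID − z from the source. The analytic
off-axis correction follows the beam-axis convention in which depth
increases away from the source; `filter_path()` documents the sign. Voxels
cover half-open intervals `[corner, corner + size)`; the lateral (x, y) grid
is uniform while the z grid is an explicit list of plane edges, so 0.278 mm
film layers and a 3.454 mm shield are represented exactly rather than forced
onto a uniform grid.

## The x-ray tube model

Spectra are generated by a semi-empirical thick-target tungsten model in the
Kramers/Birch–Marshall lineage:

* **Bremsstrahlung.** Emission along the electron slowing-down path with
  differential yield proportional to `(T − E)^(p−1)` for an electron of
  instantaneous energy `T`, which integrates to the generalized Kramers
  shape `N(E) ∝ Z (E0 − E)^p / E`. `p = 1` is the classical Kramers
  spectrum; `p > 1` softens the high-potential end the way cross-section
  based thick-target models do. The exponent scales with tube potential,
  `p = 1.25 + 0.2 kVp/100`.
* **Target self-attenuation.** Photons created while the electron has energy
  `T` escape through a tungsten path `(E0² − T²)/C · csc(θ)` with the
  Thomson–Whiddington constant `C = 1.3×10⁶ keV² cm²/g` and anode angle θ
  (30° by default). The per-bin integral over `T` uses 16-point
  Gauss–Legendre quadrature.
* **Characteristic lines.** Above the tungsten K edge (69.5 keV) the four K
  lines (59.32, 57.98, 67.24, 69.07 keV) are added with total yield
  `4×10⁻⁴ (E0/E_K − 1)^1.67` photons per electron — the middle of published
  thick-target K-yield measurements — damped by the same depth-averaged
  self-attenuation.
* **Absolute scale.** One electron per `1.602×10⁻¹⁹` mAs, emitted
  isotropically (per 4π steradian), with the Kramers constant
  `2×10⁻⁶ keV⁻¹` fixed by the standard thick-target efficiency rule
  η ≈ 10⁻⁹ Z·V. A single global `normalization` multiplier is exposed on
  `generate_spectrum()`; no per-machine fine-tuning parameters exist —
  per-machine absolute scaling is the calibration module's job.

**Calibration of the shape constants.** The spectrum model exists to
reproduce beam quality, not the internals of any particular code. The shape
exponent and the Thomson–Whiddington constant were therefore calibrated, by
grid search, to the first half-value layers in copper of the three reference
beams of the supported cabinet (300/200/100 kV, 30° anode, 3 mm Be + 0.2 mm
Cu): the model gives 1.15 / 0.56 / 0.20 mm Cu against the reference
1.1 / 0.6 / 0.2 mm, i.e. all three round to the reference values at 0.1 mm.
The resulting *absolute* air-kerma rates at 500 mm and 10 mA (1.19 / 0.56 /
0.121 Gy/min) then follow from the a-priori efficiency anchor with no
further adjustment; the acceptance suite checks the 300 kV value against its
reference (1.22 Gy/min, within 10%).

Known limitations: no anode heel effect (the fluence is azimuthally
symmetric; measured y-direction deviations up to several percent are
expected for large fields), no air-path attenuation between source and shelf
(< 0.5% above 20 keV at 500 mm), no off-tungsten anodes, and bins below
1 keV are dropped (they carry no fluence through any realistic inherent
filtration). The bin width defaults to 1 keV with centers at half-integers.

## Photon cross sections and materials

`inst/extdata/xsec_elements.csv` tabulates, for the twelve elements the
built-in materials need (H, Be, C, N, O, Mg, Cl, Ar, Ca, Cu, W, Pb), the
total mass attenuation coefficient, the mass energy-absorption coefficient,
and the photoelectric/incoherent/coherent partial fractions on 1 keV–1 MeV,
with explicit rows just below and above every K/L edge. The table is an
XCOM-style compilation assembled from standard atomic physics:
Cromer–Liberman photoabsorption for the photoelectric term (power-law
extended above the energies where that compilation is reliable), the exact
free-electron Klein–Nishina cross section for incoherent scattering, and a
Thomson × atomic-form-factor integral for coherent scattering. The mass
energy-absorption coefficient is the photoelectric term (less the K
fluorescence escape fraction) plus the Klein–Nishina mean energy transfer.
Radiative losses of secondary electrons are neglected — below 2% everywhere
under 320 keV.

The test suite checks the resulting mixture coefficients against published
reference values: dry-air mass energy-absorption agrees to better than 2%
over 60–300 keV (the range that dominates air kerma for these beams), and
water/copper attenuation to 4%/2%. The residual low-energy bias comes from
the free-electron Compton treatment (no binding/Doppler corrections, the
same documented simplification made in the transport kernel), which
overestimates incoherent attenuation by up to ~3% around 30–60 keV for
low-Z media; for lead above 200 keV the coherent form-factor model is crude
(~4%).

Materials are elemental mass-fraction mixtures with the standard mixture
rule, log-log interpolated in energy; interpolation is exact at table
energies. The catalogue ships Plastic Water LR (the vendor bulk density
1.029 g/cm³, which is not printed alongside the published composition, is
recorded in the fixture note), RB2 average-bone (1.310 g/cm³ as measured on
the slabs), lead (A = 207.19, 11.35 g/cm³), water, dry air, PMMA, beryllium,
copper and tungsten.

**Film layers.** Radiochromic film in slab stacks is modelled in practice
either as Plastic Water LR (matching the surrounding slabs) or as H₂O
(because film is calibrated to report dose to water while the Monte Carlo
scores dose to medium); the two conventions disagree by a few percent at
low energy. Both options are supported; `build_depth_dose_phantom()` defaults
to water and exposes `film_material = "plastic_water_lr"`.

## Phantoms

Shapes (boxes, cylinders, ellipsoids and boolean combinations) voxelize by a
voxel-center-inside test without volume-fraction antialiasing — adequate at
the ≤ 0.5 mm spatial scale the slit studies resolve, and checked by the
sphere-volume convergence test. Later shapes overwrite earlier ones. The
depth-dose stack builder reproduces the slab/film geometry exactly (four
5.04 mm Plastic Water LR or 5.03 mm RB2 slabs, five 0.278 mm films, 10 mm
base, 10 mm PMMA shelf: 31.55 mm total stack height), and the slit-shield
builder adds an 80 × 80 × 3.454 mm lead layer with a full-length central
slit of 3/5/10 mm, with the whole assembly translatable laterally (a 100 mm
offset puts the slit centre at world x = −100 mm). The grid is cropped to
the phantom footprint plus a configurable air margin (default 20 mm per
side); the shelf spans the whole cropped grid. Cropping understates
backscatter from the distant shelf/table, so out-of-field (shielded-region)
dose is systematically low by a few percent of the open-field maximum — the
margin can be widened for a "full table" style run at proportional cost.

## Monte Carlo transport

Histories start at a truncated isotropically emitting point source:
directions uniform per solid angle within the pyramid subtended by the field
rectangle at the isocenter plane, implemented by rejection from the bounding
cone (exact, no angular approximation); a zero-area field degenerates to a
central-axis pencil beam. Energies are drawn from the spectrum CDF. Rays
traverse the grid with an incremental Siddon-style walk with exact per-voxel
path lengths; the interaction point inverts `exp(−τ)`; the channel is chosen
from the local material's partial cross sections:

* photoelectric — the full photon energy is deposited locally (atomic
  relaxations off; for the analog estimator) and the history branch ends;
* incoherent — free-electron Klein–Nishina, sampled by the standard
  composition–rejection method; the energy difference deposits locally and
  the scattered photon continues;
* coherent — Thomson angular law (form factors omitted in the *angular*
  sampling, a documented simplification), no deposition.

Photons leaving the grid terminate; photons falling below the cutoff
(`pcut`, default 10 keV) deposit their remaining energy locally.

**Kerma approximation.** No electron transport: secondary-electron energy
deposits at the interaction site. At the 320 kV maximum tube potential,
secondary electrons stay below 320 keV, where their CSDA range in water is
under a millimetre — smaller than or comparable to every scoring voxel used
here. This is the same regime in which condensed-history codes run with an
electron transport cutoff of 0.831 MeV total energy (320 keV kinetic)
deposit all electrons locally, so the rule is physics-equivalent to that
standard configuration by construction; `run_transport()` asserts the source
maximum and warns above 320 keV (the Cs-137 line is exempted as a line
source, with interface dose then smoothed over the ~2 mm electron range in
reality — a stated validity bound).

**Scoring.** Two estimators share the same analog random walk:

* `estimator = "track"` (default): expected-value track-length kerma
  scoring — every segment of every photon track deposits
  `w·E·μ_en(E)·dl` in the voxel it crosses. Unbiased for collision kerma,
  and it is what makes thin-film scoring tractable: the analog collision
  estimator needs on the order of 10⁴ deposits per voxel for 1% statistics,
  which for 0.278 mm film planes at 2 mm lateral resolution costs ~10¹¹
  voxel steps, beyond a desk budget; the track estimator reaches the same
  statistics about three orders of magnitude faster.
* `estimator = "collision"`: analog deposits at interaction sites, exactly
  the branch rules above. This is the estimator the physics oracles use
  (interaction-density depth profiles, energy conservation), and it
  supports interaction splitting (`n_split`): the primary's track is split
  into n stratified interaction points of weight 1/n whose descendants are
  transported analog without further splitting.

Statistical uncertainty is history-by-history: all descendants (and all
splits) of one primary are one history, and per-voxel
`σ_rel = sqrt((ΣX²/N − (ΣX/N)²)/(N−1)) / (ΣX/N)`. A voxel fed by a single
history reports σ_rel = 1 — unreliable by construction.
`region_uncertainty()` summarizes the voxels above a dose threshold
(default 50% of maximum, the convergence criterion used for depth-dose
runs).

**Random numbers.** xoshiro256++ seeded per history through splitmix64 from
the user seed and the history index: every history owns a deterministic
substream, so results are bitwise reproducible for a fixed seed and
independent of any batching or scheduling.

## Off-axis correction

The point source is truncated-isotropic, so the only systematic fluence
correction applied is the analytic extra filter path for oblique rays:
`φ = atan(√(x²+y²)/(SID+z))`, `t = t_filter/cos φ`, and the transmitted
fraction `Σᵢ Nᵢ exp(−(t−t_filter) μᵢ) / Σᵢ Nᵢ` evaluated bin by bin over the
spectrum behind the filter. The spectral change introduced by the extra
copper is ignored (the ratio scales dose directly), the correction is
applied voxel-wise to the dose grid after transport, and the relative
uncertainty map is unchanged. On the central axis, and for zero filter
thickness, the correction is exactly the identity. No heel-effect model is
included; measurement-based profile corrections are out of scope, so
y-direction (anode-direction) profiles are the least accurate output for
large fields.

## Absolute calibration

The conversion factor from Gy/particle to absolute dose follows the
reference-scaling formula
`F_cal = S_ref · (ΣN_beam / ΣN_ref) · (A_beam·d_ref²)/(A_ref·d_beam²)`,
with the spectrum integrals taken as plain fluence-bin sums — deliberately
faithful to the formula as stated, even though kerma-weighted integrals
could be argued more physical. `S_ref` comes from one measured air-kerma
rate via `determine_sref()`, which makes the calibrated simulation
reproduce the measurement exactly at the reference point. With several
references on file, `nearest_reference()` selects by half-value-layer
distance (ties toward the higher tube potential); a per-spectrum reference
is preferred over cross-spectrum scaling whenever one is available, since
the measured/analytic ratio is only constant across beams to a few percent.
Absolute dose is `dose × F_cal × mAs`; applying the calibration twice is an
error caught by grid metadata.

## Dose evaluation

Depth-dose and lateral profiles report the mean over the extraction window
with the quadrature-combined statistical uncertainty (systematic
uncertainties are not modelled). FWHM uses linear interpolation of the two
half-maximum crossings — not splines, which ring at a 0.25 mm penumbra.
High-dose region metrics average voxels at or above 80% of the maximum
(boundary inclusive). Cumulative DVHs are evaluated on an even threshold
grid with D_xx/V_yy by linear interpolation. Dose-to-water conversion
multiplies each voxel by the water-to-medium mass energy-absorption ratio
fluence-averaged over the *primary* spectrum; in-phantom spectral drift with
depth is a stated approximation and the function accepts a user-supplied
local spectrum instead. The structured irradiation report collects the
reporting-checklist core (machine, kVp, filtration, HVL, SID, field,
current, phantom, calibration provenance, dose metrics, uncertainty
summary, software version, seed) and refuses to render with missing fields.

## What the fixtures emulate — and what they do not

The named fixtures reproduce the published bench geometries exactly: slab
thicknesses, film count and thickness, base, shelf, SID, shield dimensions,
slit widths and offsets, the 300 mm radial film span, and the per-potential
tube currents (10/12/25 mA at 300/200/100 kV). The slit fixtures default to
0.25 mm lateral voxels (the resolution the slit comparisons used) and
100 kV. What they do not emulate: radiochromic-film response (energy
dependence, scanner optics, calibration-curve uncertainty of ~3–4%), the
anode heel effect, focal-spot size (penumbra is purely geometric), and
backscatter from structures beyond the cropped grid. Passing the shipped
tests therefore demonstrates internal physics consistency and agreement
with the reference beam-quality/air-kerma values — not film-level agreement
with any particular bench measurement.

Problem sizes used by the shipped checks, chosen as sensible desk-scale
settings: the depth-dose uncertainty run uses 2 mm lateral scoring voxels
with film-resolved z planes and 2×10⁸ histories (reaching < 1% maximum
relative uncertainty in the ≥ 50% dose region); the slit FWHM check uses
0.25 mm voxels and 8×10⁶ histories; the physics oracles use pencil beams on
1–10 mm water columns with 10⁴–10⁶ histories.

## Known limitations

* Free-electron Compton (no binding/Doppler) and form-factor-free coherent
  *angular* sampling: ≲ 2–3% effects on attenuation for these spectra,
  concentrated at low energy and high Z.
* No electron transport: interface dose gradients sharper than the real
  sub-millimetre electron range; Cs-137 interface dose is the stated edge
  of validity.
* No heel effect; open-field anode-direction profiles deviate most.
* Out-of-field dose is understated because the geometry is cropped.
* Absolute spectrum output is anchored on a thick-target efficiency rule;
  per-machine accuracy comes from the air-kerma calibration, not from the
  analytic spectrum.
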