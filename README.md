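# kvdosim

Monte Carlo dosimetry for kilovoltage x-ray cabinet irradiators.

Preclinical radiobiology is mostly done in sealed x-ray cabinets (and in the
Cs-137 gamma irradiators they are replacing). These machines typically ship
with a single air-kerma calibration point — not with the 3D absorbed-dose
distribution through an actual sample, which varies strongly with beam
quality, geometry and tissue composition (bone can absorb several times the
dose of soft tissue at 100 kV). kvdosim closes that gap at desk scale: it
goes from a machine description plus one or a few measured air-kerma
reference points to an absolute 3D dose distribution through a voxelized
phantom, for physicists and radiobiologists who need defensible dose
reporting without a full Monte Carlo installation.

## What it computes

* **Tube spectra.** A semi-empirical thick-target tungsten model
  N(E) ∝ Z (E₀−E)ᵖ/E with Thomson–Whiddington target self-attenuation and W
  K-lines, filtered per bin by Beer–Lambert through the stated filtration;
  beam-quality indices HVL (air-kerma halving thickness, solved by
  bisection) and the central-axis air-kerma rate
  K = Σᵢ Nᵢ Eᵢ (μ_en/ρ)ₐᵢᵣ(Eᵢ)/d².
* **Materials.** An element cross-section table (1 keV–1 MeV, edge-resolved)
  with mixture-rule μ/ρ, μ_en/ρ and partial interaction fractions for water,
  air, Plastic Water LR, RB2 bone, lead, PMMA, Be, Cu, W.
* **Phantoms.** Boolean solid geometry voxelized on a grid with exact thin
  z-layers: slab/film depth-dose stacks, lead slit shields, shelf, offsets.
* **Transport.** Photon Monte Carlo with kerma-approximation scoring
  (photoelectric, free-electron Klein–Nishina Compton, Thomson coherent),
  expected-value track-length or analog collision estimators,
  history-by-history uncertainties, per-history RNG substreams
  (bit-reproducible for a fixed seed).
* **Calibration.** F_cal = S_ref · (ΣN_beam/ΣN_ref) · (A_beam d_ref²)/(A_ref d_beam²)
  converts Gy/particle to absolute Gy from a measured air-kerma point;
  nearest-HVL reference selection.
* **Evaluation.** Depth-dose/lateral profiles, FWHM, ≥80%-of-max region
  means, DVHs and D/V metrics, D_m,m → D_w,m conversion, analytic off-axis
  filter-path correction, and a structured irradiation report.

See `vignettes/kvdosim-methods.Rmd` for the models, constants and validity
bounds.

## Worked example

Characterize the 300 kV reference beam and simulate the slab/film
depth-dose phantom on the cabinet shelf:

```r
library(kvdosim)

sp <- generate_spectrum(300, anode_angle = 30,
                        filtration = c(beryllium = 3, copper = 0.2))
half_value_layer(sp, "copper")        # 1.147  (mm Cu; reference 1.1)
air_kerma_rate(sp, 500, 10)           # 1.192  (Gy/min at 500 mm, 10 mA)

fx <- fixture("depth_dose_pw", kvp = 300, voxel_xy_mm = 2)
dose <- run_transport(fx$phantom, fx$beam,
                      transport_config(n_histories = 2e7, seed = 1))
dose <- apply_offaxis_correction(dose, fx$beam)
region_uncertainty(dose, 0.5)$max     # 0.0187 (max rel. sigma, >50% region)

# absolute calibration from the measured 1.560 Gy/min air-kerma point
ref <- determine_sref(1.560, fx$beam, air_kerma_per_particle(fx$beam))
ref$s_ref                             # 8.675e11 (particles/mAs)
fcal <- conversion_factor(ref, fx$beam)
abs_dose <- to_absolute(dose, fcal, current_mA = 10, time_s = 60)  # 600 mAs
prof <- depth_dose(abs_dose, roi_xy = list(x = c(-5, 5), y = c(-5, 5)))
round(prof$dose[match(attr(fx$phantom, "film_z_mm"),
                      prof$position_mm)], 3)
# 1.926 2.122 2.306 2.445 2.451   (Gy at the five film planes, deep to top)
```

Reading the numbers: the generated 300 kV beam has a first HVL of 1.15 mm
Cu (rounding to the 1.1 mm machine value) and an analytic output of
1.19 Gy/min at the shelf. After scaling to the measured 1.560 Gy/min
reference point, a 600 mAs exposure (60 s at 10 mA, free-in-air kerma
1.56 Gy) delivers about 2.45 Gy to the top film of the Plastic Water stack
(dose to water plus phantom backscatter), falling to 1.93 Gy at the deepest
film ~27 mm down through attenuation and inverse-square falloff.

The same pipeline runs from a YAML configuration (`run("config.yaml")`) or
from the thin CLI at `inst/cli/kvdosim`
(`kvdosim simulate --config config.yaml --seed 1`).

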