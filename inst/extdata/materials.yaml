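# Built-in material catalogue: name, density (g/cm3), elemental mass fractions.
# Mass fractions must sum to 1 within 1e-4; every element must exist in the
# element cross-section table (xsec_elements.csv).
schema_version: 1
materials:
  water:
    density: 1.000
    composition: {"H": 0.1119, "O": 0.8881}
    note: liquid water, unit density
  air:
    density: 0.0012048
    composition: {"C": 0.000124, "N": 0.755268, "O": 0.231781, "Ar": 0.012827}
    note: dry air near sea level, 20 C
  plastic_water_lr:
    density: 1.029
    composition: {"H": 0.0791, "C": 0.5362, "N": 0.0174, "O": 0.2721, "Mg": 0.0929, "Cl": 0.0023}
    note: >-
      CIRS Plastic Water LR epoxy water substitute. Bulk density is the
      vendor-quoted 1.029 g/cm3 (not printed with the composition source).
  rb2_bone:
    density: 1.310
    composition: {"H": 0.0571, "C": 0.5058, "N": 0.0167, "O": 0.2820, "Cl": 0.0010, "Ca": 0.1374}
    note: >-
      RB2 average-bone equivalent; density from slab weight/dimension
      measurement, within the 1.26-1.40 g/cm3 literature range.
  lead:
    density: 11.35
    composition: {"Pb": 1.0}
    note: pure lead shielding, A = 207.19
  pmma:
    density: 1.190
    composition: {"H": 0.080538, "C": 0.599848, "O": 0.319614}
    note: Perspex / acrylic shelf material
  beryllium:
    density: 1.848
    composition: {"Be": 1.0}
    note: tube exit window (inherent filtration)
  copper:
    density: 8.960
    composition: {"Cu": 1.0}
    note: added beam filtration / HVL material
  tungsten:
    density: 19.30
    composition: {"W": 1.0}
    note: anode target material
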