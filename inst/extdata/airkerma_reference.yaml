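# Reference air-kerma points for the 320 kV cabinet: measured free-in-air
# rates at 500 mm on the central axis for 10 mA, alongside the rates derived
# from the analytic spectrum model used for calibration scaling.
schema_version: 1
distance_mm: 500
current_mA: 10
points:
  - {kvp: 300, measured_gy_min: 1.560, measured_sd: 0.013, analytic_gy_min: 1.22, ratio_printed: 1.27}
  - {kvp: 200, measured_gy_min: 0.715, measured_sd: 0.003, analytic_gy_min: 0.53, ratio_printed: 1.34}
  - {kvp: 100, measured_gy_min: 0.162, measured_sd: 0.002, analytic_gy_min: 0.12, ratio_printed: 1.35}
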