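geometry:
  length_mm: 18.3
  dx_mm: 0.0025
  thickness_base_um: 16.5
  thickness_apex_um: 5.0
  width_base_mm: 0.125
  width_apex_mm: 0.25
  area_sv_base_mm2: 0.8
  area_sv_apex_mm2: 0.3
  area_st_base_mm2: 0.8
  area_st_apex_mm2: 0.3
  thickness_profile: linear
  spiral:
    form: logarithmic
    total_angle_deg: 1080.0
    basal_radius_mm: 2.0
    taper_rate: 0.12
materials:
  plate_constant: 175.0
  overrides: ~
electrode:
  insertion_angle_deg: 900.0
  basal_diameter_mm: 0.55
  apical_diameter_mm: 0.25
  mass_loading: no
  compliance_factor: 1.0
stimulus:
  frequencies_Hz:
  - 400.0
  - 1000.0
  - 2000.0
  - 4000.0
  - 6000.0
  - 8000.0
  - 10000.0
  stapes_displacement_m: 1.0e-08
  level_label: 90 dB SPL
solver:
  formulation: incompressible
  helicotrema: matched
  footplate_area_mm2: 1.0
  tolerance: 1.0e-10
analysis:
  smoothing_window_mm: 0.2
  greenwood:
    species: chinchilla
  max_dx_shift_mm: 0.1
  max_ddb: 3.0
  greenwood_rms_fraction: 0.05
sweep:
  angles_deg:
  - 180.0
  - 360.0
  - 540.0
  - 720.0
  - 900.0
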