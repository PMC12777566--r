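# Human reference physiology (ICRP-89-style compilation; 70 kg reference
# adult). See mouse.yaml for conventions. Blood volume 5 L at 70 kg.
# The allometric cardiac-output rule gives ~399 L/h at 70 kg, consistent
# with the ~6.5 L/min resting reference value.
species: human
body_mass_default: 70.0
blood_volume_fraction: 0.0714285714
venous_fraction_of_blood: 0.667
cardiac_output:
  coefficient_L_h: 16.5
  exponent: 0.75
organs:
  - {name: blood,           weight_fraction: 0.0714, flow_fraction: 0.000, vascular_fraction: 1.000, interstitial_fraction: 0.000, phagocyte_density: 0.0}
  - {name: lung,            weight_fraction: 0.0076, flow_fraction: 1.000, vascular_fraction: 0.260, interstitial_fraction: 0.190, phagocyte_density: 2.0e6}
  - {name: muscle,          weight_fraction: 0.4000, flow_fraction: 0.170, vascular_fraction: 0.026, interstitial_fraction: 0.120, phagocyte_density: 3.0e5}
  - {name: bone,            weight_fraction: 0.1429, flow_fraction: 0.050, vascular_fraction: 0.041, interstitial_fraction: 0.100, phagocyte_density: 6.0e6}
  - {name: liver,           weight_fraction: 0.0257, flow_fraction: 0.065, vascular_fraction: 0.115, interstitial_fraction: 0.163, phagocyte_density: 1.0e7}
  - {name: stomach,         weight_fraction: 0.0021, flow_fraction: 0.010, vascular_fraction: 0.032, interstitial_fraction: 0.100, phagocyte_density: 7.0e5}
  - {name: spleen,          weight_fraction: 0.0026, flow_fraction: 0.030, vascular_fraction: 0.220, interstitial_fraction: 0.150, phagocyte_density: 4.0e7}
  - {name: small_intestine, weight_fraction: 0.0091, flow_fraction: 0.100, vascular_fraction: 0.024, interstitial_fraction: 0.094, phagocyte_density: 1.5e6}
  - {name: large_intestine, weight_fraction: 0.0053, flow_fraction: 0.040, vascular_fraction: 0.024, interstitial_fraction: 0.094, phagocyte_density: 1.5e6}
  - {name: kidney,          weight_fraction: 0.0044, flow_fraction: 0.190, vascular_fraction: 0.105, interstitial_fraction: 0.200, phagocyte_density: 1.0e6}
  - {name: skin,            weight_fraction: 0.0371, flow_fraction: 0.050, vascular_fraction: 0.019, interstitial_fraction: 0.302, phagocyte_density: 1.0e6}
  - {name: brain,           weight_fraction: 0.0200, flow_fraction: 0.120, vascular_fraction: 0.030, interstitial_fraction: 0.180, phagocyte_density: 1.0e5}
  - {name: thyroid,         weight_fraction: 0.0003, flow_fraction: 0.015, vascular_fraction: 0.100, interstitial_fraction: 0.150, phagocyte_density: 7.0e5}
  - {name: carcass,         weight_fraction: 0.2715, flow_fraction: 0.160, vascular_fraction: 0.040, interstitial_fraction: 0.100, phagocyte_density: 3.0e5}
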