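# Rat reference physiology (Brown et al. 1997-style compilation).
# See mouse.yaml for conventions; phagocyte densities adjusted to
# rat-specific literature values.
species: rat
body_mass_default: 0.25
blood_volume_fraction: 0.064
venous_fraction_of_blood: 0.667
cardiac_output:
  coefficient_L_h: 16.5
  exponent: 0.75
organs:
  - {name: blood,           weight_fraction: 0.0640, flow_fraction: 0.0000, vascular_fraction: 1.000, interstitial_fraction: 0.000, phagocyte_density: 0.0}
  - {name: lung,            weight_fraction: 0.0050, flow_fraction: 1.0000, vascular_fraction: 0.260, interstitial_fraction: 0.190, phagocyte_density: 2.5e6}
  - {name: muscle,          weight_fraction: 0.4040, flow_fraction: 0.2780, vascular_fraction: 0.026, interstitial_fraction: 0.120, phagocyte_density: 4.0e5}
  - {name: bone,            weight_fraction: 0.0730, flow_fraction: 0.1220, vascular_fraction: 0.041, interstitial_fraction: 0.100, phagocyte_density: 8.0e6}
  - {name: liver,           weight_fraction: 0.0366, flow_fraction: 0.0210, vascular_fraction: 0.115, interstitial_fraction: 0.163, phagocyte_density: 2.0e7}
  - {name: stomach,         weight_fraction: 0.0046, flow_fraction: 0.0068, vascular_fraction: 0.032, interstitial_fraction: 0.100, phagocyte_density: 8.0e5}
  - {name: spleen,          weight_fraction: 0.0020, flow_fraction: 0.0128, vascular_fraction: 0.220, interstitial_fraction: 0.150, phagocyte_density: 6.0e7}
  - {name: small_intestine, weight_fraction: 0.0140, flow_fraction: 0.0946, vascular_fraction: 0.024, interstitial_fraction: 0.094, phagocyte_density: 1.8e6}
  - {name: large_intestine, weight_fraction: 0.0084, flow_fraction: 0.0266, vascular_fraction: 0.024, interstitial_fraction: 0.094, phagocyte_density: 1.8e6}
  - {name: kidney,          weight_fraction: 0.0073, flow_fraction: 0.1410, vascular_fraction: 0.105, interstitial_fraction: 0.200, phagocyte_density: 1.2e6}
  - {name: skin,            weight_fraction: 0.1900, flow_fraction: 0.0580, vascular_fraction: 0.019, interstitial_fraction: 0.302, phagocyte_density: 1.2e6}
  - {name: brain,           weight_fraction: 0.0057, flow_fraction: 0.0200, vascular_fraction: 0.030, interstitial_fraction: 0.180, phagocyte_density: 1.0e5}
  - {name: thyroid,         weight_fraction: 0.0001, flow_fraction: 0.0016, vascular_fraction: 0.100, interstitial_fraction: 0.150, phagocyte_density: 8.0e5}
  - {name: carcass,         weight_fraction: 0.1853, flow_fraction: 0.2176, vascular_fraction: 0.040, interstitial_fraction: 0.100, phagocyte_density: 4.0e5}
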