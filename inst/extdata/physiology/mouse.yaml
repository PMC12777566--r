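# Mouse reference physiology.
# Organ weights as fractions of body mass and blood flows as fractions of
# cardiac output, compiled from standard reference tables (Brown et al. 1997
# style); vascular/interstitial sub-volume fractions from reported tissue
# composition data; tissue-resident phagocyte densities (cells/g) from
# literature macrophage counts (Kupffer cells, red-pulp macrophages,
# alveolar macrophages, ...). Units: kg, L, L/h, cells/g, h.
# carcass is the balancing term for both mass and systemic flow closure;
# lung receives total cardiac output (in-series), so its flow_fraction (1.0)
# is excluded from the systemic closure sum, as is blood (a pool, not a
# perfused tissue).
species: mouse
body_mass_default: 0.025
blood_volume_fraction: 0.049
venous_fraction_of_blood: 0.667
cardiac_output:
  coefficient_L_h: 16.5
  exponent: 0.75
organs:
  - {name: blood,           weight_fraction: 0.0490, flow_fraction: 0.000, vascular_fraction: 1.000, interstitial_fraction: 0.000, phagocyte_density: 0.0}
  - {name: lung,            weight_fraction: 0.0073, flow_fraction: 1.000, vascular_fraction: 0.260, interstitial_fraction: 0.190, phagocyte_density: 3.0e6}
  - {name: muscle,          weight_fraction: 0.3840, flow_fraction: 0.159, vascular_fraction: 0.026, interstitial_fraction: 0.120, phagocyte_density: 5.0e5}
  - {name: bone,            weight_fraction: 0.1070, flow_fraction: 0.110, vascular_fraction: 0.041, interstitial_fraction: 0.100, phagocyte_density: 5.0e6}
  - {name: liver,           weight_fraction: 0.0549, flow_fraction: 0.020, vascular_fraction: 0.115, interstitial_fraction: 0.163, phagocyte_density: 1.5e7}
  - {name: stomach,         weight_fraction: 0.0060, flow_fraction: 0.012, vascular_fraction: 0.032, interstitial_fraction: 0.100, phagocyte_density: 1.0e6}
  - {name: spleen,          weight_fraction: 0.0035, flow_fraction: 0.010, vascular_fraction: 0.220, interstitial_fraction: 0.150, phagocyte_density: 5.0e7}
  - {name: small_intestine, weight_fraction: 0.0253, flow_fraction: 0.110, vascular_fraction: 0.024, interstitial_fraction: 0.094, phagocyte_density: 2.0e6}
  - {name: large_intestine, weight_fraction: 0.0109, flow_fraction: 0.030, vascular_fraction: 0.024, interstitial_fraction: 0.094, phagocyte_density: 2.0e6}
  - {name: kidney,          weight_fraction: 0.0167, flow_fraction: 0.091, vascular_fraction: 0.105, interstitial_fraction: 0.200, phagocyte_density: 1.5e6}
  - {name: skin,            weight_fraction: 0.1653, flow_fraction: 0.058, vascular_fraction: 0.019, interstitial_fraction: 0.302, phagocyte_density: 1.5e6}
  - {name: brain,           weight_fraction: 0.0165, flow_fraction: 0.033, vascular_fraction: 0.030, interstitial_fraction: 0.180, phagocyte_density: 1.0e5}
  - {name: thyroid,         weight_fraction: 0.0001, flow_fraction: 0.002, vascular_fraction: 0.100, interstitial_fraction: 0.150, phagocyte_density: 1.0e6}
  - {name: carcass,         weight_fraction: 0.1535, flow_fraction: 0.365, vascular_fraction: 0.040, interstitial_fraction: 0.100, phagocyte_density: 5.0e5}
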