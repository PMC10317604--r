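{
  "segments": [
    {
      "id": "inlet",
      "kind": "horizontal_channel",
      "length": 0.005,
      "cross_section": {
        "shape": "rectangular",
        "width": 0.001,
        "depth": 0.00018
      },
      "contact_angle": 40,
      "inclination": 0,
      "wettability_zone": "hydrophilic_coated"
    },
    {
      "id": "well_lower",
      "kind": "vertical_well",
      "length": 0.002,
      "cross_section": {
        "shape": "cylindrical",
        "radius": 0.00025
      },
      "contact_angle": 40,
      "inclination": 90,
      "wettability_zone": "hydrophilic_coated"
    },
    {
      "id": "band",
      "kind": "vertical_well",
      "length": 0.001,
      "cross_section": {
        "shape": "cylindrical",
        "radius": 0.00025
      },
      "contact_angle": 110,
      "inclination": 90,
      "wettability_zone": "hydrophobic_band"
    },
    {
      "id": "well_upper",
      "kind": "vertical_well",
      "length": 0.001,
      "cross_section": {
        "shape": "cylindrical",
        "radius": 0.00025
      },
      "contact_angle": 40,
      "inclination": 90,
      "wettability_zone": "hydrophilic_coated"
    },
    {
      "id": "outlet",
      "kind": "outlet_channel",
      "length": 0.0085,
      "cross_section": {
        "shape": "rectangular",
        "width": 0.0005,
        "depth": 0.0001
      },
      "contact_angle": 40,
      "inclination": 0,
      "wettability_zone": "hydrophilic_coated"
    }
  ],
  "fluid": {
    "viscosity": 0.35,
    "density": 1060,
    "surface_tension": 0.058,
    "gravity": 9.81,
    "coagulation_tau": 900
  },
  "species": [
    {
      "name": "plasma",
      "diffusivity": 1e-10,
      "molecular_weight": 1,
      "initial_mass_fraction": 0.601,
      "barrier_transmission": 1
    },
    {
      "name": "cells",
      "diffusivity": 1e-10,
      "molecular_weight": 1,
      "initial_mass_fraction": 0.399,
      "barrier_transmission": 0.0098
    }
  ],
  "operating": {
    "injected_volume_ul": 10,
    "pump_rate_ul_min": 0.8,
    "hematocrit": 0.399,
    "run_duration_min": 12
  }
}
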