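{
  "params": {
    "I": 0.005,
    "eC": 1e-05,
    "eD": 1e-05,
    "v0D": 1e+08,
    "EvD": 47,
    "K0D": 1.3e+08,
    "EKD": 30,
    "v0U": 1e+05,
    "EvU": 38,
    "K0U": 1100,
    "EKU": 20,
    "dM": 0.0002,
    "dZ": 0.001,
    "gM": 0.31,
    "gZ": 0.5,
    "Rgas": 0.008314
  },
  "scenario": {
    "kind": "kinetics_only",
    "Tref": 20,
    "gM_floor": 0.01
  },
  "kernel": {
    "c0": 1.17,
    "c0_values": [1.1, 1.17, 1.4]
  },
  "projection": {
    "mode": "both",
    "depth_cm": 1
  },
  "seed": 1,
  "notes": {
    "units": "mg C per cm^3 soil, hours; activation energies kJ/mol with Rgas in kJ/(mol K)",
    "I": "litter input to SOC, 5e-3 mg C cm^-3 h^-1 (published model configuration)",
    "eC_eD": "small abiotic leaching, 1e-5 h^-1 each; eC > 0 keeps SOC bounded when enzymes vanish (package choice, the AWB source model has no leaching)",
    "v0U_EvU": "uptake kinetics pre-exponential 1e5 and activation energy 38 kJ/mol (published model configuration)",
    "v0D_EvD": "decomposition kinetics 1e8 and 47 kJ/mol (AWB literature values)",
    "K0D_EKD_K0U_EKU": "Arrhenius half-saturation constants chosen so KmD(20C) ~ 582 and KmU(20C) ~ 0.30 mg C cm^-3, matching AWB 20 C magnitudes (package choice: the AWB source model uses linear-in-T Km)",
    "dM_dZ": "biomass turnover 2e-4 h^-1 and enzyme deactivation 1e-3 h^-1 (AWB literature values)",
    "gM": "growth efficiency 0.31 = AWB carbon use efficiency at 20 C",
    "gZ": "enzyme production efficiency 0.5 (package choice, not constrained by the source model)",
    "c0": "competition advantage slope, intermediate published value 1.17; 1.1 and 1.4 flank it as the low/high sweep values (package choice: any c0 <= 1 makes the positive optimum nonexistent everywhere, so the low value must stay above the existence threshold ~1/(1 - dM/(gM vmaxU)))"
  }
}
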