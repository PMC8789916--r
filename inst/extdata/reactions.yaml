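# Catabolic reactions of the deep hot-biosphere energetics stage.
#
# Stoichiometric coefficients: products positive, reactants negative,
# per mol of the reference substrate (SO4^2- or CH4).
#
# dG0_insitu_kj_mol is INPUT DATA: the standard-state Gibbs energy at
# in-situ temperature and pressure, normally produced by a thermodynamic
# code (SUPCRT-family) for the user's own T/P. The values for SR_acetate
# and MG_acetate are calibrated anchors: evaluated against the
# anchor_conditions block below (through this package's extended
# Debye-Hueckel coefficients) they return in-situ reaction energies of
# -105 kJ (mol SO4^2-)^-1 and -43 kJ (mol CH4)^-1 at 920 mbsf / 100 C.
# The remaining three values are illustrative order-of-magnitude
# standard-state energies near 100 C (synthetic; replace with computed
# values for quantitative work).
reactions:
  AOM:
    equation: "CH4 + SO4-2 -> HCO3- + HS- + H2O"
    stoichiometry: {"CH4": -1, "SO4-2": -1, "HCO3-": 1, "HS-": 1, "H2O": 1}
    dG0_insitu_kj_mol: -25.0
    dG0_source: illustrative
  SR_acetate:
    equation: "SO4-2 + CH3COO- -> HS- + 2 HCO3-"
    stoichiometry: {"SO4-2": -1, "CH3COO-": -1, "HS-": 1, "HCO3-": 2}
    dG0_insitu_kj_mol: -47.8896
    dG0_source: calibrated_anchor
  SR_H2:
    equation: "4 H2 + SO4-2 + H+ -> HS- + 4 H2O"
    stoichiometry: {"H2": -4, "SO4-2": -1, "H+": -1, "HS-": 1, "H2O": 4}
    dG0_insitu_kj_mol: -195.0
    dG0_source: illustrative
  MG_acetate:
    equation: "CH3COO- + H2O -> CH4 + HCO3-"
    stoichiometry: {"CH3COO-": -1, "H2O": -1, "CH4": 1, "HCO3-": 1}
    dG0_insitu_kj_mol: -14.4261
    dG0_source: calibrated_anchor
  MG_H2:
    equation: "4 H2 + HCO3- + H+ -> CH4 + 3 H2O"
    stoichiometry: {"H2": -4, "HCO3-": -1, "H+": -1, "CH4": 1, "H2O": 3}
    dG0_insitu_kj_mol: -176.0
    dG0_source: illustrative

# Reference porewater composition at the calibration anchor
# (920 mbsf, 100 C, 55.8 MPa, ionic strength 0.64, pH 7.5; HS- at its
# 0.1 umol L^-1 below-detection floor).
anchor_conditions:
  depth_mbsf: 920
  temp_C: 100
  pressure_MPa: 55.8
  ionic_strength_mol_l: 0.64
  pH: 7.5
  conc_mol_l:
    SO4-2: 3.0e-3
    CH3COO-: 1.0e-2
    HCO3-: 1.0e-3
    HS-: 1.0e-7
    CH4: 1.0e-3
  target_dG_kj_mol:
    SR_acetate: -105
    MG_acetate: -43
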