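# Example role map: species -> atom name -> analysis role + partial charge (e).
# Atom names follow the synthetic generator's convention; real force fields
# name atoms differently (e.g. CHARMM36 cholesterol hydroxyl oxygen is O3),
# which is exactly why the map is a config file and not hard-coded.
# Charges here are formal headgroup charges; substitute force-field partial
# charges for quantitative profiles.
DOPC:
  P:  {role: LIPID_P, charge: -1.0}
  N:  {role: LIPID_N, charge:  1.0}
CHOL:
  O3: {role: CHOL_O, charge: 0.0}
KOR105:
  N1: {role: N_PLUS, charge: 1.0}
  CP: {role: PARA_C, charge: 0.0}
  CT: {role: TERM_C, charge: 0.0}
BAC:
  N1: {role: N_PLUS, charge: 1.0}
  CP: {role: PARA_C, charge: 0.0}
  CT: {role: TERM_C, charge: 0.0}
SDS:
  S1: {role: SULFATE_S, charge: -1.0}
  CT: {role: TERM_C, charge: 0.0}
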