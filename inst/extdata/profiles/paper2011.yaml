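# Default parameter profile: gramicidin A dimer in a monoglyceride-like
# bilayer. Energies in kBT, lengths in nm, rates in units of the
# pre-exponential factor A (A itself is not fixed by the model).
model:
  D_e: 20.0        # subunit-subunit dissociation energy (multi-H-bond junction)
  r_e: 1.1         # equilibrium centre-of-mass separation (half the dimer length)
  beta: 10.0       # Morse stiffness; decay length 1/beta = 0.1 nm
  l0: 2.2          # dimer hydrophobic length at equilibrium
  d: 3.0           # bilayer hydrophobic thickness (mismatch d - l0 = 0.8 nm)
  H_B: 20.0        # phenomenological membrane spring coefficient
  A: 1.0           # Arrhenius pre-exponential factor (reduced time units)
  kBT: 1.0         # thermal energy scale (energies already thermal)
  coupling_slope: 1.0  # dl/dr: hydrophobic length gained per nm of separation
units:
  energy_label: kBT
  energy_to_kBT: 1.0
  length_label: nm
  length_to_nm: 1.0
scan:
  variable: thickness
  min: 2.6
  max: 3.4
  n_points: 9
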