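# United-atom (CHARMM19/EEF1-style) solvation parameter set used to seed the
# coarse-grained bead table.  The water column follows published EEF1
# magnitudes; the cyclohexane (chex) column is a synthetic set constructed
# from water-to-cyclohexane transfer trends (aliphatic groups favourable in
# the membrane interior, polar and ionic groups strongly penalized).  All
# entries are replaceable input data, not constants of the method.
#
# Fields per type:
#   volume      A^3, solvation volume
#   lambda      A, correlation length of the Gaussian solvation shell
#   dgref_w/c   kcal/mol, reference solvation free energy (water / chex)
#   dgfree_w/c  kcal/mol, free-group solvation free energy (water / chex)
#   rvdw        A, van der Waals radius
#   mass        amu
atoms:
  C:    {volume: 14.7, lambda: 3.5, dgref_w:  0.000, dgfree_w:  0.000, dgref_c: -0.30, dgfree_c: -0.30, rvdw: 1.70, mass: 12.011}
  CR:   {volume: 14.7, lambda: 3.5, dgref_w:  0.000, dgfree_w:  0.000, dgref_c: -0.35, dgfree_c: -0.35, rvdw: 1.70, mass: 12.011}
  CH1E: {volume: 23.7, lambda: 3.5, dgref_w: -0.187, dgfree_w: -0.187, dgref_c: -0.55, dgfree_c: -0.55, rvdw: 2.00, mass: 13.019}
  CH2E: {volume: 22.4, lambda: 3.5, dgref_w:  0.372, dgfree_w:  0.372, dgref_c: -0.40, dgfree_c: -0.40, rvdw: 2.00, mass: 14.027}
  CH3E: {volume: 30.0, lambda: 3.5, dgref_w:  1.089, dgfree_w:  1.089, dgref_c: -0.70, dgfree_c: -0.70, rvdw: 2.00, mass: 15.035}
  CR1E: {volume: 18.4, lambda: 3.5, dgref_w:  0.057, dgfree_w:  0.080, dgref_c: -0.50, dgfree_c: -0.50, rvdw: 1.85, mass: 13.019}
  "N":  {volume:  4.4, lambda: 3.5, dgref_w: -1.550, dgfree_w: -1.550, dgref_c: -0.60, dgfree_c: -0.60, rvdw: 1.55, mass: 14.007}
  NH1:  {volume:  4.4, lambda: 3.5, dgref_w: -5.950, dgfree_w: -8.900, dgref_c: -1.30, dgfree_c: -1.90, rvdw: 1.55, mass: 15.015}
  NR:   {volume:  4.4, lambda: 3.5, dgref_w: -3.820, dgfree_w: -4.654, dgref_c: -1.10, dgfree_c: -1.30, rvdw: 1.55, mass: 14.007}
  NH2:  {volume: 11.2, lambda: 3.5, dgref_w: -5.450, dgfree_w: -7.800, dgref_c: -1.40, dgfree_c: -2.00, rvdw: 1.55, mass: 16.023}
  NH3:  {volume: 11.2, lambda: 6.0, dgref_w: -20.00, dgfree_w: -20.00, dgref_c: -2.50, dgfree_c: -2.50, rvdw: 1.55, mass: 17.031}
  NC2:  {volume: 11.2, lambda: 6.0, dgref_w: -10.00, dgfree_w: -10.00, dgref_c: -2.00, dgfree_c: -2.00, rvdw: 1.55, mass: 16.023}
  O:    {volume: 10.8, lambda: 3.5, dgref_w: -5.330, dgfree_w: -5.330, dgref_c: -1.20, dgfree_c: -1.20, rvdw: 1.52, mass: 15.999}
  OC:   {volume: 10.8, lambda: 6.0, dgref_w: -10.00, dgfree_w: -10.00, dgref_c: -1.80, dgfree_c: -1.80, rvdw: 1.52, mass: 15.999}
  OH1:  {volume: 10.8, lambda: 3.5, dgref_w: -5.920, dgfree_w: -6.700, dgref_c: -1.60, dgfree_c: -2.00, rvdw: 1.52, mass: 17.007}
  S:    {volume: 14.7, lambda: 3.5, dgref_w: -3.240, dgfree_w: -4.100, dgref_c: -1.90, dgfree_c: -2.10, rvdw: 1.80, mass: 32.060}
  SH1E: {volume: 21.4, lambda: 3.5, dgref_w: -2.050, dgfree_w: -2.700, dgref_c: -1.50, dgfree_c: -1.70, rvdw: 1.90, mass: 33.068}
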