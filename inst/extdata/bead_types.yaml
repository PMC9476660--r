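# Coarse-grained bead type registry: 40 types spanning the four polarity
# classes (apolar C*, intermediate N*, polar P*, charged Q*), their
# small/ring S-variants, and auxiliary variant slots (AC1, AC2, BP1, BP4).
# The solvation parameter table is dimensioned over exactly these 40 types
# for the two environments (water, cyclohexane) and the four tunable
# parameters, giving the 40 x 2 x 4 = 320 slot layout.
# charge in elementary units; mass in amu (ring beads are lighter).
types:
  - {name: P5,   class: polar,        charge:  0, ring: false, mass: 72}
  - {name: P4,   class: polar,        charge:  0, ring: false, mass: 72}
  - {name: P3,   class: polar,        charge:  0, ring: false, mass: 72}
  - {name: P2,   class: polar,        charge:  0, ring: false, mass: 72}
  - {name: P1,   class: polar,        charge:  0, ring: false, mass: 72}
  - {name: Nda,  class: intermediate, charge:  0, ring: false, mass: 72}
  - {name: Nd,   class: intermediate, charge:  0, ring: false, mass: 72}
  - {name: Na,   class: intermediate, charge:  0, ring: false, mass: 72}
  - {name: N0,   class: intermediate, charge:  0, ring: false, mass: 72}
  - {name: C5,   class: apolar,       charge:  0, ring: false, mass: 72}
  - {name: C4,   class: apolar,       charge:  0, ring: false, mass: 72}
  - {name: C3,   class: apolar,       charge:  0, ring: false, mass: 72}
  - {name: C2,   class: apolar,       charge:  0, ring: false, mass: 72}
  - {name: C1,   class: apolar,       charge:  0, ring: false, mass: 72}
  - {name: Qda,  class: charged,      charge:  0, ring: false, mass: 72}
  - {name: Qd,   class: charged,      charge:  1, ring: false, mass: 72}
  - {name: Qa,   class: charged,      charge: -1, ring: false, mass: 72}
  - {name: Q0,   class: charged,      charge:  1, ring: false, mass: 72}
  - {name: SP5,  class: polar,        charge:  0, ring: true,  mass: 45}
  - {name: SP4,  class: polar,        charge:  0, ring: true,  mass: 45}
  - {name: SP3,  class: polar,        charge:  0, ring: true,  mass: 45}
  - {name: SP2,  class: polar,        charge:  0, ring: true,  mass: 45}
  - {name: SP1,  class: polar,        charge:  0, ring: true,  mass: 45}
  - {name: SNda, class: intermediate, charge:  0, ring: true,  mass: 45}
  - {name: SNd,  class: intermediate, charge:  0, ring: true,  mass: 45}
  - {name: SNa,  class: intermediate, charge:  0, ring: true,  mass: 45}
  - {name: SN0,  class: intermediate, charge:  0, ring: true,  mass: 45}
  - {name: SC5,  class: apolar,       charge:  0, ring: true,  mass: 45}
  - {name: SC4,  class: apolar,       charge:  0, ring: true,  mass: 45}
  - {name: SC3,  class: apolar,       charge:  0, ring: true,  mass: 45}
  - {name: SC2,  class: apolar,       charge:  0, ring: true,  mass: 45}
  - {name: SC1,  class: apolar,       charge:  0, ring: true,  mass: 45}
  - {name: SQda, class: charged,      charge:  0, ring: true,  mass: 45}
  - {name: SQd,  class: charged,      charge:  1, ring: true,  mass: 45}
  - {name: SQa,  class: charged,      charge: -1, ring: true,  mass: 45}
  - {name: SQ0,  class: charged,      charge:  1, ring: true,  mass: 45}
  - {name: AC1,  class: apolar,       charge:  0, ring: false, mass: 72}
  - {name: AC2,  class: apolar,       charge:  0, ring: false, mass: 72}
  - {name: BP1,  class: polar,        charge:  0, ring: false, mass: 72}
  - {name: BP4,  class: polar,        charge:  0, ring: false, mass: 72}
lennard_jones:
  sigma: 4.7        # A, regular pairs
  sigma_ring: 4.3   # A, when both partners are ring beads
  ring_scale: 0.75  # epsilon scale for ring-ring pairs
  # class-level well depths, kcal/mol (hydrophobic effect encoded as weak
  # polar-apolar cross interactions, strong polar-polar/polar-charged)
  epsilon:
    apolar:       {apolar: 0.836, intermediate: 0.645, polar: 0.478, charged: 0.478}
    intermediate: {apolar: 0.645, intermediate: 0.836, polar: 0.956, charged: 0.956}
    polar:        {apolar: 0.478, intermediate: 0.956, polar: 1.147, charged: 1.338}
    charged:      {apolar: 0.478, intermediate: 0.956, polar: 1.338, charged: 0.836}
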