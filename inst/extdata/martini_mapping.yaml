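# Residue -> coarse-grained bead mapping in the style of the MARTINI 2.x
# protein force field: one backbone bead (BB) per residue built from the
# peptide unit (plus CB for alanine), and 0-4 side-chain beads (SC1..SC4).
# Each atom entry is [pdb_atom_name, united_atom_type]; united-atom types
# key into the atomic solvation table.  Glycine and alanine map to a single
# bead.  The backbone bead is typed P5 for every residue; secondary
# structure enters through bonded parameters, not bead identity.
residues:
  GLY:
    - {label: BB, type: P5, atoms: [["N", NH1], [CA, CH2E], [C, C], [O, O]]}
  ALA:
    - {label: BB, type: P5, atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O], [CB, CH3E]]}
  CYS:
    - {label: BB,  type: P5, atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: C5, atoms: [[CB, CH2E], [SG, SH1E]]}
  VAL:
    - {label: BB,  type: P5, atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: C2, atoms: [[CB, CH1E], [CG1, CH3E], [CG2, CH3E]]}
  LEU:
    - {label: BB,  type: P5, atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: C1, atoms: [[CB, CH2E], [CG, CH1E], [CD1, CH3E], [CD2, CH3E]]}
  ILE:
    - {label: BB,  type: P5, atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: C1, atoms: [[CB, CH1E], [CG1, CH2E], [CG2, CH3E], [CD1, CH3E]]}
  MET:
    - {label: BB,  type: P5, atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: C5, atoms: [[CB, CH2E], [CG, CH2E], [SD, S], [CE, CH3E]]}
  PRO:
    - {label: BB,  type: P5, atoms: [["N", "N"], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: C3, atoms: [[CB, CH2E], [CG, CH2E], [CD, CH2E]]}
  SER:
    - {label: BB,  type: P5, atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: P1, atoms: [[CB, CH2E], [OG, OH1]]}
  THR:
    - {label: BB,  type: P5, atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: P1, atoms: [[CB, CH1E], [OG1, OH1], [CG2, CH3E]]}
  ASN:
    - {label: BB,  type: P5, atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: P5, atoms: [[CB, CH2E], [CG, C], [OD1, O], [ND2, NH2]]}
  GLN:
    - {label: BB,  type: P5, atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: P4, atoms: [[CB, CH2E], [CG, CH2E], [CD, C], [OE1, O], [NE2, NH2]]}
  ASP:
    - {label: BB,  type: P5, atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: Qa, atoms: [[CB, CH2E], [CG, C], [OD1, OC], [OD2, OC]]}
  GLU:
    - {label: BB,  type: P5, atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: Qa, atoms: [[CB, CH2E], [CG, CH2E], [CD, C], [OE1, OC], [OE2, OC]]}
  LYS:
    - {label: BB,  type: P5, atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: C3, atoms: [[CB, CH2E], [CG, CH2E], [CD, CH2E]]}
    - {label: SC2, type: Qd, atoms: [[CE, CH2E], [NZ, NH3]]}
  ARG:
    - {label: BB,  type: P5, atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: N0, atoms: [[CB, CH2E], [CG, CH2E], [CD, CH2E]]}
    - {label: SC2, type: Qd, atoms: [[NE, NH1], [CZ, C], [NH1, NC2], [NH2, NC2]]}
  HIS:
    - {label: BB,  type: P5,  atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: SC4, atoms: [[CB, CH2E], [CG, CR]]}
    - {label: SC2, type: SP1, atoms: [[CD2, CR1E], [NE2, NR]]}
    - {label: SC3, type: SP1, atoms: [[ND1, NH1], [CE1, CR1E]]}
  PHE:
    - {label: BB,  type: P5,  atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: SC5, atoms: [[CB, CH2E], [CG, CR]]}
    - {label: SC2, type: SC5, atoms: [[CD1, CR1E], [CE1, CR1E]]}
    - {label: SC3, type: SC5, atoms: [[CD2, CR1E], [CE2, CR1E], [CZ, CR1E]]}
  TYR:
    - {label: BB,  type: P5,  atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: SC4, atoms: [[CB, CH2E], [CG, CR]]}
    - {label: SC2, type: SC4, atoms: [[CD1, CR1E], [CE1, CR1E]]}
    - {label: SC3, type: SP1, atoms: [[CD2, CR1E], [CE2, CR1E], [CZ, CR], [OH, OH1]]}
  TRP:
    - {label: BB,  type: P5,  atoms: [["N", NH1], [CA, CH1E], [C, C], [O, O]]}
    - {label: SC1, type: SC4, atoms: [[CB, CH2E], [CG, CR]]}
    - {label: SC2, type: SNd, atoms: [[CD1, CR1E], [NE1, NH1], [CE2, CR]]}
    - {label: SC3, type: SC5, atoms: [[CD2, CR], [CE3, CR1E], [CZ3, CR1E]]}
    - {label: SC4, type: SC5, atoms: [[CZ2, CR1E], [CH2, CR1E]]}
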