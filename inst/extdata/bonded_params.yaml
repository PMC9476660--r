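# Bonded parameter set for the coarse-grained protein backbone and side
# chains.  Functional forms used by the engine:
#   bond      E = k (r - theta r0)^2            k in kcal/mol/A^2
#   angle     E = k (cos th - cos th0)^2        k in kcal/mol
#   dihedral  E = k (1 + cos(m phi - phi_s))    k in kcal/mol, phi_s in deg
# Backbone equilibrium values are secondary-structure dependent (H/E/C from
# the per-residue annotation); minima are consistent with ideal CG helix
# (rise 1.5 A, twist 100 deg, radius 2.3 A) and extended-strand geometry.
# The file is input data and may be replaced by a full published set.
backbone:
  bond:
    H: {r0: 3.83, k: 1.50}
    E: {r0: 3.86, k: 1.50}
    C: {r0: 3.50, k: 1.50}
  angle:
    H: {theta0: 91.0,  k: 20.0}
    E: {theta0: 118.0, k: 10.0}
    C: {theta0: 127.0, k: 3.0}
  dihedral:           # phi_s = phi_min - 180 for the m = 1 cosine form
    H: {phi_s: -130.0, k: 10.0, mult: 1}
    E: {phi_s: 0.0,   k: 2.0,  mult: 1}
    # coil: no backbone dihedral
sidechain:
  default_bond_k: 1.25
  bonds:            # [from_label, to_label, r0]
    CYS: [[BB, SC1, 3.10]]
    VAL: [[BB, SC1, 2.65]]
    LEU: [[BB, SC1, 3.30]]
    ILE: [[BB, SC1, 3.10]]
    MET: [[BB, SC1, 4.00]]
    PRO: [[BB, SC1, 3.00]]
    SER: [[BB, SC1, 2.50]]
    THR: [[BB, SC1, 2.60]]
    ASN: [[BB, SC1, 3.20]]
    GLN: [[BB, SC1, 4.00]]
    ASP: [[BB, SC1, 3.20]]
    GLU: [[BB, SC1, 4.00]]
    LYS: [[BB, SC1, 3.30], [SC1, SC2, 2.80]]
    ARG: [[BB, SC1, 3.30], [SC1, SC2, 3.40]]
    HIS: [[BB, SC1, 3.10], [SC1, SC2, 2.70], [SC1, SC3, 2.70], [SC2, SC3, 2.70]]
    PHE: [[BB, SC1, 3.10], [SC1, SC2, 2.70], [SC1, SC3, 2.70], [SC2, SC3, 2.70]]
    TYR: [[BB, SC1, 3.20], [SC1, SC2, 2.70], [SC1, SC3, 2.70], [SC2, SC3, 2.70]]
    TRP: [[BB, SC1, 3.00], [SC1, SC2, 2.70], [SC2, SC3, 2.70], [SC3, SC4, 2.80], [SC2, SC4, 2.70]]
chain_break_threshold: 5.0   # A; consecutive backbone beads farther apart
                             # than this get no bonded terms (warned)
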