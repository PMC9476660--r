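---
title: "A coarse-grained implicit water-membrane model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained implicit water-membrane model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgimm)
```

## The model

`cgimm` combines three well-established ingredients into one force field
for membrane proteins: a residue-based coarse-grained protein
representation in the MARTINI tradition, a Gaussian solvent-exclusion
implicit solvation term in the EEF1 tradition, and an IMM1-style implicit
membrane.  The package's contribution is the integrated energy model with
analytic forces, the Langevin propagator, the trajectory fitness score and
the genetic-algorithm machinery for fitting the solvation parameters —
everything a desk-scale study of the model's behaviour needs, with no
external downloads.

### Coarse-grained topology

Every residue contributes one backbone bead (the peptide unit N, CA, C, O;
alanine's CB folds into it) and up to four side-chain beads; each bead sits
at the centre of mass of its constituent heavy atoms, hydrogens ignored.
The mapping ships as an editable YAML data file.  Two deliberate
simplifications are documented here rather than hidden: the backbone bead
is typed `P5` (polar) for every residue and every secondary structure —
in MARTINI 2.x the backbone bead identity changes with secondary
structure, which would make the parameter table's composition depend on
the annotation — and termini carry their residue's standard bead type.
Secondary structure therefore enters only through the bonded parameters
(helix/strand/coil equilibrium values for the backbone bond, angle and
dihedral) and through the fitness metrics.  The bonded parameter file is
input data; its equilibrium geometry is consistent with the ideal
coarse-grained helix (rise 1.5 Å/residue, twist 100°, radius 2.3 Å; 1–4
distance 6.20 Å, backbone dihedral +50.0°) and extended-strand geometry,
so the synthetic fixtures are near their own force-field minima.  Users
with access to a full published parameter set can substitute it file for
file.

A chain break — consecutive backbone beads more than 5 Å apart — omits
the bonded terms across the gap with a warning, instead of creating an
absurd spring.

### Solvation and the implicit membrane

The solvation free energy of bead *i* is its reference value minus what
its neighbours occlude:

$$\Delta G_i = \Delta G_i^{\mathrm{ref}}(z_i)
  - \sum_{j \ne i,\; r_{ij} \le 16\,\text{Å}} h_i(r_{ij})\, V_j, \qquad
  h_i(r) = \frac{\alpha_i}{4\pi r^2}
  \exp\!\left[-\left(\frac{r - R_i}{\lambda_i}\right)^2\right],\quad
  \alpha_i = \frac{2\,\Delta G_i^{\mathrm{free}}}{\sqrt{\pi}\,\lambda_i}.$$

The occlusion follows the EEF1 convention: the occluder contributes its
solvation volume $V_j$, while the Gaussian density carries the solvated
bead's parameters.  This product form is a midpoint approximation of the
density integral over the occluded region; the test suite quantifies its
accuracy against an adaptive quadrature oracle (see *Numerical choices*).

The membrane is a slab of hydrophobic thickness $T$ normal to $z$ and
centred at $z = 0$.  Each bead's environment follows the switching
function $f(z') = z'^n/(1+z'^n)$ with $z' = |z|/(T/2)$; $f$ is exactly 0.5
at the interface and, with the default steepness $n = 10$, completes its
0.1→0.9 rise within $\tfrac{T}{2}(9^{1/10} - 9^{-1/10})$ ≈ 5.76 Å for
$T = 26$ Å.  The reference free energy interpolates linearly in $f$
between the water and cyclohexane columns of the parameter table.  The
same interpolation is applied to $\Delta G^{\mathrm{free}}$, $\lambda$ and
$V$ (the table's other tunables), because bead properties should change
smoothly across the interface; a `ref`-only mode
(`interp_all = FALSE`) reproduces the stricter original-IMM1 convention
where only the reference term is position dependent.  The bead radius $R$
is fixed (it derives from van der Waals geometry, not thermodynamics).
$T$ is a plain configuration number — per-protein hydrophobic thicknesses
in the OPM convention are typical inputs — and there are no periodic
boundary conditions: with no explicit solvent there is no box to wrap.

Electrostatics act only between charged beads and use a
distance-dependent dielectric $\varepsilon = r^{p}$ with
$p = a + (1-a)\sqrt{f_i f_j}$ and $a = 0.85$: in bulk water ($f = 1$) this
is exactly the familiar $\varepsilon = r$ screening, while deep in the
membrane $\varepsilon = r^{0.85}$, strengthening charge–charge
interactions where no water screens them.  The Coulomb constant is
332.0636 kcal·Å/(mol·e²).  Lennard-Jones and electrostatic terms use
CHARMM-style energy switching on 12–14 Å (energy and force continuous at
both bounds); the solvation sum is truncated at 16 Å.  Bonded 1–2 and 1–3
pairs are excluded from the nonbonded terms, 1–4 pairs included.

### Parameter table, seeding and genome encoding

The table holds $V$, $\lambda$, $\Delta G^{\mathrm{ref}}$,
$\Delta G^{\mathrm{free}}$ for 40 bead types × 2 environments — 320
tunable slots.  Initial values are built from a united-atom table: $V$
and the free energies add over a bead's constituent atoms; $\lambda$ is
the volume-weighted mean (a correlation length is not additive — summing
lengths would be dimensionally indefensible, so additivity is deliberately
not applied to it); $R$ is the radius of the sphere holding the summed
van der Waals volumes.  Bead types that several residues share are
averaged over their occurrences; types unused by the protein mapping are
filled from their polarity-class mean so the full 320-slot table is always
populated.  The shipped united-atom table follows published EEF1
magnitudes for water; its cyclohexane column is a synthetic set built
from water-to-cyclohexane transfer trends and is explicitly marked
replaceable.  Temperature corrections are omitted — the table is valid at
298 K, the only temperature the dynamics protocol targets.

Slots are grouped into free parameters for optimization: identity
grouping (320 genes), polarity-class grouping (32 genes), or a coarse
6-gene scheme ($V$; $\lambda$; the two free energies split by
environment).  Group membership is data, not code, and grouped slots
share one genome value exactly.  Per-gene candidate grids are discrete:
multiplicative around the seeded mean for the positive-definite $V$ and
$\lambda$, additive for the free energies.

### Dynamics

The Langevin equation is integrated with the BAOAB splitting at
temperature 298 K, friction γ = 50 ps⁻¹ and time step 20 fs.  That
friction is unusually strong — γ·dt = 1 — which is precisely why BAOAB
was chosen: its configurational sampling stays accurate at large γ·dt,
and at γ = 0 it reduces to velocity Verlet (the suite verifies < 0.1 %
energy drift over 10⁴ steps in that limit, equipartition of a harmonic
degree of freedom to within three standard errors over 10⁶ steps, and a
mean kinetic temperature within 3 K of target).  Bead masses default to
the sum of constituent atomic masses (a uniform-mass mode is available);
initial velocities are Maxwell–Boltzmann; all randomness flows from one
seed through R's RNG, so trajectories are bit-reproducible.  No
constraints are applied; the bonded springs are soft enough for a 20 fs
step.  Blow-ups (non-finite energy or runaway coordinates) abort with the
failing step index.

### Fitness

The printed form of the per-protein fitness combines mean trajectory
RMSD (backbone beads, frame-wise Kabsch superposition), the relative
drift of the radius of gyration from the reference structure, and the
relative deviations of the 1–4 backbone distances and dihedrals from
their per-class reference values (helix 58.8°/5.8 Å, sheet 172°/10.3 Å),
with weights 1.0 Å⁻¹, 3.0, 2.0 and 2.0.  The package maps that weighted
deviation sum $S$ to $F = 1/(1+S)$: $F = 1$ exactly when every deviation
vanishes, $F$ decreases strictly in each component, and values are
comparable across proteins — the properties the optimizer needs.
Dihedrals are compared as folded magnitudes (the reference values are
means of folded distributions); deviations average over every saved frame
and window with uniform weight; a protein without helix or sheet windows
simply contributes nothing for the missing class.  The training-set score
is the geometric mean of the per-protein values, so one collapsing
protein annihilates the aggregate rather than being averaged away.

### Genetic algorithm

A generational μ+λ scheme with the reference protocol's settings as
defaults: constant population 100, at most 200 generations, tournament
selection (size 3 — the protocol specifies only "a small number"),
two-point crossover (the era-standard operator), 5 % per-gene mutation by
redrawing from the gene's candidate grid, and survivor truncation over
the combined parent+child pool — the strictest reading of children
competing with parents, which also makes the best-so-far fitness provably
non-decreasing.  Every genome ever evaluated is memoized, so the number
of MD evaluations equals the number of distinct genomes; children that
duplicate a living genome or the cache are re-varied up to a bounded
number of retries, after which the duplicate is accepted with a warning
(relevant only when a small genome space is nearly exhausted).  The run
stops at the generation cap or when the relative change of the mean
fitness over five generations falls below 10⁻³ (the protocol names no
number; this is the package's choice).  A diverging MD evaluation scores
fitness 0 and is annihilated by the geometric mean.

## Synthetic fixtures and what they do (not) show

The generators produce an ideal helix, an ideal strand, a β-hairpin, a
membrane-centred polyleucine helix (backbone + side-chain beads), a
C3-symmetric trimer of that helix at 8 Å axis radius — a minimal stand-in
for trimeric membrane proteins — and a self-avoiding random coil.  Each
fixture returns reference metrics computed from its generating geometry
(closed-form 1–4 distance, exact radius of gyration), which the test
suite cross-checks against the measurement code to 10⁻⁸.  The toy
training manifest mirrors a nine-protein set: two water-soluble entries
(thickness 0 = no membrane), four single-chain transmembrane helices and
three trimers with per-entry thicknesses of 24–30 Å.

These fixtures have idealized geometry, poly-Leu/poly-Ala composition, no
loops, no charged surface patterns and no experimental disorder.  Tests
passing on them demonstrate internal correctness of the energy terms,
integrator, metrics and optimizer — not that the shipped parameter data
reproduce experimental membrane-protein behaviour.  Conclusions about
real proteins require the full published parameter tables and
substantially longer simulations than the desk-scale defaults.

## Numerical choices

* **Solvation pair term vs quadrature.**  The package evaluates the EEF1
  point form $h_i(r_{ij}) V_j$.  The independent oracle integrates the
  Gaussian density over the occluder's volume-equivalent sphere by
  adaptive quadrature.  On two-bead energies the two agree to about 1 %
  at the representative separation $r = R + \lambda$, but the midpoint
  character of the point form makes the disagreement grow toward contact
  (several per cent for realistically sized beads, order 10 % on the
  correction term alone).  The suite therefore locks the measured
  accuracy at $r = R + \lambda$ and documents — rather than hides — that
  sub-1 % agreement across the whole $[R, R+4\lambda]$ range is not a
  property the point approximation possesses.
* **Energy minimization** is adaptive steepest descent (energy
  non-increasing by construction); it is a pre-dynamics relaxer, not an
  optimizer of record.
* **Angles** use the cosine-harmonic form, which is finite and smooth at
  collinear geometry; dihedrals over collinear backbone segments are
  undefined and the window is skipped.
* **Switching** is CHARMM-style energy switching; at the outer cutoff
  both the energy and its derivative vanish, so forces are continuous.
* **Desk-scale sizes.**  The shipped demos and tests use 5–25 residues
  per chain, 10³–10⁶ step runs and a 6-gene optimization with a
  population of 6–100; these sizes were chosen so the full validation
  suite completes on a single CPU while still exercising every code
  path (the reference protocol's 10 ns evaluations and 100-residue
  proteins are configuration values, not limits of the implementation).

## Known limitations

Single flat membrane slab only (no curvature, no dipole potential, no
multi-slab systems); no Ewald/PME (by design — no periodic box); protein
beads only (no lipids, nucleic acids, ligands); secondary structure is
an input annotation, never inferred; the 298 K-only parameter table; and
the shipped LJ/bonded/atomic data files are approximate transcriptions
intended as replaceable inputs, not as a validated re-release of any
published force field.
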