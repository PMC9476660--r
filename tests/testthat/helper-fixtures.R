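# shared builders for the test suite

default_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- init_from_atomic()
    tab
  }
})

# bare structure from explicit bead coordinates (single chain, BB beads)
bare_cg <- function(xyz, types = "P5", resname = "GLY", chain = "A") {
  n <- nrow(xyz)
  reg <- bead_type_registry()
  types <- rep_len(types, n)
  beads <- data.frame(
    id = seq_len(n), chain = rep_len(chain, n), resid = seq_len(n),
    resname = rep_len(resname, n), label = rep_len("BB", n), type = types,
    charge = reg$charge[match(types, reg$name)],
    mass = reg$mass[match(types, reg$name)],
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
  cgimm:::new_cg_structure(beads)
}

# random membrane-spanning structure with charged beads, min separation kept
random_membrane_cg <- function(n = 30, seed = 1, with_bonds = TRUE) {
  reg <- bead_type_registry()
  set.seed(seed)
  types <- sample(reg$name, n, replace = TRUE,
                  prob = ifelse(reg$charge != 0, 3, 1))
  repeat {
    xyz <- cbind(runif(n, -8, 8), runif(n, -8, 8), runif(n, -15, 15))
    if (min(dist(xyz)) > 2.0) break
  }
  cg <- bare_cg(xyz, types = types)
  if (with_bonds)
    cg$bonds <- data.frame(i = 1:(n - 1), j = 2:n, r0 = 3.5,
                           k = 1.5)[seq(1, n - 1, by = 3), ]
  cg
}

# Gaussian solvation free-energy density (independent re-statement used by
# the quadrature oracle): h(r) = 2 dgfree / (sqrt(pi) lam) / (4 pi r^2)
# exp(-((r - R)/lam)^2)
h_density <- function(r, dgfree, lam, R) {
  2 * dgfree / (sqrt(pi) * lam) / (4 * pi * r^2) * exp(-((r - R) / lam)^2)
}

# integral of a radial function over a sphere of radius a centred at
# distance d from the origin (exact reduction of the 3D integral)
sphere_quadrature <- function(F, d, a, rel.tol = 1e-10) {
  integrand <- function(r) r * F(r) * (a^2 - (d - r)^2)
  (pi / d) * integrate(integrand, max(d - a, 1e-9), d + a,
                       rel.tol = rel.tol)$value
}

# minimal all-atom PDB text fixtures
write_minimal_pdb <- function(path, lines) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, alt = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, alt, resname, chain, resno, x, y, z, occ, 0)
}

# ideal helix coordinates (independent of make_fixture internals)
helix_coords <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  th <- (seq_len(n) - 1) * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), (seq_len(n) - 1) * rise)
}
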