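#' Implicit membrane model
#'
#' The membrane is a hydrophobic slab of thickness `thickness` (A) normal
#' to z and centred at z = 0.  Each bead's environment is set by the
#' switching function f(z') = z'^n / (1 + z'^n) with z' = |z|/(T/2): f = 0
#' in the membrane core, 0.5 at the interface |z| = T/2 and f -> 1 in bulk
#' water.  `a` is the dielectric attenuation exponent: the electrostatic
#' screening is eps = r^p with p = a + (1-a) sqrt(f_i f_j), so eps = r in
#' water and eps = r^a deep in the membrane.
#'
#' @param thickness hydrophobic thickness T, A (> 0); use `NULL` for a pure
#'   water environment
#' @param n switching steepness exponent (default 10)
#' @param a dielectric exponent parameter (default 0.85)
#' @return object of class `membrane_model`
#' @export
membrane_model <- function(thickness, n = 10, a = 0.85) {
  if (is.null(thickness)) {
    return(structure(list(on = FALSE, thickness = 0, n = n, a = a),
                     class = "membrane_model"))
  }
  stopifnot(thickness > 0, n >= 1, a > 0, a <= 1)
  structure(list(on = TRUE, thickness = thickness, n = n, a = a),
            class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  if (!x$on) cat("No membrane (bulk water environment)\n")
  else cat("Implicit membrane: thickness", x$thickness, "A, n =", x$n,
           ", a =", x$a, "\n")
  invisible(x)
}

#' Membrane switching function
#'
#' @param z z-coordinate(s), A
#' @param membrane a `membrane_model`
#' @return f in `[0, 1]`; 1 everywhere if the membrane is off
#' @export
switching_f <- function(z, membrane) {
  if (!membrane$on) return(rep(1, length(z)))
  .cg_switching_cpp(as.numeric(z), membrane$thickness, membrane$n)
}

#' Interpolate a bead property between environments
#'
#' Returns `f * water + (1 - f) * chex`, the smooth water/membrane
#' interpolation applied to the per-environment solvation parameters.
#'
#' @param water,chex property values in the two bulk environments
#' @param f switching-function value(s) in `[0, 1]`
#' @return interpolated value(s)
#' @export
env_value <- function(water, chex, f) {
  stopifnot(all(f >= 0 & f <= 1))
  f * water + (1 - f) * chex
}

#' Compile a structure + parameters into the form the engine consumes
#' @keywords internal
#' @noRd
compile_system <- function(cg, table, membrane = membrane_model(NULL),
                           components = c("bond", "angle", "dihedral",
                                          "lj", "elec", "solvation"),
                           interp_all = TRUE, r_on = 12, r_off = 14,
                           cut_solv = 16, restraints = NULL,
                           mass_mode = c("constituent", "uniform")) {
  mass_mode <- match.arg(mass_mode)
  beads <- cg$beads
  n <- nrow(beads)
  reg <- bead_type_registry()
  tidx <- match(beads$type, reg$name)
  if (anyNA(tidx))
    stop("bead type(s) absent from registry: ",
         paste(unique(beads$type[is.na(tidx)]), collapse = ", "))
  miss <- setdiff(beads$type, table$types)
  if (length(miss))
    stop("bead type(s) absent from parameter table: ",
         paste(miss, collapse = ", "))
  solv <- cbind(
    table$water[beads$type, "V"], table$chex[beads$type, "V"],
    table$water[beads$type, "lambda"], table$chex[beads$type, "lambda"],
    table$water[beads$type, "dgref"], table$chex[beads$type, "dgref"],
    table$water[beads$type, "dgfree"], table$chex[beads$type, "dgfree"],
    table$water[beads$type, "R"])
  if (anyNA(solv)) stop("parameter table has unpopulated slots")
  if (any(solv[, 1:4] <= 0) || any(solv[, 9] <= 0))
    stop("solvation parameters V, lambda and R must be positive")
  lj <- lj_tables()
  # 1-2 and 1-3 exclusions from the bond graph (LJ + electrostatics)
  nb <- nrow(cg$bonds)
  adj <- vector("list", n)
  if (nb > 0) {
    for (r in seq_len(nb)) {
      i <- cg$bonds$i[r]; j <- cg$bonds$j[r]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  ex <- list()
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      if (j > i) ex[[length(ex) + 1]] <- c(i, j)
      for (k in adj[[j]]) if (k > i) ex[[length(ex) + 1]] <- c(i, k)
    }
  }
  excl_pairs <- if (length(ex)) unique(do.call(rbind, ex)) else
    matrix(integer(), 0, 2)
  mass <- if (mass_mode == "uniform") reg$mass[tidx] else beads$mass
  zero_mat <- function(m) matrix(0, 0, m)
  bonds <- if ("bond" %in% components && nb > 0)
    cbind(cg$bonds$i - 1, cg$bonds$j - 1, cg$bonds$r0, cg$bonds$k) else
    zero_mat(4)
  angles <- if ("angle" %in% components && nrow(cg$angles) > 0)
    cbind(cg$angles$i - 1, cg$angles$j - 1, cg$angles$k - 1,
          cos(cg$angles$theta0 * pi / 180), cg$angles$kf) else zero_mat(5)
  dihedrals <- if ("dihedral" %in% components && nrow(cg$dihedrals) > 0)
    cbind(cg$dihedrals$i - 1, cg$dihedrals$j - 1, cg$dihedrals$k - 1,
          cg$dihedrals$l - 1, cg$dihedrals$phi_s * pi / 180,
          cg$dihedrals$kf, cg$dihedrals$mult) else zero_mat(7)
  eps <- if ("lj" %in% components) lj$epsilon else lj$epsilon * 0
  charge <- if ("elec" %in% components) beads$charge else rep(0, n)
  if (!"solvation" %in% components) {
    solv <- solv * 0
    solv[, 1:4] <- 1 # keep volumes and lambdas positive; dG terms vanish
    solv[, 9] <- 1
  }
  rmat <- if (is.null(restraints)) matrix(0, 0, 6) else {
    stopifnot(is.matrix(restraints), nrow(restraints) == n,
              ncol(restraints) == 6)
    restraints
  }
  list(type = as.integer(tidx - 1L), charge = as.numeric(charge),
       mass = as.numeric(mass), solv = solv,
       lj_eps = eps, lj_sig = lj$sigma,
       excl_pairs = matrix(as.integer(excl_pairs - 1L),
                           nrow = nrow(excl_pairs)),
       bonds = bonds, angles = angles, dihedrals = dihedrals,
       restraints = rmat,
       membrane = list(on = membrane$on, thickness = membrane$thickness,
                       n = membrane$n, a = membrane$a),
       interp_all = interp_all, r_on = r_on, r_off = r_off,
       cut_solv = cut_solv)
}

#' Total potential energy and analytic forces
#'
#' Evaluates the full model: harmonic bonds, cosine-harmonic angles,
#' periodic dihedrals, switched 12-6 Lennard-Jones (12-14 A), switched
#' Coulomb with the membrane-attenuated distance-dependent dielectric, and
#' the Gaussian solvent-exclusion solvation term with z-interpolated
#' reference free energies (16 A cutoff).
#'
#' @param cg a `cg_structure` with bonded terms built
#' @param table a populated `cg_parameter_table`
#' @param membrane a `membrane_model` (default: no membrane, bulk water)
#' @param interp_all interpolate dGfree, lambda and V between environments
#'   as well as dGref (`TRUE`, default); `FALSE` interpolates the reference
#'   term only
#' @param restraints optional n x 6 matrix of per-axis harmonic positional
#'   restraints (kx, ky, kz, x0, y0, z0), E = k (x - x0)^2
#' @param components which energy terms to evaluate
#' @return an `energy_report`: list with `total` (kcal/mol), `terms`
#'   (named decomposition), `per_bead_solvation` and `forces`
#'   (n x 3, kcal/mol/A)
#' @export
total_energy_forces <- function(cg, table, membrane = membrane_model(NULL),
                                interp_all = TRUE, restraints = NULL,
                                components = c("bond", "angle", "dihedral",
                                               "lj", "elec", "solvation")) {
  if (nrow(cg$beads) == 0) {
    return(structure(list(
      total = 0,
      terms = setNames(numeric(7), c("bond", "angle", "dihedral", "lj",
                                     "elec", "solvation", "restraint")),
      per_bead_solvation = numeric(0),
      forces = matrix(numeric(), 0, 3)), class = "energy_report"))
  }
  sys <- compile_system(cg, table, membrane, components = components,
                        interp_all = interp_all, restraints = restraints)
  res <- .cg_energy_cpp(sys, cg_xyz(cg))
  structure(res, class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat("Potential energy:", format(x$total, digits = 8), "kcal/mol\n")
  for (nm in names(x$terms))
    cat(sprintf("  %-10s %12.4f\n", nm, x$terms[[nm]]))
  invisible(x)
}

#' Individual energy terms
#'
#' Convenience wrappers evaluating a single component of the potential
#' (with its forces).  `solvation_energy` returns the implicit-solvation
#' term including the per-bead decomposition; `elec_energy` the switched
#' membrane-dielectric Coulomb term; `lj_energy` the switched
#' Lennard-Jones term; `bonded_energy` bonds + angles + dihedrals.
#'
#' @inheritParams total_energy_forces
#' @return an `energy_report` restricted to the requested term
#' @export
solvation_energy <- function(cg, table, membrane = membrane_model(NULL),
                             interp_all = TRUE) {
  total_energy_forces(cg, table, membrane, interp_all,
                      components = "solvation")
}

#' @rdname solvation_energy
#' @export
elec_energy <- function(cg, table, membrane = membrane_model(NULL)) {
  total_energy_forces(cg, table, membrane, components = "elec")
}

#' @rdname solvation_energy
#' @export
lj_energy <- function(cg, table, membrane = membrane_model(NULL)) {
  total_energy_forces(cg, table, membrane, components = "lj")
}

#' @rdname solvation_energy
#' @export
bonded_energy <- function(cg, table, membrane = membrane_model(NULL)) {
  total_energy_forces(cg, table, membrane,
                      components = c("bond", "angle", "dihedral"))
}
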