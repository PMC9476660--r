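#' Langevin dynamics configuration
#'
#' Defaults follow the model's reference protocol: 298 K, a friction of
#' 50 ps^-1 and a 20 fs time step.  This friction is deliberately strong
#' (gamma * dt = 1); the BAOAB splitting used by the integrator remains
#' accurate for configurational sampling in that regime.
#'
#' @param temperature target temperature, K
#' @param gamma friction coefficient, ps^-1 (0 gives the NVE limit)
#' @param dt time step, fs
#' @param n_steps number of steps
#' @param save_stride save every `save_stride`-th frame
#' @param seed RNG seed for velocities and the thermostat noise
#' @param mass_mode `"constituent"` (sum of mapped atom masses, default) or
#'   `"uniform"` (registry bead masses)
#' @return a `langevin_config` list
#' @export
langevin_config <- function(temperature = 298, gamma = 50, dt = 20,
                            n_steps = 1000, save_stride = 10, seed = 1,
                            mass_mode = c("constituent", "uniform")) {
  stopifnot(temperature > 0, gamma >= 0, dt > 0, n_steps >= 1,
            save_stride >= 1)
  structure(list(temperature = temperature, gamma = gamma, dt = dt,
                 n_steps = as.integer(n_steps),
                 save_stride = as.integer(save_stride), seed = seed,
                 mass_mode = match.arg(mass_mode)),
            class = "langevin_config")
}

KB_KCAL <- 0.0019872041  # kcal/mol/K
FCONV_ACC <- 4.184e-4    # (kcal/mol/A)/amu -> A/fs^2

#' Maxwell-Boltzmann velocities
#' @param mass bead masses, amu
#' @param temperature K
#' @return n x 3 matrix of velocities, A/fs
#' @keywords internal
maxwell_velocities <- function(mass, temperature) {
  n <- length(mass)
  sd <- sqrt(KB_KCAL * temperature * FCONV_ACC / mass)
  matrix(rnorm(3 * n, 0, rep(sd, 3)), n, 3)
}

#' Run Langevin dynamics
#'
#' Propagates the system with the BAOAB splitting of the Langevin equation:
#' deterministic forces from the full potential, friction and a
#' fluctuation-dissipation-consistent random force at the target
#' temperature.  With `gamma = 0` the scheme reduces to velocity Verlet.
#' Trajectories are reproducible for a given seed.
#'
#' @param cg a `cg_structure` with bonded terms built
#' @param table a `cg_parameter_table`
#' @param membrane a `membrane_model`
#' @param config a `langevin_config`
#' @param restraints optional n x 6 per-axis harmonic restraint matrix
#' @param start_vel optional n x 3 starting velocities (default: sampled
#'   from Maxwell-Boltzmann at the target temperature)
#' @param interp_all see [total_energy_forces()]
#' @return a `cg_trajectory`: list with `coords` (frames x beads x 3),
#'   `times` (ps), `kinetic`, `potential` (kcal/mol per frame),
#'   `kinetic_temperature` (K per frame), the final `xyz`/`vel`, `config`
#'   and `n_beads`
#' @export
run_langevin <- function(cg, table, membrane = membrane_model(NULL),
                         config = langevin_config(), restraints = NULL,
                         start_vel = NULL, interp_all = TRUE) {
  sys <- compile_system(cg, table, membrane, interp_all = interp_all,
                        restraints = restraints,
                        mass_mode = config$mass_mode)
  n <- nrow(cg$beads)
  set.seed(config$seed)
  vel <- if (is.null(start_vel))
    maxwell_velocities(sys$mass, config$temperature) else start_vel
  res <- .cg_langevin_cpp(sys, cg_xyz(cg), vel, config$dt,
                          config$gamma * 1e-3, # ps^-1 -> fs^-1
                          config$temperature, config$n_steps,
                          config$save_stride, TRUE)
  if (res$blow_step > 0)
    stop("dynamics diverged (non-finite energy or coordinates) at step ",
         res$blow_step)
  nf <- res$n_saved
  coords <- array(NA_real_, c(nf, n, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(res$frames[f, ], n, 3, byrow = TRUE)
  # frames are stored x1 y1 z1 x2 ... in the engine row
  ndof <- 3 * n
  structure(list(
    coords = coords,
    times = res$times[seq_len(nf)] / 1000, # fs -> ps
    kinetic = res$kinetic[seq_len(nf)],
    potential = res$potential[seq_len(nf)],
    kinetic_temperature = 2 * res$kinetic[seq_len(nf)] / (ndof * KB_KCAL),
    xyz = res$xyz, vel = res$vel,
    config = config, n_beads = n,
    table_hash = parameter_table_hash(table)),
    class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[1], "frames,", x$n_beads, "beads, t =",
      if (length(x$times)) round(max(x$times), 3) else 0, "ps\n")
  if (length(x$kinetic_temperature))
    cat("  mean kinetic temperature:",
        round(mean(x$kinetic_temperature), 1), "K\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`
#' @return integer
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' A short provenance hash of a parameter table
#' @param table a `cg_parameter_table`
#' @return character scalar
#' @export
parameter_table_hash <- function(table) {
  v <- c(as.matrix(table$water[, -1]), as.matrix(table$chex[, -1]))
  s <- paste(format(v, digits = 10), collapse = ",")
  # small rolling hash; provenance only, not cryptographic
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 268435456
  sprintf("%07x", h)
}

#' Energy minimization
#'
#' Adaptive steepest descent on the full potential; the energy is
#' non-increasing over accepted steps.
#'
#' @inheritParams run_langevin
#' @param max_iter iteration cap
#' @param force_tol convergence threshold on the largest force component,
#'   kcal/mol/A
#' @param step0 initial step, A
#' @return the structure with relaxed coordinates; attributes `energy` and
#'   `iterations`
#' @export
minimize <- function(cg, table, membrane = membrane_model(NULL),
                     restraints = NULL, max_iter = 500, force_tol = 1e-3,
                     step0 = 0.1, interp_all = TRUE) {
  sys <- compile_system(cg, table, membrane, interp_all = interp_all,
                        restraints = restraints)
  res <- .cg_minimize_cpp(sys, cg_xyz(cg), as.integer(max_iter), force_tol,
                          step0)
  out <- cg_set_xyz(cg, res$xyz)
  attr(out, "energy") <- res$energy
  attr(out, "iterations") <- res$iterations
  out
}
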