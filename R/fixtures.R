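#' Synthetic coarse-grained fixtures with known geometry
#'
#' Deterministic generators for test and demonstration structures:
#' \describe{
#'   \item{`ideal_helix`}{poly-alanine backbone on an ideal helix (rise
#'     1.5 A/residue, twist 100 deg, radius 2.3 A), labelled H}
#'   \item{`ideal_strand`}{extended zigzag backbone (3.3 A rise, 1.0 A
#'     lateral amplitude), labelled E}
#'   \item{`beta_hairpin`}{two antiparallel strands joined by a two-residue
#'     coil turn}
#'   \item{`tm_polyleucine`}{a polyleucine helix (backbone + side-chain
#'     beads) oriented along z and centred on the membrane midplane}
#'   \item{`tm_trimer`}{three tm_polyleucine copies with C3 symmetry about
#'     z at 8 A axis radius}
#'   \item{`random_coil`}{self-avoiding-ish random walk with fixed 3.5 A
#'     steps, labelled C}
#' }
#' Reference metrics (exact radius of gyration and, for the periodic
#' kinds, the closed-form 1-4 distance) are computed from the generating
#' geometry, independently of the measurement code in this package.
#'
#' @param kind fixture kind, see above
#' @param n residue count (per chain for the trimer); >= 5 for 1-4 metrics
#' @param rise,twist,radius helix parameters (A, degrees, A)
#' @param thickness membrane thickness used to centre/scale the
#'   transmembrane kinds, A
#' @param noise isotropic Gaussian positional noise sigma, A
#' @param seed RNG seed used when `noise > 0` or for `random_coil`
#' @return list with `cg` (a `cg_structure` with SS assigned and bonded
#'   terms built), `ss` (label string) and `reference` (named list of
#'   analytic metrics)
#' @export
make_fixture <- function(kind = c("ideal_helix", "ideal_strand",
                                  "beta_hairpin", "tm_polyleucine",
                                  "tm_trimer", "random_coil"),
                         n = 12, rise = 1.5, twist = 100, radius = 2.3,
                         thickness = 30, noise = 0, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n >= 5, noise >= 0)
  helix_xyz <- function(n, z0 = 0) {
    th <- (seq_len(n) - 1) * twist * pi / 180
    cbind(radius * cos(th), radius * sin(th),
          z0 + (seq_len(n) - 1) * rise)
  }
  strand_xyz <- function(n, x0 = 0, dir = 1, z0 = 0) {
    cbind(x0 + rep(c(1, -1), length.out = n), 0,
          z0 + dir * (seq_len(n) - 1) * 3.3)
  }
  d14_helix <- sqrt((4 * rise)^2 +
                      (2 * radius * sin(2 * twist * pi / 180))^2)
  build <- function(resnames, xyz_bb, ss, chains = NULL, sc = NULL) {
    # sc: optional list parallel to residues of side-chain coordinates
    reg <- bead_type_registry()
    mapping <- residue_mapping()
    atab <- atomic_solvation_table()
    rows <- list(); id <- 0
    nres <- length(resnames)
    if (is.null(chains)) chains <- rep("A", nres)
    for (r in seq_len(nres)) {
      beads <- mapping[[resnames[r]]]
      for (bi in seq_along(beads)) {
        b <- beads[[bi]]
        pos <- if (bi == 1) xyz_bb[r, ] else sc[[r]][[bi - 1]]
        mass <- sum(atab[b$atoms$ua_type, "mass"])
        id <- id + 1
        rows[[id]] <- data.frame(
          id = id, chain = chains[r], resid = r, resname = resnames[r],
          label = b$label, type = b$type,
          charge = reg$charge[match(b$type, reg$name)], mass = mass,
          x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
      }
    }
    cg <- new_cg_structure(do.call(rbind, rows))
    cg <- assign_ss_labels(cg, ss)
    build_bonded_terms(cg)
  }
  ref <- list()
  if (kind == "ideal_helix") {
    xyz <- helix_xyz(n)
    fx <- build(rep("ALA", n), xyz, paste(rep("H", n), collapse = ""))
    ref$d14 <- d14_helix
  } else if (kind == "ideal_strand") {
    xyz <- strand_xyz(n)
    fx <- build(rep("ALA", n), xyz, paste(rep("E", n), collapse = ""))
    ref$d14 <- 4 * 3.3
  } else if (kind == "beta_hairpin") {
    n1 <- floor((n - 2) / 2); n2 <- n - 2 - n1
    s1 <- strand_xyz(n1)
    top <- (n1 - 1) * 3.3
    turn <- rbind(c(3.0, 2.0, top + 1.8), c(6.0, 2.0, top + 1.8))
    s2 <- strand_xyz(n2, x0 = 8, dir = -1, z0 = top)
    xyz <- rbind(s1, turn, s2)
    ss <- paste(c(rep("E", n1), "C", "C", rep("E", n2)), collapse = "")
    fx <- build(rep("ALA", n), xyz, ss)
    ref$d14 <- 4 * 3.3
  } else if (kind == "tm_polyleucine") {
    z0 <- -(n - 1) * rise / 2 # centre the helix on the membrane midplane
    xyz <- helix_xyz(n, z0 = z0)
    sc <- sidechain_positions(xyz, "LEU")
    fx <- build(rep("LEU", n), xyz, paste(rep("H", n), collapse = ""),
                sc = sc)
    ref$d14 <- d14_helix
    ref$z_span <- c(z0, -z0)
  } else if (kind == "tm_trimer") {
    z0 <- -(n - 1) * rise / 2
    xyz1 <- helix_xyz(n, z0 = z0)
    all_bb <- list(); all_sc <- list(); chains <- character()
    for (c in 0:2) {
      phi <- c * 2 * pi / 3
      Rz <- matrix(c(cos(phi), sin(phi), 0, -sin(phi), cos(phi), 0,
                     0, 0, 1), 3, 3)
      shift <- c(8 * cos(phi), 8 * sin(phi), 0)
      bb <- sweep(xyz1 %*% Rz, 2, shift, "+")
      all_bb[[c + 1]] <- bb
      all_sc <- c(all_sc, sidechain_positions(bb, "LEU"))
      chains <- c(chains, rep(LETTERS[c + 1], n))
    }
    xyz <- do.call(rbind, all_bb)
    fx <- build(rep("LEU", 3 * n), xyz,
                paste(rep("H", 3 * n), collapse = ""), chains = chains,
                sc = all_sc)
    ref$d14 <- d14_helix
    ref$z_span <- c(z0, -z0)
  } else { # random_coil
    set.seed(seed)
    xyz <- matrix(0, n, 3)
    for (r in 2:n) {
      repeat {
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        cand <- xyz[r - 1, ] + 3.5 * dir
        if (r < 3 || min(sqrt(rowSums(sweep(xyz[1:(r - 2), , drop = FALSE],
                                            2, cand)^2))) > 3.8) break
      }
      xyz[r, ] <- cand
    }
    fx <- build(rep("GLY", n), xyz, paste(rep("C", n), collapse = ""))
  }
  if (noise > 0) fx <- perturb(fx, noise, seed)
  bbx <- cg_xyz(fx)[backbone_indices(fx), , drop = FALSE]
  # exact Rgyr of the generated backbone coordinates (unit masses)
  com <- colMeans(bbx)
  ref$rgyr_bb <- sqrt(mean(rowSums(sweep(bbx, 2, com)^2)))
  list(cg = fx, ss = paste(fx$ss, collapse = ""), reference = ref)
}

# deterministic outward-pointing side-chain positions for a helix backbone
sidechain_positions <- function(bb, resname, dist = 3.3) {
  n <- nrow(bb)
  ctr <- colMeans(bb)
  lapply(seq_len(n), function(r) {
    v <- bb[r, ] - c(ctr[1], ctr[2], bb[r, 3])
    nv <- sqrt(sum(v^2))
    v <- if (nv < 1e-8) c(1, 0, 0) else v / nv
    list(bb[r, ] + dist * v)
  })
}

#' Add isotropic Gaussian noise to bead positions
#'
#' Each coordinate receives N(0, sigma^2) noise; the expected unaligned
#' RMSD against the original is sigma * sqrt(3) (slightly less after
#' superposition).
#'
#' @param cg a `cg_structure`
#' @param sigma noise standard deviation per axis, A
#' @param seed RNG seed
#' @return the perturbed structure
#' @export
perturb <- function(cg, sigma, seed = 1) {
  if (sigma == 0) return(cg)
  set.seed(seed)
  xyz <- cg_xyz(cg)
  cg_set_xyz(cg, xyz + matrix(rnorm(length(xyz), 0, sigma), nrow(xyz), 3))
}

#' Toy training-set manifest
#'
#' Builds the nine-entry training set used for solvation-parameter
#' optimization demos: two water-soluble structures (no membrane), four
#' single-chain transmembrane helices and three C3-symmetric transmembrane
#' trimers, each with its membrane thickness (0 = no membrane).  With an
#' `outdir`, structures are written as CG PDB files together with a YAML
#' manifest; otherwise the manifest is returned in memory.
#'
#' @param outdir optional output directory
#' @param n_scale residue-count scale factor for quick demos
#' @return list of 9 entries: `name`, `kind`, `n`, `thickness`, `seed`
#'   (and `path`/`ss_path` when written); class `cg_manifest`
#' @export
make_training_manifest <- function(outdir = NULL, n_scale = 1) {
  sc <- function(n) max(5, round(n * n_scale))
  entries <- list(
    list(name = "sol_helix", kind = "ideal_helix", n = sc(14), thickness = 0),
    list(name = "sol_hairpin", kind = "beta_hairpin", n = sc(12), thickness = 0),
    list(name = "tm_helix_a", kind = "tm_polyleucine", n = sc(19), thickness = 26),
    list(name = "tm_helix_b", kind = "tm_polyleucine", n = sc(23), thickness = 30),
    list(name = "tm_helix_c", kind = "tm_polyleucine", n = sc(21), thickness = 28),
    list(name = "tm_helix_d", kind = "tm_polyleucine", n = sc(17), thickness = 24),
    list(name = "trimer_a", kind = "tm_trimer", n = sc(15), thickness = 26),
    list(name = "trimer_b", kind = "tm_trimer", n = sc(17), thickness = 30),
    list(name = "trimer_c", kind = "tm_trimer", n = sc(13), thickness = 24))
  entries <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]; e$seed <- i; e
  })
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    entries <- lapply(entries, function(e) {
      fx <- make_fixture(e$kind, n = e$n, seed = e$seed)
      e$path <- file.path(outdir, paste0(e$name, ".cgpdb"))
      e$ss_path <- file.path(outdir, paste0(e$name, ".ss"))
      write_cg_pdb(fx$cg, e$path)
      writeLines(fx$ss, e$ss_path)
      e
    })
    yaml::write_yaml(list(entries = entries),
                     file.path(outdir, "manifest.yaml"))
  }
  structure(entries, class = "cg_manifest")
}
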