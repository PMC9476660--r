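#' Coarse-grained bead type registry
#'
#' Returns the registry of the 40 bead types the model is dimensioned over:
#' name, polarity class (apolar / intermediate / polar / charged), default
#' charge, ring flag and mass.  The registry is read from the shipped
#' `bead_types.yaml` data file and cached.
#'
#' @return data.frame with columns `name`, `class`, `charge`, `ring`, `mass`
#' @export
#' @examples
#' nrow(bead_type_registry())  # 40
bead_type_registry <- function() {
  if (is.null(.cgimm_env$registry)) {
    raw <- yaml::read_yaml(cgimm_file("extdata", "bead_types.yaml"))
    df <- do.call(rbind, lapply(raw$types, function(t) {
      data.frame(name = t$name, class = t$class, charge = t$charge,
                 ring = t$ring, mass = t$mass, stringsAsFactors = FALSE)
    }))
    stopifnot(!anyDuplicated(df$name))
    .cgimm_env$registry <- df
    .cgimm_env$lj_raw <- raw$lennard_jones
  }
  .cgimm_env$registry
}

#' Pairwise Lennard-Jones parameter tables
#'
#' Builds the full pairwise well-depth and diameter tables over all bead
#' types from the class-level interaction matrix: ring-ring pairs use the
#' smaller diameter and a scaled well depth.
#'
#' @return list with matrices `epsilon` (kcal/mol) and `sigma` (Angstrom),
#'   dimension n_types x n_types, dimnames = type names
#' @export
lj_tables <- function() {
  reg <- bead_type_registry()
  lj <- .cgimm_env$lj_raw
  n <- nrow(reg)
  eps <- matrix(0, n, n, dimnames = list(reg$name, reg$name))
  sig <- matrix(lj$sigma, n, n, dimnames = list(reg$name, reg$name))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      e <- lj$epsilon[[reg$class[i]]][[reg$class[j]]]
      if (reg$ring[i] && reg$ring[j]) {
        e <- e * lj$ring_scale
        sig[i, j] <- lj$sigma_ring
      }
      eps[i, j] <- e
    }
  }
  list(epsilon = eps, sigma = sig)
}

#' United-atom solvation parameter input set
#'
#' Reads the shipped united-atom (EEF1-style) solvation table used to seed
#' the coarse-grained parameter table; see [init_from_atomic()].
#'
#' @param path optional path to a replacement YAML table
#' @return data.frame keyed by united-atom type with columns `volume`,
#'   `lambda`, `dgref_w`, `dgfree_w`, `dgref_c`, `dgfree_c`, `rvdw`, `mass`
#' @export
atomic_solvation_table <- function(path = NULL) {
  if (is.null(path) && !is.null(.cgimm_env$atomic)) return(.cgimm_env$atomic)
  p <- if (is.null(path)) cgimm_file("extdata", "atomic_solvation.yaml") else path
  raw <- yaml::read_yaml(p)
  df <- do.call(rbind, lapply(names(raw$atoms), function(nm) {
    a <- raw$atoms[[nm]]
    data.frame(type = nm, volume = a$volume, lambda = a$lambda,
               dgref_w = a$dgref_w, dgfree_w = a$dgfree_w,
               dgref_c = a$dgref_c, dgfree_c = a$dgfree_c,
               rvdw = a$rvdw, mass = a$mass, stringsAsFactors = FALSE)
  }))
  rownames(df) <- df$type
  if (is.null(path)) .cgimm_env$atomic <- df
  df
}

#' Residue-to-bead mapping
#'
#' Reads the shipped MARTINI-style residue mapping: for every standard amino
#' acid, the ordered list of beads with their constituent heavy atoms and
#' united-atom types.  Glycine and alanine map to a single (backbone) bead.
#'
#' @param path optional path to a replacement YAML mapping
#' @return named list: residue -> list of beads, each a list with `label`,
#'   `type` and an `atoms` matrix (`atom`, `ua_type`)
#' @export
residue_mapping <- function(path = NULL) {
  if (is.null(path) && !is.null(.cgimm_env$mapping)) return(.cgimm_env$mapping)
  p <- if (is.null(path)) cgimm_file("extdata", "martini_mapping.yaml") else path
  raw <- yaml::read_yaml(p)
  mp <- lapply(raw$residues, function(beads) {
    lapply(beads, function(b) {
      atoms <- do.call(rbind, lapply(b$atoms, function(a) {
        data.frame(atom = a[[1]], ua_type = a[[2]], stringsAsFactors = FALSE)
      }))
      list(label = b$label, type = b$type, atoms = atoms)
    })
  })
  # sanity: each mapped heavy atom appears exactly once per residue
  for (res in names(mp)) {
    atoms <- unlist(lapply(mp[[res]], function(b) b$atoms$atom))
    if (anyDuplicated(atoms))
      stop("mapping for ", res, " assigns an atom to more than one bead")
  }
  if (is.null(path)) .cgimm_env$mapping <- mp
  mp
}

#' Bonded parameter set
#'
#' Reads the shipped bonded parameter data (backbone bond/angle/dihedral
#' parameters per secondary-structure state, side-chain bond topology per
#' residue, and the chain-break threshold).
#'
#' @param path optional path to a replacement YAML parameter file
#' @return nested list mirroring the file structure
#' @export
bonded_parameters <- function(path = NULL) {
  if (is.null(path) && !is.null(.cgimm_env$bonded)) return(.cgimm_env$bonded)
  p <- if (is.null(path)) cgimm_file("extdata", "bonded_params.yaml") else path
  raw <- yaml::read_yaml(p)
  if (is.null(path)) .cgimm_env$bonded <- raw
  raw
}
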