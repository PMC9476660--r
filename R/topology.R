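#' Read an all-atom protein structure from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] that keeps protein ATOM records
#' only (waters and other HETATM are dropped), resolves alternate locations
#' to the highest-occupancy conformer, and returns a plain atom table.
#'
#' @param path path to a PDB file
#' @return object of class `aa_structure`: a list with an `atoms`
#'   data.frame (`chain`, `resid`, `resname`, `atom`, `x`, `y`, `z`)
#' @export
load_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no protein atoms in ", path)
  # altloc: keep blank records, else the highest-occupancy alternative
  alt <- !(at$alt %in% c("", " ", NA))
  if (any(alt)) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[alt])) {
      idx <- which(key == k)
      if (length(idx) > 1) {
        occ <- at$o[idx]
        occ[is.na(occ)] <- 0
        keep[idx] <- FALSE
        keep[idx[which.max(occ)]] <- TRUE
      }
    }
    at <- at[keep, , drop = FALSE]
  }
  atoms <- data.frame(chain = at$chain, resid = at$resno,
                      resname = at$resid, atom = at$elety,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source = path), class = "aa_structure")
}

new_cg_structure <- function(beads, ss = NULL) {
  rkey <- paste(beads$chain, beads$resid)
  resk <- unique(rkey)
  if (is.null(ss)) ss <- rep("C", length(resk))
  names(ss) <- resk
  empty_bonds <- data.frame(i = integer(), j = integer(),
                            r0 = numeric(), k = numeric())
  structure(list(
    beads = beads,
    bonds = empty_bonds,
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        theta0 = numeric(), kf = numeric()),
    dihedrals = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), phi_s = numeric(), kf = numeric(),
                           mult = numeric()),
    ss = ss), class = "cg_structure")
}

#' @export
print.cg_structure <- function(x, ...) {
  cat("Coarse-grained structure:", nrow(x$beads), "beads,",
      length(x$ss), "residues,", length(unique(x$beads$chain)), "chain(s)\n")
  cat("  bonded terms:", nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$dihedrals), "dihedrals\n")
  tab <- table(factor(x$ss, levels = c("H", "E", "C")))
  cat("  secondary structure: H =", tab["H"], " E =", tab["E"],
      " C =", tab["C"], "\n")
  invisible(x)
}

#' Bead coordinates of a coarse-grained structure
#' @param cg a `cg_structure`
#' @return numeric matrix n_beads x 3
#' @export
cg_xyz <- function(cg) {
  as.matrix(cg$beads[, c("x", "y", "z")])
}

#' Replace bead coordinates
#' @param cg a `cg_structure`
#' @param xyz numeric matrix n_beads x 3
#' @return the updated structure
#' @export
cg_set_xyz <- function(cg, xyz) {
  stopifnot(nrow(xyz) == nrow(cg$beads), ncol(xyz) == 3)
  cg$beads$x <- xyz[, 1]; cg$beads$y <- xyz[, 2]; cg$beads$z <- xyz[, 3]
  cg
}

#' Indices of backbone beads
#' @param cg a `cg_structure`
#' @return integer vector of bead indices with label `"BB"`
#' @export
backbone_indices <- function(cg) which(cg$beads$label == "BB")

#' Map an all-atom structure to coarse-grained beads
#'
#' Each bead is placed at the centre of mass of its constituent heavy atoms
#' (hydrogens are ignored).  Bead mass is the sum of the constituent atomic
#' masses; bead charge comes from the bead-type registry.
#'
#' @param aa an `aa_structure` from [load_pdb()]
#' @param mapping residue mapping, default [residue_mapping()]
#' @param permissive if `TRUE`, beads with some (but not all) constituent
#'   atoms missing are placed at the centroid of the available atoms;
#'   default is an error
#' @return a `cg_structure` (bonded terms not yet built; see
#'   [build_bonded_terms()])
#' @export
map_to_cg <- function(aa, mapping = residue_mapping(), permissive = FALSE) {
  atoms <- aa$atoms
  atab <- atomic_solvation_table()
  reg <- bead_type_registry()
  rows <- list()
  id <- 0L
  rkey <- paste(atoms$chain, atoms$resid)
  for (rk in unique(rkey)) {
    sel <- atoms[rkey == rk, , drop = FALSE]
    resname <- sel$resname[1]
    if (!resname %in% names(mapping))
      stop("residue ", resname, " not present in the mapping")
    for (bead in mapping[[resname]]) {
      hit <- match(bead$atoms$atom, sel$atom)
      if (anyNA(hit)) {
        if (!permissive || all(is.na(hit)))
          stop("residue ", rk, " (", resname, "): missing atoms ",
               paste(bead$atoms$atom[is.na(hit)], collapse = ", "))
        hit <- hit[!is.na(hit)]
        m <- rep(1, length(hit)) # centroid fallback
        mass <- sum(atab[bead$atoms$ua_type, "mass"])
      } else {
        m <- atab[bead$atoms$ua_type, "mass"]
        mass <- sum(m)
      }
      com <- c(sum(sel$x[hit] * m), sum(sel$y[hit] * m),
               sum(sel$z[hit] * m)) / sum(m)
      id <- id + 1L
      rows[[id]] <- data.frame(
        id = id, chain = sel$chain[1], resid = sel$resid[1],
        resname = resname, label = bead$label, type = bead$type,
        charge = reg$charge[match(bead$type, reg$name)], mass = mass,
        x = com[1], y = com[2], z = com[3], stringsAsFactors = FALSE)
    }
  }
  new_cg_structure(do.call(rbind, rows))
}

#' Assign secondary-structure labels
#'
#' Labels are supplied externally (the package never infers secondary
#' structure).  The annotation may be a single string (`"HHHCC..."`), a
#' character vector of per-residue labels, or a range specification such as
#' `"3-7:H;10-12:E"` (1-based residue positions in bead order).  Residues
#' without annotation are coil (`C`).
#'
#' @param cg a `cg_structure`
#' @param annotation see above; `""` or `NULL` labels everything coil
#' @return the structure with `ss` populated
#' @export
assign_ss_labels <- function(cg, annotation = NULL) {
  nres <- length(cg$ss)
  lab <- rep("C", nres)
  if (!is.null(annotation) && length(annotation) > 0 &&
      !identical(annotation, "")) {
    if (length(annotation) == 1 && grepl(":", annotation)) {
      for (part in strsplit(annotation, ";")[[1]]) {
        mt <- regmatches(part, regexec("^\\s*(\\d+)-(\\d+):([HEC])\\s*$", part))[[1]]
        if (length(mt) != 4) stop("bad range spec: ", part)
        from <- as.integer(mt[2]); to <- as.integer(mt[3])
        if (from < 1 || to > nres || from > to)
          stop("range ", part, " outside 1..", nres)
        lab[from:to] <- mt[4]
      }
    } else {
      if (length(annotation) == 1) annotation <- strsplit(annotation, "")[[1]]
      if (length(annotation) != nres)
        stop("annotation length ", length(annotation),
             " does not match residue count ", nres)
      if (!all(annotation %in% c("H", "E", "C")))
        stop("labels must be H, E or C")
      lab <- annotation
    }
  }
  names(lab) <- names(cg$ss)
  cg$ss <- lab
  cg
}

#' Build bonded interaction lists
#'
#' Backbone bonds connect consecutive residues of the same chain; a
#' backbone pair farther apart than the chain-break threshold is treated as
#' a break (warning, no bonded terms across it).  Angles run over
#' consecutive backbone triples and dihedrals over quadruples; their
#' parameters are selected from the secondary-structure labels (a term is
#' helical/extended only if all its residues are).  Side-chain bonds follow
#' the per-residue topology of the bonded parameter file.  Rebuilding is
#' idempotent: terms are always derived from scratch.
#'
#' @param cg a `cg_structure` with `ss` assigned
#' @param ff bonded parameter set, default [bonded_parameters()]
#' @return the structure with `bonds`, `angles`, `dihedrals` populated
#' @export
build_bonded_terms <- function(cg, ff = bonded_parameters()) {
  beads <- cg$beads
  bb <- backbone_indices(cg)
  xyz <- cg_xyz(cg)
  thr <- ff$chain_break_threshold
  ss_of <- function(idx) cg$ss[paste(beads$chain[idx], beads$resid[idx])]

  bonds <- list(); angles <- list(); dihedrals <- list()
  # consecutive backbone beads of one chain, break-checked
  ok_link <- logical(max(length(bb) - 1, 0))
  for (t in seq_along(ok_link)) {
    i <- bb[t]; j <- bb[t + 1]
    if (beads$chain[i] != beads$chain[j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > thr) {
      warning("chain break between residues ", beads$resid[i], " and ",
              beads$resid[j], " of chain ", beads$chain[i],
              " (backbone distance ", round(d, 2), " A); bond omitted")
      next
    }
    ok_link[t] <- TRUE
    sspair <- c(ss_of(i), ss_of(j))
    state <- if (all(sspair == "H")) "H" else if (all(sspair == "E")) "E" else "C"
    p <- ff$backbone$bond[[state]]
    bonds[[length(bonds) + 1]] <- data.frame(i = i, j = j, r0 = p$r0, k = p$k)
  }
  # angles over linked triples, dihedrals over linked quadruples
  for (t in seq_len(max(length(bb) - 2, 0))) {
    if (!(ok_link[t] && ok_link[t + 1])) next
    idx <- bb[t:(t + 2)]
    sss <- ss_of(idx)
    state <- if (all(sss == "H")) "H" else if (all(sss == "E")) "E" else "C"
    p <- ff$backbone$angle[[state]]
    angles[[length(angles) + 1]] <- data.frame(
      i = idx[1], j = idx[2], k = idx[3], theta0 = p$theta0, kf = p$k)
  }
  for (t in seq_len(max(length(bb) - 3, 0))) {
    if (!(ok_link[t] && ok_link[t + 1] && ok_link[t + 2])) next
    idx <- bb[t:(t + 3)]
    sss <- ss_of(idx)
    state <- if (all(sss == "H")) "H" else if (all(sss == "E")) "E" else NA
    if (is.na(state)) next # coil: no backbone dihedral
    p <- ff$backbone$dihedral[[state]]
    dihedrals[[length(dihedrals) + 1]] <- data.frame(
      i = idx[1], j = idx[2], k = idx[3], l = idx[4],
      phi_s = p$phi_s, kf = p$k, mult = p$mult)
  }
  # side-chain bonds within each residue
  kd <- ff$sidechain$default_bond_k
  rkey <- paste(beads$chain, beads$resid)
  for (rk in unique(rkey)) {
    sel <- which(rkey == rk)
    resname <- beads$resname[sel[1]]
    sc <- ff$sidechain$bonds[[resname]]
    if (is.null(sc)) next
    for (b in sc) {
      i <- sel[match(b[[1]], beads$label[sel])]
      j <- sel[match(b[[2]], beads$label[sel])]
      if (is.na(i) || is.na(j)) next
      bonds[[length(bonds) + 1]] <- data.frame(
        i = i, j = j, r0 = as.numeric(b[[3]]), k = kd)
    }
  }
  cg$bonds <- if (length(bonds)) do.call(rbind, bonds) else cg$bonds[0, ]
  cg$angles <- if (length(angles)) do.call(rbind, angles) else cg$angles[0, ]
  cg$dihedrals <- if (length(dihedrals)) do.call(rbind, dihedrals) else
    cg$dihedrals[0, ]
  rownames(cg$bonds) <- rownames(cg$angles) <- rownames(cg$dihedrals) <- NULL
  cg
}

#' Write / read a coarse-grained structure as PDB
#'
#' Beads are written as ATOM records with the bead label in the atom-name
#' field, the bead type in the segment-id field and coordinates at PDB
#' precision (3 decimals).  Secondary-structure labels are stored in
#' `REMARK 300 SS` records, so `read_cg_pdb(write_cg_pdb(cg))` round-trips
#' order, labels, types and coordinates.
#'
#' @param cg a `cg_structure`
#' @param path output / input file path
#' @return `write_cg_pdb`: the path, invisibly; `read_cg_pdb`: a
#'   `cg_structure` (bonded terms not rebuilt)
#' @export
write_cg_pdb <- function(cg, path) {
  b <- cg$beads
  if (any(nchar(b$label) > 4)) stop("bead labels longer than 4 characters")
  if (any(nchar(b$type) > 4)) stop("bead type names longer than 4 characters")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK 300 SS %s", paste(cg$ss, collapse = "")), con)
  for (r in seq_len(nrow(b))) {
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s",
      b$id[r] %% 100000L, b$label[r], substr(b$resname[r], 1, 3),
      substr(b$chain[r], 1, 1), b$resid[r] %% 10000L,
      b$x[r], b$y[r], b$z[r], 1.0, 0.0, b$type[r]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_cg_pdb
#' @export
read_cg_pdb <- function(path) {
  lines <- readLines(path)
  ss_line <- grep("^REMARK 300 SS ", lines, value = TRUE)
  at <- lines[startsWith(lines, "ATOM  ")]
  if (length(at) == 0) stop("no ATOM records in ", path)
  reg <- bead_type_registry()
  f <- function(l, a, b) trimws(substr(l, a, b))
  type <- vapply(at, f, "", 73, 76, USE.NAMES = FALSE)
  beads <- data.frame(
    id = seq_along(at),
    chain = vapply(at, f, "", 22, 22, USE.NAMES = FALSE),
    resid = as.integer(vapply(at, f, "", 23, 26, USE.NAMES = FALSE)),
    resname = vapply(at, f, "", 18, 20, USE.NAMES = FALSE),
    label = vapply(at, f, "", 13, 16, USE.NAMES = FALSE),
    type = type,
    charge = reg$charge[match(type, reg$name)],
    mass = reg$mass[match(type, reg$name)],
    x = as.numeric(vapply(at, f, "", 31, 38, USE.NAMES = FALSE)),
    y = as.numeric(vapply(at, f, "", 39, 46, USE.NAMES = FALSE)),
    z = as.numeric(vapply(at, f, "", 47, 54, USE.NAMES = FALSE)),
    stringsAsFactors = FALSE)
  cg <- new_cg_structure(beads)
  if (length(ss_line) == 1) {
    ss <- sub("^REMARK 300 SS ", "", ss_line[1])
    cg <- assign_ss_labels(cg, ss)
  }
  cg
}
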