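test_that("load_pdb round-trips a minimal structure and applies filters", {
  path <- tempfile(fileext = ".pdb")
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.3, 0.5, 0),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.4, -0.4, 0),
    pdb_atom_line(4, "O", "ALA", "A", 1, 2.5, -1.6, 0),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 1.4, 1.5, 1.2),
    pdb_atom_line(6, "N", "GLY", "A", 2, 3.4, 0.3, 0),
    pdb_atom_line(7, "CA", "GLY", "A", 2, 4.6, -0.3, 0.4),
    pdb_atom_line(8, "C", "GLY", "A", 2, 5.8, 0.5, 0),
    pdb_atom_line(9, "O", "GLY", "A", 2, 5.9, 1.7, 0.2),
    pdb_atom_line(10, "N", "GLY", "A", 3, 6.8, -0.2, -0.4),
    pdb_atom_line(11, "CA", "GLY", "A", 3, 8.1, 0.4, -0.5),
    pdb_atom_line(12, "C", "GLY", "A", 3, 9.1, -0.6, -1.0),
    pdb_atom_line(13, "O", "GLY", "A", 3, 9.0, -1.8, -0.8),
    "HETATM   14  O   HOH A   4      20.000  20.000  20.000  1.00  0.00",
    "END")
  write_minimal_pdb(path, lines)
  aa <- load_pdb(path)
  expect_equal(length(unique(paste(aa$atoms$chain, aa$atoms$resid))), 3)
  expect_false(any(aa$atoms$resname == "HOH"))
  expect_error(load_pdb(tempfile()), "not found")
})

test_that("altloc records resolve to the highest occupancy", {
  path <- tempfile(fileext = ".pdb")
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.6, alt = "A"),
    pdb_atom_line(3, "CA", "ALA", "A", 1, 9.0, 9, 9, occ = 0.4, alt = "B"),
    pdb_atom_line(4, "C", "ALA", "A", 1, 2.4, -0.4, 0),
    pdb_atom_line(5, "O", "ALA", "A", 1, 2.5, -1.6, 0),
    pdb_atom_line(6, "CB", "ALA", "A", 1, 1.4, 1.5, 1.2),
    "END")
  write_minimal_pdb(path, lines)
  aa <- load_pdb(path)
  ca <- aa$atoms[aa$atoms$atom == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.0)
})

test_that("mapping gives one bead for Gly/Ala, two for Leu, COM placement", {
  mapping <- residue_mapping()
  expect_true(all(c("GLY", "ALA") %in% names(mapping)))
  expect_equal(length(mapping$GLY), 1)
  expect_equal(length(mapping$ALA), 1)
  expect_equal(length(mapping$LEU), 2)
  # poly-alanine: 10 residues -> 10 beads
  path <- tempfile(fileext = ".pdb")
  lines <- unlist(lapply(1:10, function(r) {
    z <- (r - 1) * 3.5
    c(pdb_atom_line(5 * r - 4, "N", "ALA", "A", r, 0, 0, z),
      pdb_atom_line(5 * r - 3, "CA", "ALA", "A", r, 1.3, 0.5, z),
      pdb_atom_line(5 * r - 2, "C", "ALA", "A", r, 2.4, -0.4, z),
      pdb_atom_line(5 * r - 1, "O", "ALA", "A", r, 2.5, -1.6, z),
      pdb_atom_line(5 * r, "CB", "ALA", "A", r, 1.4, 1.5, z + 1.2))
  }))
  write_minimal_pdb(path, c(lines, "END"))
  cg <- map_to_cg(load_pdb(path))
  expect_equal(nrow(cg$beads), 10)
  expect_true(all(cg$beads$label == "BB"))
  # centre of mass of a 2-atom equal-mass group
  atab <- atomic_solvation_table()
  p2 <- tempfile(fileext = ".pdb")
  write_minimal_pdb(p2, c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(3, "C", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(4, "O", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(6, "N", "CYS", "A", 2, 0, 0, 0),
    pdb_atom_line(7, "CA", "CYS", "A", 2, 0, 0, 0),
    pdb_atom_line(8, "C", "CYS", "A", 2, 0, 0, 0),
    pdb_atom_line(9, "O", "CYS", "A", 2, 0, 0, 0),
    pdb_atom_line(10, "CB", "CYS", "A", 2, 0, 0, 0),
    pdb_atom_line(11, "SG", "CYS", "A", 2, 2, 0, 0),
    "END"))
  cg2 <- map_to_cg(load_pdb(p2))
  sc <- cg2$beads[cg2$beads$label == "SC1", ]
  mCB <- atab["CH2E", "mass"]; mSG <- atab["SH1E", "mass"]
  expect_equal(sc$x, 2 * mSG / (mCB + mSG), tolerance = 1e-12)
  # mass conservation: bead masses sum to mapped heavy-atom masses
  expect_equal(sum(cg2$beads$mass),
               sum(atab[c("NH1", "CH1E", "C", "O", "CH3E",
                          "NH1", "CH1E", "C", "O", "CH2E", "SH1E"), "mass"]))
  # missing side-chain atom errors unless permissive
  p3 <- tempfile(fileext = ".pdb")
  write_minimal_pdb(p3, c(
    pdb_atom_line(1, "N", "CYS", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "CYS", "A", 1, 1, 0, 0),
    pdb_atom_line(3, "C", "CYS", "A", 1, 2, 0, 0),
    pdb_atom_line(4, "O", "CYS", "A", 1, 3, 0, 0),
    pdb_atom_line(5, "CB", "CYS", "A", 1, 1, 1.5, 0),
    "END"))
  expect_error(map_to_cg(load_pdb(p3)), "missing atoms")
  cgp <- map_to_cg(load_pdb(p3), permissive = TRUE)
  expect_equal(nrow(cgp$beads), 2)
})

test_that("secondary-structure labels: strings, ranges and defaults", {
  cg <- bare_cg(helix_coords(10))
  cg <- assign_ss_labels(cg, "HHHHHHHHHH")
  expect_true(all(cg$ss == "H"))
  cg <- assign_ss_labels(cg, NULL)
  expect_true(all(cg$ss == "C"))
  cg <- assign_ss_labels(cg, "3-7:H")
  expect_equal(unname(cg$ss), c("C", "C", "H", "H", "H", "H", "H",
                                "C", "C", "C"))
  expect_error(assign_ss_labels(cg, "HHH"), "length")
})

test_that("bonded terms: counts, chain separation, ss-dependent params", {
  # 4-residue single-bead chain: 3 bonds, 2 angles, 1 dihedral (helix)
  cg <- bare_cg(helix_coords(4))
  cg <- assign_ss_labels(cg, "HHHH")
  cg <- build_bonded_terms(cg)
  expect_equal(nrow(cg$bonds), 3)
  expect_equal(nrow(cg$angles), 2)
  expect_equal(nrow(cg$dihedrals), 1)
  # idempotent
  cg2 <- build_bonded_terms(cg)
  expect_identical(cg$bonds, cg2$bonds)
  expect_identical(cg$dihedrals, cg2$dihedrals)
  # helix-labelled segment carries helix dihedral parameters: compare to a
  # hand-built topology for the 5-residue fixture
  ff <- bonded_parameters()
  cg5 <- build_bonded_terms(assign_ss_labels(bare_cg(helix_coords(5)),
                                             "HHHHH"))
  expect_equal(nrow(cg5$dihedrals), 2)
  expect_equal(unique(cg5$dihedrals$phi_s), ff$backbone$dihedral$H$phi_s)
  expect_equal(unique(cg5$bonds$r0), ff$backbone$bond$H$r0)
  expect_equal(unique(cg5$angles$theta0), ff$backbone$angle$H$theta0)
  # coil labels give no backbone dihedral
  cgc <- build_bonded_terms(assign_ss_labels(bare_cg(helix_coords(5)), NULL))
  expect_equal(nrow(cgc$dihedrals), 0)
  # two chains: no inter-chain terms
  xyz <- rbind(helix_coords(4), sweep(helix_coords(4), 2, c(30, 0, 0), "+"))
  cg2c <- bare_cg(xyz)
  cg2c$beads$chain <- rep(c("A", "B"), each = 4)
  cg2c$beads$resid <- rep(1:4, 2)
  cg2c <- cgimm:::new_cg_structure(cg2c$beads)
  cg2c <- build_bonded_terms(assign_ss_labels(cg2c, NULL))
  expect_equal(nrow(cg2c$bonds), 6)
  expect_equal(nrow(cg2c$angles), 4)
  # chain break: far-apart consecutive residues are not bonded
  xyzb <- helix_coords(4)
  xyzb[3:4, 3] <- xyzb[3:4, 3] + 50
  expect_warning(cgb <- build_bonded_terms(assign_ss_labels(bare_cg(xyzb),
                                                            NULL)),
                 "chain break")
  expect_equal(nrow(cgb$bonds), 2)
  expect_equal(nrow(cgb$angles), 0)
})

test_that("CG PDB write/read round-trips labels, types and coordinates", {
  fx <- make_fixture("tm_polyleucine", n = 10)
  path <- tempfile(fileext = ".cgpdb")
  write_cg_pdb(fx$cg, path)
  back <- read_cg_pdb(path)
  expect_equal(nrow(back$beads), nrow(fx$cg$beads))
  expect_equal(back$beads$label, fx$cg$beads$label)
  expect_equal(back$beads$type, fx$cg$beads$type)
  expect_equal(unname(back$ss), unname(fx$cg$ss))
  expect_equal(cg_xyz(back), round(cg_xyz(fx$cg), 3), ignore_attr = TRUE)
  # PDB precision truncates to 3 decimals
  cg <- bare_cg(matrix(c(123.4567, 0, 0, 1, 2, 3), 2, 3, byrow = TRUE))
  p <- tempfile(fileext = ".cgpdb")
  write_cg_pdb(cg, p)
  expect_equal(read_cg_pdb(p)$beads$x[1], 123.457)
  # over-long labels are rejected
  bad <- cg
  bad$beads$label <- c("TOOLONG", "BB")
  expect_error(write_cg_pdb(bad, tempfile()), "4 characters")
})
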