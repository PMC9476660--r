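quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

test_that("Kabsch alignment: exact recovery and brute-force agreement", {
  set.seed(21)
  ref <- matrix(rnorm(15, sd = 4), 5, 3)
  # identical sets give the identity transform
  a0 <- kabsch_align(ref, ref)
  expect_equal(a0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(max(abs(a0$aligned - ref)), 0, tolerance = 1e-10)
  # a known rotation + translation is recovered exactly
  R <- quat_rotation(c(0.8, 0.1, -0.5, 0.3))
  mob <- sweep(ref %*% R, 2, c(3, -2, 7), "+")
  al <- kabsch_align(mob, ref)
  expect_lt(rmsd(al$aligned, ref, align = FALSE), 1e-10)
  expect_equal(det(al$rotation), 1, tolerance = 1e-10)
  # randomly deformed set: optimal RMSD matches a quaternion brute force
  mob2 <- mob + matrix(rnorm(15, sd = 0.6), 5, 3)
  impl <- rmsd(mob2, ref)
  cm <- sweep(mob2, 2, colMeans(mob2)); cr <- sweep(ref, 2, colMeans(ref))
  grid_rmsd <- function(par) {
    Rg <- quat_rotation(par)
    sqrt(mean(rowSums((cm %*% Rg - cr)^2)))
  }
  set.seed(22)
  best <- Inf; best_q <- NULL
  for (i in 1:4000) {
    q <- rnorm(4)
    v <- grid_rmsd(q)
    if (v < best) { best <- v; best_q <- q }
  }
  ref_opt <- optim(best_q, grid_rmsd, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(impl, ref_opt$value, tolerance = 1e-6)
  # degenerate inputs are rejected
  expect_error(kabsch_align(ref[1:2, ], ref[1:2, ]), "3 points")
  lin <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_align(lin, lin), "collinear")
})

test_that("RMSD: invariances and the hand-evaluated deviation", {
  set.seed(23)
  ref <- matrix(rnorm(24, sd = 3), 8, 3)
  expect_equal(rmsd(ref, ref), 0, tolerance = 1e-12)
  # pure translation vanishes after alignment
  expect_equal(rmsd(sweep(ref, 2, c(1, 0, 0), "+"), ref), 0,
               tolerance = 1e-10)
  # any rigid transform of the mobile set leaves RMSD unchanged
  R <- quat_rotation(c(1, 2, -1, 0.5))
  mob <- ref + matrix(rnorm(24, sd = 0.5), 8, 3)
  expect_equal(rmsd(sweep(mob %*% R, 2, c(-4, 2, 9), "+"), ref),
               rmsd(mob, ref), tolerance = 1e-9)
  # two beads deviating 3 and 4 A with no rigid component: sqrt(12.5)
  expect_equal(sqrt(mean(c(3, 4)^2)), sqrt(12.5))
  frame <- rbind(c(0, 0, 3), c(0, 0, -4))
  refer <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(rmsd(frame, refer, align = FALSE), sqrt(12.5))
  expect_error(rmsd(ref, ref, selection = integer()), "empty")
})

test_that("radius of gyration: closed forms and invariances", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(radius_of_gyration(two), 5)
  # mass weighting shifts toward the heavy bead
  expect_lt(radius_of_gyration(two, masses = c(3, 1)), 5)
  set.seed(24)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(radius_of_gyration(sweep(x, 2, c(5, 6, 7), "+")),
               radius_of_gyration(x), tolerance = 1e-12)
})

test_that("1-4 geometry on the ideal helix matches closed-form values", {
  fx <- make_fixture("ideal_helix", n = 12)
  d14_closed <- sqrt((4 * 1.5)^2 +
                       (2 * 2.3 * sin(2 * 100 * pi / 180))^2) # 6.2028 A
  for (n in 1:8)
    expect_equal(one_four_distance(fx$cg, n), d14_closed, tolerance = 1e-9)
  expect_equal(d14_closed, 6.2028, tolerance = 1e-4)
  # independent torsion evaluation agrees with the dihedral
  xyz <- cg_xyz(fx$cg)[backbone_indices(fx$cg), ]
  phi_bio3d <- bio3d::torsion.xyz(as.vector(t(xyz[1:4, ])))
  expect_equal(one_four_dihedral(fx$cg, 1), phi_bio3d, tolerance = 1e-6)
  # planar zigzag gives 180 deg; collinear geometry is undefined
  zig <- bare_cg(cbind(c(1, -1, 1, -1), 0, c(0, 3, 6, 9)))
  expect_equal(abs(one_four_dihedral(zig, 1)), 180)
  lin <- bare_cg(cbind(0, 0, c(0, 3, 6, 9)))
  expect_true(is.na(one_four_dihedral(lin, 1)))
})

test_that("protein fitness: frozen hand computation, extremum, monotonicity", {
  # 6-bead helix-labelled reference, 2-frame synthetic trajectory
  ref_xyz <- helix_coords(6)
  cg <- assign_ss_labels(bare_cg(ref_xyz), "HHHHHH")
  f1 <- ref_xyz
  f1[6, 1] <- f1[6, 1] + 0.9           # bend the terminus
  R <- quat_rotation(c(2, 0.3, 0.1, -0.2))
  f2 <- sweep((ref_xyz + 0.15) %*% R, 2, c(1, 2, 3), "+") # rigid + uniform
  traj <- cgimm:::.traj_from_frames(list(f1, f2), c(1, 2))
  impl <- protein_fitness(traj, cg)
  # independent spreadsheet-style evaluation (bio3d for the dihedrals,
  # explicit arithmetic for everything else)
  w <- list(rmsd = 1.0, gyr = 3.0, dih = 2.0, dist = 2.0,
            th_h = 58.8, d_h = 5.8)
  rg <- function(x) sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
  al <- function(x) kabsch_align(x, ref_xyz)$aligned
  rmsd_m <- mean(vapply(list(f1, f2), function(x)
    sqrt(mean(rowSums((al(x) - ref_xyz)^2))), 0))
  gyr_m <- mean(abs(vapply(list(f1, f2), rg, 0) - rg(ref_xyz))) / rg(ref_xyz)
  dihs <- function(x) vapply(1:3, function(t)
    abs(bio3d::torsion.xyz(as.vector(t(x[t:(t + 3), ])))), 0)
  dih_m <- mean(abs(c(dihs(f1), dihs(f2)) - w$th_h)) / w$th_h
  dists <- function(x) vapply(1:2, function(t)
    sqrt(sum((x[t, ] - x[t + 4, ])^2)), 0)
  dist_m <- mean(abs(c(dists(f1), dists(f2)) - w$d_h)) / w$d_h
  S <- w$rmsd * rmsd_m + w$gyr * gyr_m + w$dih * dih_m + w$dist * dist_m
  expect_equal(impl$fitness, 1 / (1 + S), tolerance = 1e-10)
  # a trajectory identical to a reference whose geometry matches all
  # reference constants exactly attains the extremal fitness 1
  cfg0 <- fitness_config(theta_helix = abs(one_four_dihedral(cg, 1)),
                         d_helix = one_four_distance(cg, 1))
  t0 <- cgimm:::.traj_from_frames(list(ref_xyz, ref_xyz), c(1, 2))
  expect_equal(protein_fitness(t0, cg, cfg0)$fitness, 1, tolerance = 1e-12)
  # doubling RMSD at fixed other terms strictly worsens fitness
  S2 <- S + w$rmsd * rmsd_m
  expect_lt(1 / (1 + S2), 1 / (1 + S))
  expect_lt(protein_fitness(traj, cg,
                            fitness_config(w_rmsd = 2))$fitness,
            impl$fitness)
})

test_that("geometric-mean aggregation: closed forms and inequalities", {
  expect_equal(aggregate_fitness(c(4, 9)), 6)
  expect_equal(aggregate_fitness(5.5), 5.5)
  expect_equal(aggregate_fitness(c(0.3, 0, 0.9)), 0)
  expect_error(aggregate_fitness(c(0.3, -0.1)), "negative")
  set.seed(25)
  for (i in 1:20) {
    v <- runif(5)
    expect_lte(aggregate_fitness(v), mean(v) + 1e-12)
  }
  expect_equal(aggregate_fitness(rep(0.4, 4)), 0.4, tolerance = 1e-12)
})

test_that("trajectory report: flat series, normalized histograms", {
  fx <- make_fixture("ideal_helix", n = 10)
  xyz <- cg_xyz(fx$cg)
  traj <- cgimm:::.traj_from_frames(list(xyz, xyz, xyz), 1:3)
  rep <- trajectory_report(traj, fx$cg)
  expect_equal(rep$rmsd, rep(0, 3), tolerance = 1e-10)
  expect_equal(sum(rep$hist$dist_H$prob), 1)
  expect_equal(sum(rep$hist$dih_H$prob), 1)
  # the ideal helix concentrates all dihedral mass in one bin
  expect_equal(max(rep$hist$dih_H$prob), 1)
  expect_null(rep$hist$dist_E)
})
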