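test_that("switching function: interface value, bounds, parity, width", {
  mem <- membrane_model(26, n = 10)
  expect_equal(switching_f(13, mem), 0.5)
  expect_equal(switching_f(-13, mem), 0.5)
  expect_equal(switching_f(0, mem), 0)
  expect_equal(switching_f(1e5, mem), 1, tolerance = 1e-12)
  # interface value is exact for any thickness / steepness
  for (T in c(10, 26, 40)) for (n in c(2, 10, 20))
    expect_equal(switching_f(T / 2, membrane_model(T, n = n)), 0.5)
  z <- seq(0, 40, by = 0.05)
  f <- switching_f(z, mem)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) >= 0))
  expect_equal(f, switching_f(-z, mem))
  # 0.1 -> 0.9 transition width for n = 10, T = 26: T/2 (9^(1/10) - 9^(-1/10))
  z10 <- uniroot(function(z) switching_f(z, mem) - 0.1, c(1, 13),
                 tol = 1e-12)$root
  z90 <- uniroot(function(z) switching_f(z, mem) - 0.9, c(13, 26),
                 tol = 1e-12)$root
  width_closed <- 13 * (9^(1 / 10) - 9^(-1 / 10))
  expect_equal(z90 - z10, width_closed, tolerance = 1e-6)
  expect_lt(z90 - z10, 6)
})

test_that("environment interpolation is linear in f with exact endpoints", {
  expect_equal(env_value(-5, 1, 1), -5)
  expect_equal(env_value(-5, 1, 0), 1)
  expect_equal(env_value(-5, 1, 0.5), -2)
  expect_error(env_value(1, 2, 1.5))
})

test_that("solvation energy: reference limits, cutoff, overlap guard", {
  tab <- default_table()
  # one isolated bead deep in water: energy equals dGref(water)
  cg1 <- bare_cg(matrix(c(0, 0, 1000), 1, 3), types = "C1")
  mem <- membrane_model(26)
  e1 <- solvation_energy(cg1, tab, mem)
  expect_equal(e1$total, tab$water["C1", "dgref"], tolerance = 1e-9)
  # the same bead at the membrane centre: dGref(chex)
  cg0 <- bare_cg(matrix(c(0, 0, 0), 1, 3), types = "C1")
  expect_equal(solvation_energy(cg0, tab, mem)$total,
               tab$chex["C1", "dgref"], tolerance = 1e-12)
  # two beads beyond the 16 A cutoff: sum of reference values
  cg2 <- bare_cg(rbind(c(0, 0, 1000), c(20, 0, 1000)), types = c("C1", "P4"))
  e2 <- solvation_energy(cg2, tab, mem)
  expect_equal(e2$total, tab$water["C1", "dgref"] + tab$water["P4", "dgref"],
               tolerance = 1e-9)
  # within cutoff the occlusion reduces each bead's solvation magnitude
  cg3 <- bare_cg(rbind(c(0, 0, 1000), c(6, 0, 1000)), types = c("P4", "P4"))
  e3 <- solvation_energy(cg3, tab, mem)
  expect_gt(e3$total, 2 * tab$water["P4", "dgref"]) # dGref < 0, occlusion adds
  expect_equal(sum(e3$per_bead_solvation), e3$total)
  # overlapping beads are an error
  cgx <- bare_cg(rbind(c(0, 0, 0), c(0.05, 0, 0)))
  expect_error(solvation_energy(cgx, tab, mem), "overlap")
})

test_that("pair solvation matches the 3D quadrature oracle at r = R + lambda", {
  # two identical beads in bulk water: the solvent-exclusion correction is
  # the density integral over the occluding sphere; the model's point
  # approximation must track the quadrature oracle closely at contact+lambda
  tab <- default_table()
  mem <- membrane_model(26)
  for (ty in c("P4", "C1", "N0")) {
    V <- tab$water[ty, "V"]; lam <- tab$water[ty, "lambda"]
    R <- tab$water[ty, "R"]; gf <- tab$water[ty, "dgfree"]
    gr <- tab$water[ty, "dgref"]
    r <- R + lam
    cg <- bare_cg(rbind(c(0, 0, 200), c(r, 0, 200)), types = ty)
    impl <- solvation_energy(cg, tab, mem)$total
    a <- (3 * V / (4 * pi))^(1 / 3)
    corr_q <- sphere_quadrature(function(rr) h_density(rr, gf, lam, R), r, a)
    oracle <- 2 * gr - 2 * corr_q
    expect_lt(abs(impl - oracle) / abs(oracle), 0.02)
  }
})

test_that("electrostatics: water limit is eps = r; membrane strengthens", {
  tab <- default_table()
  mem <- membrane_model(26)
  # both beads far from the membrane: E = 332.0636 q1 q2 / r^2 exactly
  for (r in c(3, 6, 10)) {
    cg <- bare_cg(rbind(c(0, 0, 1000), c(r, 0, 1000)), types = c("Qd", "Qa"))
    e <- elec_energy(cg, tab, mem)
    expect_equal(e$total, 332.0636 * (1) * (-1) / r^2, tolerance = 1e-12)
  }
  # zero-charge structure: exactly zero
  cg0 <- bare_cg(rbind(c(0, 0, 0), c(5, 0, 0)), types = "C1")
  expect_equal(elec_energy(cg0, tab, mem)$total, 0)
  # like-charge pair at the membrane centre vs in bulk water, equal r:
  # reduced screening strengthens the interaction
  r <- 8
  cgm <- bare_cg(rbind(c(0, 0, 0), c(r, 0, 0)), types = "Qd")
  cgw <- bare_cg(rbind(c(0, 0, 1000), c(r, 0, 1000)), types = "Qd")
  em <- elec_energy(cgm, tab, mem)$total
  ew <- elec_energy(cgw, tab, mem)$total
  expect_gte(abs(em), abs(ew))
  # monotone: energy magnitude non-increasing in f at fixed r
  zs <- c(0, 6, 11, 13, 16, 40)
  mags <- vapply(zs, function(z) {
    cg <- bare_cg(rbind(c(0, 0, z), c(r, 0, z)), types = "Qd")
    abs(elec_energy(cg, tab, mem)$total)
  }, 0)
  expect_true(all(diff(mags) <= 1e-12))
})

test_that("Lennard-Jones: zero at sigma, minimum -eps, zero beyond cutoff", {
  tab <- default_table()
  lj <- lj_tables()
  sig <- lj$sigma["C1", "C1"]; eps <- lj$epsilon["C1", "C1"]
  at_r <- function(r) {
    cg <- bare_cg(rbind(c(0, 0, 0), c(r, 0, 0)), types = "C1")
    lj_energy(cg, tab)$total
  }
  expect_equal(at_r(sig), 0, tolerance = 1e-12)
  expect_equal(at_r(2^(1 / 6) * sig), -eps, tolerance = 1e-12)
  expect_equal(at_r(14.0), 0)
  expect_equal(at_r(15.0), 0)
  # switching keeps energy continuous at both bounds
  expect_lt(abs(at_r(12 - 1e-7) - at_r(12 + 1e-7)), 1e-6)
  expect_lt(abs(at_r(14 - 1e-7)), 1e-6)
  # ring-ring pairs use the smaller diameter
  expect_equal(lj$sigma["SC4", "SP1"], 4.3)
  expect_equal(lj$sigma["SC4", "P1"], 4.7)
})

test_that("bonded terms: zero at equilibrium, quadratic bond form", {
  tab <- default_table()
  cg <- bare_cg(rbind(c(0, 0, 0), c(3.5, 0, 0)))
  cg$bonds <- data.frame(i = 1, j = 2, r0 = 3.5, k = 2.0)
  e0 <- bonded_energy(cg, tab)
  expect_equal(e0$total, 0)
  expect_equal(max(abs(e0$forces)), 0)
  cg2 <- cg_set_xyz(cg, rbind(c(0, 0, 0), c(3.5 + 0.25, 0, 0)))
  expect_equal(bonded_energy(cg2, tab)$total, 2.0 * 0.25^2, tolerance = 1e-12)
  # angle at theta0 gives zero energy
  th0 <- 100
  xyz <- rbind(c(cos(th0 * pi / 180), sin(th0 * pi / 180), 0),
               c(0, 0, 0), c(1, 0, 0)) * 3.5
  cga <- bare_cg(xyz)
  cga$angles <- data.frame(i = 1, j = 2, k = 3, theta0 = th0, kf = 5)
  expect_equal(bonded_energy(cga, tab)$total, 0, tolerance = 1e-20)
})

test_that("forces equal the analytic gradient; symmetries hold", {
  tab <- default_table()
  mem <- membrane_model(26)
  # finite differences on random charged membrane-spanning structures
  worst <- 0
  for (s in 1:4) {
    cg <- random_membrane_cg(n = 20, seed = s)
    er <- total_energy_forces(cg, tab, mem)
    xyz <- cg_xyz(cg); fs <- max(abs(er$forces)); h <- 1e-5
    set.seed(100 + s)
    for (k in sample(length(xyz), 12)) {
      xp <- xyz; xp[k] <- xp[k] + h
      xm <- xyz; xm[k] <- xm[k] - h
      ep <- total_energy_forces(cg_set_xyz(cg, xp), tab, mem)$total
      em <- total_energy_forces(cg_set_xyz(cg, xm), tab, mem)$total
      i <- (k - 1) %% nrow(xyz) + 1; c <- (k - 1) %/% nrow(xyz) + 1
      worst <- max(worst, abs(-(ep - em) / (2 * h) - er$forces[i, c]) / fs)
    }
  }
  expect_lt(worst, 1e-4)
  # x/y translation invariance; z translation moves membrane terms only
  cg <- random_membrane_cg(n = 15, seed = 9)
  e0 <- total_energy_forces(cg, tab, mem)
  exy <- total_energy_forces(
    cg_set_xyz(cg, sweep(cg_xyz(cg), 2, c(5, -3, 0), "+")), tab, mem)
  expect_equal(exy$total, e0$total, tolerance = 1e-9)
  ez <- total_energy_forces(
    cg_set_xyz(cg, sweep(cg_xyz(cg), 2, c(0, 0, 4), "+")), tab, mem)
  expect_false(isTRUE(all.equal(ez$total, e0$total)))
  expect_equal(ez$terms[["bond"]], e0$terms[["bond"]])
  expect_equal(ez$terms[["lj"]], e0$terms[["lj"]])
  # rotation about z leaves everything invariant
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  erot <- total_energy_forces(cg_set_xyz(cg, cg_xyz(cg) %*% Rz), tab, mem)
  expect_equal(erot$total, e0$total, tolerance = 1e-9)
  # decomposition sums to the total
  expect_equal(sum(e0$terms), e0$total, tolerance = 1e-12)
  # net force vanishes for all translation-invariant directions
  expect_lt(max(abs(colSums(e0$forces)[1:2])), 1e-8)
  # empty structure gives all zeros
  empty <- bare_cg(matrix(numeric(), 0, 3))
  ee <- total_energy_forces(empty, tab, mem)
  expect_equal(ee$total, 0)
})
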