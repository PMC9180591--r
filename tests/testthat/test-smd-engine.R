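test_that("closed-form energies: bond, Coulomb and LJ special points", {
  mk2 <- function(x2, charge = c(0, 0), eps0 = TRUE) {
    atoms <- data.frame(name = c("A", "B"), element = "C", resname = "T",
                        resid = 1L, x = c(0, x2), y = 0, z = 0,
                        charge = charge, stringsAsFactors = FALSE)
    top <- assign_topology(mol_system(list(molecule(atoms, NULL)), "other",
                                      c(60, 60, 60)))
    if (eps0) top$eps <- c(0, 0)
    top
  }
  # two bonded atoms at r0: zero bond energy and force
  atoms <- data.frame(name = c("A", "B"), element = "C", resname = "T",
                      resid = 1L, x = c(0, 1.5), y = 0, z = 0, charge = 0)
  topb <- assign_topology(mol_system(list(molecule(atoms, cbind(1, 2))),
                                     "other", c(60, 60, 60)))
  expect_equal(total_energy(topb)$bond, 0)
  expect_equal(max(abs(md_forces(topb))), 0, tolerance = 1e-12)
  # unit charges at 5 A, no LJ: shifted Coulomb 332.06 (1/5 - 1/rc)
  topq <- mk2(5, charge = c(1, -1))
  expect_equal(total_energy(topq)$coulomb,
               -332.0636 * (1 / 5 - 1 / 10.5), tolerance = 1e-6)
  # LJ at r = sigma: shifted zero up to the cutoff offset
  topl <- mk2(3.4, eps0 = FALSE)
  shift <- 4 * 0.1 * ((3.4 / 10.5)^12 - (3.4 / 10.5)^6)
  expect_equal(total_energy(topl)$vdw, 0 - shift, tolerance = 1e-9)
  # LJ at the minimum 2^(1/6) sigma: -eps (minus the same shift)
  topm <- mk2(2^(1 / 6) * 3.4, eps0 = FALSE)
  expect_equal(total_energy(topm)$vdw, -0.1 - shift, tolerance = 1e-9)
})

test_that("analytic forces match finite differences on random systems", {
  worst <- 0
  for (seed in 1:3) {
    top <- assign_topology(random_chain_system(n = 10, seed = seed))
    worst <- max(worst, gradient_deviation(top))
  }
  expect_lt(worst, 1e-4)
  # torsion and improper terms in isolation, off-equilibrium
  tt <- bare_quad_topology()
  tt$tor_v <- rep(2.5, length(tt$tor_v))
  tt$tor_g <- rep(0.7, length(tt$tor_g))
  tt$tor_n <- rep(2, length(tt$tor_n))
  expect_lt(gradient_deviation(tt, h = 1e-6), 1e-5)
  ti <- bare_quad_topology()
  ti$imp_i <- 1L; ti$imp_j <- 2L; ti$imp_k <- 3L; ti$imp_l <- 4L
  ti$imp_kf <- 3.0; ti$imp_x0 <- 0.5
  expect_lt(gradient_deviation(ti, h = 1e-6), 1e-5)
})

test_that("internal forces obey Newton's third law", {
  for (seed in 1:3) {
    top <- assign_topology(random_chain_system(n = 12, seed = seed))
    expect_equal(max(abs(colSums(md_forces(top)))), 0, tolerance = 1e-9)
  }
})

test_that("velocity Verlet: exact free flight and harmonic period", {
  atoms <- data.frame(name = "X", element = "C", resname = "T", resid = 1L,
                      x = 10, y = 10, z = 10, charge = 0)
  top <- assign_topology(mol_system(list(molecule(atoms, NULL)), "other",
                                    c(50, 50, 50)))
  v0 <- matrix(c(1, 0.5, -0.2), 1, 3)
  out <- run_md(top, n_steps = 100, vel = v0, sample_every = 100)
  expect_equal(as.numeric(out$pos), c(10, 10, 10) + 0.1 * as.numeric(v0),
               tolerance = 1e-12)
  # dimer as a 1-D oscillator: period 2 pi sqrt(mu / (2 k))
  atoms2 <- data.frame(name = c("A", "B"), element = "C", resname = "T",
                       resid = 1L, x = c(10, 11.6), y = 10, z = 10,
                       charge = 0)
  top2 <- assign_topology(mol_system(list(molecule(atoms2, cbind(1, 2))),
                                     "other", c(50, 50, 50)))
  top2$eps <- c(0, 0)
  top2$bond_k <- 100
  top2$bond_r0 <- 1.5
  out2 <- run_md(top2, n_steps = 10000, dt = 1e-4, sample_every = 1)
  pe <- out2$trace$potential
  peaks <- which(diff(sign(diff(pe))) < 0) + 1
  period <- 2 * mean(diff(out2$trace$time_ps[peaks]))
  mu <- prod(c(12.011, 12.011)) / sum(c(12.011, 12.011))
  expected <- 2 * pi / sqrt(2 * 100 * 418.4 / mu)
  expect_equal(period, expected, tolerance = 0.01)
})

test_that("NVE energy and momentum are conserved", {
  # LJ dimer started inside the attractive well
  atoms <- data.frame(name = c("A", "B"), element = "C", resname = "T",
                      resid = 1L, x = c(10, 13.6), y = 10, z = 10,
                      charge = 0)
  top <- assign_topology(mol_system(list(molecule(atoms, NULL)), "other",
                                    c(50, 50, 50)))
  out <- run_md(top, n_steps = 20000, dt = 0.001, sample_every = 100)
  E <- out$trace$kinetic + out$trace$potential
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-3)
  # linear momentum on a thermalized bonded chain (gentler time step)
  topc <- assign_topology(random_chain_system(n = 8, seed = 4,
                                              box = c(40, 40, 40)))
  vel <- init_velocities(topc, 200, seed = 5)
  outc <- run_md(topc, n_steps = 10000, dt = 2e-4, vel = vel,
                 sample_every = 100)
  p0 <- colSums(vel * topc$mass)
  p1 <- colSums(outc$vel * topc$mass)
  expect_lt(max(abs(p1 - p0)), 1e-8)
})

test_that("collisional thermostat: identity at zero frequency,
           determinism, and temperature recovery", {
  top <- assign_topology(random_chain_system(n = 8, seed = 4))
  vel <- init_velocities(top, 300, seed = 2)
  a <- run_md(top, 200, vel = vel,
              thermostat = thermostat_params(350, 0, 18), seed = 9)
  b <- run_md(top, 200, vel = vel, thermostat = NULL, seed = 10)
  expect_identical(a$pos, b$pos)  # frequency 0 changes nothing
  c1 <- run_md(top, 200, vel = vel,
               thermostat = thermostat_params(350, 10, 18), seed = 7)
  c2 <- run_md(top, 200, vel = vel,
               thermostat = thermostat_params(350, 10, 18), seed = 7)
  expect_identical(c1$pos, c2$pos)  # bit-identical on the same seed
  expect_false(identical(
    c1$pos, run_md(top, 200, vel = vel,
                   thermostat = thermostat_params(350, 10, 18),
                   seed = 8)$pos))
  # temperature recovery on a small LJ gas (short run; looser band than
  # the long acceptance run)
  g <- expand.grid(x = seq(2, 18, len = 4), y = seq(2, 18, len = 4),
                   z = seq(2, 18, len = 3))
  atoms <- data.frame(name = paste0("X", 1:48), element = "C",
                      resname = "T", resid = 1L,
                      x = g$x, y = g$y, z = g$z, charge = 0)
  topg <- assign_topology(mol_system(list(molecule(atoms, NULL)), "other",
                                     c(20, 20, 20)))
  velg <- init_velocities(topg, 350, seed = 3)
  outg <- run_md(topg, 20000, vel = velg,
                 thermostat = thermostat_params(350, 10, 18),
                 sample_every = 50, seed = 11)
  kb <- 0.83144626
  Tser <- outg$trace$kinetic * 418.4 * 2 / (3 * 48 * kb)
  expect_equal(mean(Tser[-(1:50)]), 350, tolerance = 0.10)
})

test_that("thermostat velocities pass a KS test against Maxwell", {
  # ideal gas: LJ off, collisions only
  n <- 64
  g <- expand.grid(x = seq(1, 15, len = 4), y = seq(1, 15, len = 4),
                   z = seq(1, 15, len = 4))
  atoms <- data.frame(name = paste0("X", 1:n), element = "C",
                      resname = "T", resid = 1L, x = g$x, y = g$y,
                      z = g$z, charge = 0)
  top <- assign_topology(mol_system(list(molecule(atoms, NULL)), "other",
                                    c(16, 16, 16)))
  top$eps <- rep(0, n)
  vel <- init_velocities(top, 350, seed = 1)
  vx <- numeric(0)
  out <- run_md(top, 5000, vel = vel,
                thermostat = thermostat_params(350, 10, 18),
                sample_every = 5000, seed = 21)
  vx <- as.numeric(out$vel)  # all components after decorrelation
  kb <- 0.83144626
  sdv <- sqrt(kb * 350 / 12.011)
  ks <- suppressWarnings(stats::ks.test(vx, "pnorm", 0, sdv))
  expect_gt(ks$p.value, 0.01)
})

test_that("steering distributes spring force by mass and modes coincide
           for single atoms", {
  atoms <- data.frame(name = c("A", "B"), element = "C", resname = "T",
                      resid = 1L, x = c(10, 12), y = 10, z = 10,
                      charge = 0)
  top <- assign_topology(mol_system(list(molecule(atoms, NULL)), "other",
                                    c(50, 50, 50)))
  spec <- steering_spec("com", pulled = c(1, 2), k = 10, velocity = 0.1,
                        direction = c(-1, 0, 0))
  # dx = 0 at t = 0: all steering forces zero
  expect_equal(max(abs(steering_forces(top, spec, t = 0))), 0)
  # wall advanced 0.5 A: equal masses each get k dx / 2; sum is k dx
  f <- steering_forces(top, spec, t = 5)
  expect_equal(f[1, 1], -10 * 0.5 / 2)
  expect_equal(f[2, 1], -10 * 0.5 / 2)
  expect_equal(sum(f[, 1]), -10 * 0.5, tolerance = 1e-12)
  # unequal masses: proportional to m_i, vector sum exact
  atoms$element <- c("C", "S")
  topu <- assign_topology(mol_system(list(molecule(atoms, NULL)), "other",
                                     c(50, 50, 50)))
  fu <- steering_forces(topu, spec, t = 5)
  expect_equal(fu[2, 1] / fu[1, 1], 32.06 / 12.011, tolerance = 1e-9)
  expect_equal(sum(fu[, 1]), -10 * 0.5, tolerance = 1e-12)
  # swapping equal-mass atom order leaves a COM-pulled trajectory intact
  atoms$element <- c("C", "C")
  tope <- assign_topology(mol_system(list(molecule(atoms, NULL)), "other",
                                     c(50, 50, 50)))
  o_ab <- run_md(tope, 500, spec = steering_spec("com", c(1, 2), k = 10,
                                                 velocity = 0.1))
  o_ba <- run_md(tope, 500, spec = steering_spec("com", c(2, 1), k = 10,
                                                 velocity = 0.1))
  expect_equal(o_ab$pos, o_ba$pos, tolerance = 1e-12)
  # terminal-atom and COM modes identical for a single-atom selection
  atoms1 <- atoms[1, ]
  top1 <- assign_topology(mol_system(list(molecule(atoms1, NULL)), "other",
                                     c(50, 50, 50)))
  oa <- run_md(top1, 1000, spec = steering_spec("atom", 1, k = 10,
                                                velocity = 0.1))
  oc <- run_md(top1, 1000, spec = steering_spec("com", 1, k = 10,
                                                velocity = 0.1))
  expect_identical(oa$pos, oc$pos)
  expect_error(steering_spec("com", integer(0)), "empty")
  expect_error(steering_spec("com", 1:2, restrained = 2:3), "disjoint")
})

test_that("run_smd records the expected trace bookkeeping", {
  cfg <- mini_build_config()
  sys <- build_system("GA", cfg, solvent = FALSE)
  tr <- run_smd(sys, mode = "com", velocity = 0.1, k = 50,
                n_steps = 500, sample_every = 10, seed = 3)
  expect_s3_class(tr, "force_trace")
  expect_equal(nrow(tr), 500 / 10)
  expect_true(all(diff(tr$time_ps) > 0))
  expect_true(all(is.finite(tr$pulled_force)))
  # same seed reproduces bit-identically
  tr2 <- run_smd(sys, mode = "com", velocity = 0.1, k = 50,
                 n_steps = 500, sample_every = 10, seed = 3)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
  # an interacting (non-bonded) atom pair placed on top of each other
  # aborts with a clear integration error
  bad <- sys
  ip <- which(bad$atoms$role == "peptide")[1]
  il <- which(bad$atoms$role == "lipid")[1]
  bad$atoms$x[ip] <- bad$atoms$x[il]
  bad$atoms$y[ip] <- bad$atoms$y[il]
  bad$atoms$z[ip] <- bad$atoms$z[il] + 1e-4
  expect_error(run_smd(bad, mode = "com", velocity = 0.1, n_steps = 200),
               "overlap|non-finite")
})
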