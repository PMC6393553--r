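test_that("cell-list neighbor search equals the O(N^2) oracle", {
  set.seed(21)
  for (case in list(list(n = 300, box = c(9, 9, 9)),
                    list(n = 200, box = c(12, 8, 16)))) {
    pos <- matrix(runif(3 * case$n), case$n, 3) %*% diag(case$box)
    sys <- particle_system(pos, rep("W", case$n), case$box)
    got <- build_cell_list(sys, 2.5)
    want <- brute_force_pairs(sys$positions, case$box, 2.5)
    expect_identical(pair_key(got), pair_key(want))
  }
  # pair straddling the periodic boundary is found with minimum image
  sysb <- particle_system(rbind(c(0.2, 5, 5), c(11.8, 5, 5)), c("W", "W"),
                          c(12, 12, 12))
  expect_identical(nrow(build_cell_list(sysb, 1.0)), 1L)
  # two particles just inside / outside the cutoff
  d1 <- particle_system(rbind(c(1, 1, 1), c(3.49, 1, 1)), c("W", "W"), c(12, 12, 12))
  d2 <- particle_system(rbind(c(1, 1, 1), c(3.51, 1, 1)), c("W", "W"), c(12, 12, 12))
  expect_identical(nrow(build_cell_list(d1, 2.5)), 1L)
  expect_identical(nrow(build_cell_list(d2, 2.5)), 0L)
  expect_error(build_cell_list(d1, 5, skin = 2), "2 x")
})

test_that("forces obey Newton's third law with all terms active", {
  set.seed(8)
  n <- 120
  pos <- matrix(runif(3 * n), n, 3) %*% diag(c(10, 10, 10))
  spc <- sample(c("W", "H", "T", "O"), n, replace = TRUE)
  sys <- particle_system(pos, spc, c(10, 10, 10))
  idx <- which(spc %in% c("H", "T"))[1:8]
  topo <- make_topo(bonds = cbind(idx[1:4], idx[5:8]), bond_kind = rep(0L, 4),
                    bond_k = rep(100, 4), bond_l0 = rep(1, 4),
                    angles = rbind(idx[c(1, 2, 3)]), angle_k = 50,
                    angle_theta0 = pi,
                    dihedrals = rbind(idx[c(1, 2, 3, 4)]), dih_k = 5, dih_d = 1)
  f <- compute_forces(sys, force_field("nemd"), topo)
  # random placement includes near-overlaps, so compare against the force scale
  scale <- max(abs(f$forces))
  expect_lt(max(abs(colSums(f$forces))) / scale, 1e-12)
  # virial tensor is symmetric
  expect_lt(max(abs(f$virial - t(f$virial))) / max(abs(f$virial)), 1e-12)
})

test_that("velocity Verlet: uniform motion, oscillator period, dimer energy", {
  ff0 <- force_field("custom", eps = matrix(0, 4, 4))
  # single free particle moves uniformly
  sys <- particle_system(matrix(c(1, 1, 1), 1, 3), "W", c(10, 10, 10),
                         matrix(c(0.3, 0, 0), 1, 3))
  run <- md_run(sys, ff0, nsteps = 1000, dt = 0.01, thermostat = "none",
                sample_every = 1000)
  expect_equal(run$system$positions[1, 1], (1 + 0.3 * 10) %% 10,
               tolerance = 1e-12)
  expect_identical(run$system$velocities[1, ], c(0.3, 0, 0))

  # two-body harmonic spring: relative coordinate oscillates with
  # period 2*pi*sqrt(mu/k), mu = 1/2
  k <- 10
  topo <- make_topo(bonds = rbind(c(1L, 2L)), bond_kind = 0L, bond_k = k,
                    bond_l0 = 1)
  sys2 <- particle_system(rbind(c(5, 5, 5), c(6.2, 5, 5)), c("W", "W"),
                          c(20, 20, 20))
  dt <- 0.002
  nst <- 25000
  sep <- numeric(nst %/% 10)
  s <- sys2
  for (i in seq_along(sep)) {
    r <- md_run(s, ff0, topo, nsteps = 10, dt = dt, thermostat = "none",
                sample_every = 10)
    s <- r$system
    sep[i] <- abs(s$positions[2, 1] - s$positions[1, 1])
  }
  x <- sep - 1  # displacement about l0
  crossings <- which(x[-1] * x[-length(x)] < 0)
  period <- 2 * mean(diff(crossings)) * 10 * dt
  expect_equal(period, 2 * pi * sqrt(0.5 / k), tolerance = 1e-3)

  # gently oscillating LJ dimer conserves energy to < 1e-5 over 1e4 steps
  sysd <- particle_system(rbind(c(5, 5, 5), c(5 + 2^(1 / 6) + 0.02, 5, 5)),
                          c("W", "W"), c(12, 12, 12))
  rund <- md_run(sysd, force_field("lv"), nsteps = 10000, thermostat = "none",
                 sample_every = 100)
  e <- rund$samples$etot
  expect_lt(max(abs(e - e[1])), 1e-5)
})

test_that("Langevin thermostat is seeded-reproducible and hits its target", {
  set.seed(3)
  n <- 400
  sys <- particle_system(matrix(runif(3 * n) * 8, n, 3), rep("W", n),
                         c(8, 8, 8), init_velocities(n, 1, 3))
  ff0 <- force_field("custom", eps = matrix(0, 4, 4))
  r1 <- md_run(sys, ff0, nsteps = 2000, thermostat = "langevin",
               T_target = 0.723, damping = 1, seed = 11)
  r2 <- md_run(sys, ff0, nsteps = 2000, thermostat = "langevin",
               T_target = 0.723, damping = 1, seed = 11)
  expect_identical(r1$system$positions, r2$system$positions)
  expect_identical(r1$system$velocities, r2$system$velocities)
  r3 <- md_run(sys, ff0, nsteps = 2000, thermostat = "langevin",
               T_target = 0.723, damping = 1, seed = 12)
  expect_false(identical(r1$system$positions, r3$system$positions))
  s <- r1$samples[r1$samples$step > 500, ]
  expect_equal(mean(s$temperature), 0.723, tolerance = 0.02)
  expect_error(md_run(sys, ff0, nsteps = 10, thermostat = "langevin",
                      T_target = 1, damping = 0), "damping")
})

test_that("virial pressure matches the ideal-gas law and bulk isotropy", {
  set.seed(5)
  n <- 1000
  sys <- particle_system(matrix(runif(3 * n) * 10, n, 3), rep("W", n),
                         c(10, 10, 10), init_velocities(n, 0.9, 5))
  ff0 <- force_field("custom", eps = matrix(0, 4, 4))
  run <- md_run(sys, ff0, nsteps = 4000, thermostat = "langevin", T_target = 0.9,
                damping = 1, seed = 6)
  s <- run$samples[run$samples$step > 1000, ]
  rhoT <- 1.0 * 0.9
  for (cmp in c("Pxx", "Pyy", "Pzz"))
    expect_equal(mean(s[[cmp]]), rhoT, tolerance = 0.05)
  for (cmp in c("Pxy", "Pxz", "Pyz"))
    expect_lt(abs(mean(s[[cmp]])), 0.03)

  # equilibrated bulk liquid is isotropic within statistical scatter
  sysl <- create_bulk_system(0.8, c(8, 8, 8), T_target = 0.723, steps = 2000,
                             seed = 7)
  runl <- md_run(sysl, force_field("lv"), nsteps = 4000,
                 thermostat = "langevin", T_target = 0.723, seed = 8)
  sl <- runl$samples[runl$samples$step > 1000, ]
  expect_lt(abs(mean(sl$Pxx) - mean(sl$Pzz)),
            3 * (stats::sd(sl$Pxx) + stats::sd(sl$Pzz)) / sqrt(nrow(sl)) + 0.05)
  # single-configuration tensor agrees with the sampled one in shape
  P <- pressure_tensor(runl$system, force_field("lv"))
  expect_identical(dim(P), c(3L, 3L))
  expect_lt(max(abs(P - t(P))), 1e-9)
})

test_that("slab construction yields two interfaces and a dilute vapor", {
  slab <- create_slab_system(0.8, c(8, 8, 16), T_target = 0.723, mode = "lv",
                             steps_bulk = 1500, steps_slab = 3000, seed = 2)
  expect_true(slab$slab)
  prof <- velocity_profile(
    md_run(slab, force_field("lv"), nsteps = 500, thermostat = "langevin",
           T_target = 0.723, seed = 3, store_frames = TRUE, sample_every = 50),
    n_bins = 16)
  zint <- locate_interface(prof)
  expect_length(zint, 2)
  expect_gt(diff(zint), 4)  # slab occupies the middle of the box
  dens <- rowSums(prof$density)
  expect_lt(min(dens), 0.1 * max(dens))  # vapor below 10% of liquid
  expect_error(create_slab_system(0.001, c(8, 8, 16), steps_bulk = 0,
                                  steps_slab = 0), "density")
})

test_that("identity-swap insertion preserves counts and registers topology", {
  slab <- create_slab_system(0.8, c(8, 8, 16), T_target = 0.723, mode = "lv",
                             steps_bulk = 1500, steps_slab = 3000, seed = 2)
  n0 <- nrow(slab$positions)
  ins <- insert_copolymers_by_identity_swap(slab, "H6T2", 4, seed = 5,
                                            bond = "harmonic")
  expect_identical(nrow(ins$system$positions), n0)      # density unchanged
  expect_identical(ins$system$positions, slab$positions)
  expect_identical(sum(ins$system$species == "H"), 24L)
  expect_identical(sum(ins$system$species == "T"), 8L)
  expect_identical(nrow(ins$topology$bonds), 4L * 7L)
  expect_length(ins$topology$molecule, 4)
  # chains split between the two interfaces
  zint <- locate_interface(sidmr:::density_profile_system(slab, 16))
  side <- vapply(ins$topology$molecule, function(m)
    which.min(abs(zint - mean(slab$positions[m, 3]))), integer(1))
  expect_setequal(unique(side), c(1L, 2L))

  # triblock: angles and dihedrals only on the middle H block
  ins3 <- insert_copolymers_by_identity_swap(slab, "T2H4T2", 2, seed = 6,
                                             bond = "harmonic")
  expect_identical(nrow(ins3$topology$angles), 2L * 2L)      # 4 H -> 2 angles
  expect_identical(nrow(ins3$topology$dihedrals), 2L * 1L)   # 4 H -> 1 dihedral
  h_beads <- which(ins3$system$species == "H")
  expect_true(all(ins3$topology$angles %in% h_beads))
  expect_true(all(ins3$topology$dihedrals %in% h_beads))

  # count = 0 leaves the system untouched
  ins0 <- insert_copolymers_by_identity_swap(slab, "H6T2", 0)
  expect_identical(ins0$system$species, slab$species)
  expect_identical(nrow(ins0$topology$bonds), 0L)
})

test_that("Kirkwood-Buff surface tension rejects non-slab input and is zero in bulk", {
  sys <- create_bulk_system(0.8, c(8, 8, 8), T_target = 0.723, steps = 1500,
                            seed = 9)
  run <- md_run(sys, force_field("lv"), nsteps = 3000, thermostat = "langevin",
                T_target = 0.723, seed = 10)
  expect_error(surface_tension_kirkwood_buff(run), "non-slab")
  # isotropic bulk: gamma is zero within its own statistical error
  s <- run$samples[run$samples$step > 1000, ]
  g_t <- (8 / 2) * (s$Pzz - (s$Pxx + s$Pyy) / 2)
  batches <- tapply(g_t, cut(seq_along(g_t), 8), mean)
  se <- stats::sd(batches) / sqrt(length(batches))
  expect_lt(abs(mean(g_t)), 5 * se + 0.05)
})
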