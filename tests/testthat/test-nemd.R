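# constructed slab_profiles with a known linear bulk profile and film plateau
constructed_profiles <- function(Lz = 24, n_bins = 24, v_slope = 0.1,
                                 v_plateau = 1.0, interface_z = 12,
                                 sigma_se = 1e-4) {
  z <- seq(Lz / n_bins / 2, Lz - Lz / n_bins / 2, length.out = n_bins)
  vx <- ifelse(z > interface_z, v_plateau + v_slope * 0,  v_slope * (z - 2))
  dens <- matrix(0, n_bins, 4, dimnames = list(NULL, c("W", "H", "T", "O")))
  dens[z <= interface_z, "W"] <- 0.7
  dens[z > interface_z & z <= interface_z + 3, "H"] <- 0.4
  dens[z > interface_z & z <= interface_z + 3, "T"] <- 0.4
  dens[z > interface_z + 3, "O"] <- 0.7
  sidmr:::new_slab_profiles(z, dens, vx, rep(sigma_se, n_bins),
                            rep(1000L, n_bins), c(12, 12, Lz), 100L)
}

test_that("friction coefficient reproduces the momentum-balance arithmetic", {
  # linear bulk profile extrapolating to v_x = 1.5 at the interface and a film
  # plateau at v_x^s = 1.0 with sigma_xz = 1 gives zeta = 2
  n_bins <- 48; Lz <- 24
  z <- seq(Lz / n_bins / 2, Lz - Lz / n_bins / 2, length.out = n_bins)
  interface_z <- 14
  vx <- ifelse(z < interface_z, 1.5 + 0.25 * (z - interface_z), 1.0)
  dens <- matrix(0, n_bins, 4, dimnames = list(NULL, c("W", "H", "T", "O")))
  dens[z < interface_z, "W"] <- 0.7
  dens[z >= interface_z & z < interface_z + 2, "H"] <- 0.5
  dens[z >= interface_z & z < interface_z + 2, "T"] <- 0.5
  prof <- sidmr:::new_slab_profiles(z, dens, vx, rep(1e-6, n_bins),
                                    rep(1000L, n_bins), c(12, 12, Lz), 100L)
  est <- friction_coefficient(prof, interface_z, sigma_xz = 1,
                              direction = -1,
                              surface_region = c(interface_z + 0.1,
                                                 interface_z + 1.9))
  expect_false(est$unresolved)
  expect_equal(est$v_bulk_extrapolated, 1.5, tolerance = 1e-9)
  expect_equal(est$v_surface, 1.0, tolerance = 1e-9)
  expect_equal(est$zeta_xx, 2, tolerance = 1e-6)
  # exact identity: zeta = sigma / (v_bulk - v_surface)
  expect_identical(est$zeta_xx, est$sigma_xz / (est$v_bulk_extrapolated -
                                                est$v_surface))

  # degenerate denominator: flat profile -> perfect-coupling limit
  prof2 <- prof; prof2$vx <- rep(1, n_bins)
  est2 <- friction_coefficient(prof2, interface_z, sigma_xz = 1,
                               direction = -1,
                               surface_region = c(interface_z + 0.1,
                                                  interface_z + 1.9))
  expect_true(est2$unresolved)
  expect_true(is.na(est2$zeta_xx))
  expect_output(print(est2), "perfect-coupling")

  # overlapping regions refuse
  expect_error(friction_coefficient(prof, interface_z, 1, direction = -1,
                                    bulk_fit_region = c(10, 16),
                                    surface_region = c(14, 16)), "overlap")
})

test_that("interfaces are located at density midpoints", {
  n_bins <- 40; Lz <- 20
  z <- seq(0.25, Lz - 0.25, length.out = n_bins)
  dens <- matrix(0, n_bins, 4, dimnames = list(NULL, c("W", "H", "T", "O")))
  # sharp step slab between z = 5 and z = 15
  dens[z > 5 & z < 15, "W"] <- 0.8
  prof <- sidmr:::new_slab_profiles(z, dens, rep(NA_real_, n_bins),
                                    rep(NA_real_, n_bins), rep(1L, n_bins),
                                    c(10, 10, Lz), 1L)
  zi <- locate_interface(prof)
  expect_equal(zi, c(5, 15), tolerance = 0.5)

  # tanh profile of known centres, recovered within half a bin
  dens2 <- dens
  dens2[, "W"] <- 0.4 * (tanh((z - 4.3) / 0.8) - tanh((z - 16.1) / 0.8))
  prof2 <- sidmr:::new_slab_profiles(z, dens2, rep(NA_real_, n_bins),
                                     rep(NA_real_, n_bins), rep(1L, n_bins),
                                     c(10, 10, Lz), 1L)
  zi2 <- locate_interface(prof2)
  expect_equal(zi2[1], 4.3, tolerance = 0.25)
  expect_equal(zi2[2], 16.1, tolerance = 0.25)

  # symmetric two-interface slab: planes symmetric about the centre
  expect_equal(mean(zi2), (4.3 + 16.1) / 2, tolerance = 0.25)

  # featureless profile errors
  dens3 <- dens; dens3[, "W"] <- 0.8
  prof3 <- sidmr:::new_slab_profiles(z, dens3, rep(NA_real_, n_bins),
                                     rep(NA_real_, n_bins), rep(1L, n_bins),
                                     c(10, 10, Lz), 1L)
  expect_error(locate_interface(prof3), "no density transition")
})

test_that("velocity profiles recover constructed frame kinematics", {
  box <- c(6, 6, 12)
  n <- 600
  set.seed(13)
  pos <- matrix(runif(3 * n), n, 3) %*% diag(box)
  # uniform translation
  fr1 <- lapply(1:5, function(i) list(step = i * 50, pos = pos,
                                      vel = cbind(rep(0.37, n), 0, 0)))
  run1 <- fake_run(fr1, box, rep("W", n))
  p1 <- velocity_profile(run1, n_bins = 12)
  expect_true(all(abs(p1$vx - 0.37) < 1e-12))
  expect_equal(sum(p1$density) * prod(box) / 12, n, tolerance = 1e-9)

  # imposed linear profile recovered within 1%
  fr2 <- lapply(1:5, function(i) list(step = i * 50, pos = pos,
                                      vel = cbind(0.05 * (pos[, 3] - 6), 0, 0)))
  p2 <- velocity_profile(fake_run(fr2, box, rep("W", n)), n_bins = 12)
  fit <- stats::lm(p2$vx ~ p2$z)
  expect_equal(unname(coef(fit)[2]), 0.05, tolerance = 0.01)

  # empty bins are flagged, not zeroed
  pos3 <- pos; pos3[, 3] <- pos3[, 3] / 2  # empty the top half
  fr3 <- lapply(1:3, function(i) list(step = i * 50, pos = pos3,
                                      vel = matrix(0, n, 3)))
  p3 <- velocity_profile(fake_run(fr3, box, rep("W", n)), n_bins = 12)
  expect_true(any(p3$empty))
  expect_true(all(is.na(p3$vx[p3$empty])))
})

test_that("shear runs are seeded-deterministic and rate 0 is equilibrium", {
  sys <- create_bulk_system(0.7, c(6, 6, 6), T_target = 1.0, species = "W",
                            forcefield = force_field("nemd"), steps = 1500,
                            seed = 4)
  r1 <- md_run(sys, force_field("nemd"), nsteps = 300, thermostat = "langevin",
               T_target = 1, seed = 5, shear_rate = 0.05)
  r2 <- md_run(sys, force_field("nemd"), nsteps = 300, thermostat = "langevin",
               T_target = 1, seed = 5, shear_rate = 0.05)
  expect_identical(r1$system$positions, r2$system$positions)
  expect_identical(r1$xshift, r2$xshift)

  # rate 0: flat velocity profile within noise
  sr0 <- run_shear(sys, force_field("nemd"), shear_rate = 0, steps = 4000,
                   seed = 6, n_bins = 6, warmup_fraction = 0.25)
  expect_lt(diff(range(sr0$profiles$vx)), 0.15)
  expect_lt(abs(sr0$sigma_xz), 0.05)

  # absurd rate trips the stability guard
  expect_error(run_shear(sys, force_field("nemd"), shear_rate = 50,
                         steps = 100, seed = 1), "stability")
})
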