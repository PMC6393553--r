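#' Desk-scale simulation presets
#'
#' Ready-made small systems for the standard study geometries, sized to run
#' in minutes on one CPU (boxes of 11-13 sigma, 10^3-4x10^3 particles).
#' Paper-scale geometries (50.56 sigma boxes, ~10^5 particles, 10^5-10^6
#' steps) are shipped as YAML configurations under
#' `system.file("configs", package = "sidmr")` and are flagged long-running;
#' they use the same code path.
#'
#' * `desk_couette_system()`: homogeneous W liquid at the NEMD state point
#'   (T = 1.0, rho ~ 0.7), for Couette-flow checks.
#' * `desk_lv_slab()`: bare liquid-vapor W slab at the equilibrium state
#'   point (T = 0.723, rho ~ 0.8), two interfaces normal to z.
#' * `desk_interface_system()`: symmetric W|O|W liquid-liquid sandwich at
#'   T = 1.0 with `count` H_n T_n diblocks (FENE bonds) on the two
#'   interfaces.
#'
#' @param L Lateral box length (sigma).
#' @param rho Number density (sigma^-3).
#' @param T_target Temperature (epsilon/kB).
#' @param seed Integer seed.
#' @param steps_bulk,steps_slab,steps_equil Equilibration step counts.
#' @return A [particle_system()]; `desk_interface_system()` returns a list
#'   with `system`, `topology`, and the `forcefield` used.
#' @export
desk_couette_system <- function(L = 11, rho = 0.7, T_target = 1.0, seed = 1L,
                                steps_bulk = 4000) {
  create_bulk_system(rho, c(L, L, L), T_target, "W",
                     force_field("nemd"), steps = steps_bulk, seed = seed)
}

#' @rdname desk_couette_system
#' @export
desk_lv_slab <- function(L = 12, rho = 0.8, T_target = 0.723, seed = 1L,
                         steps_bulk = 4000, steps_slab = 8000) {
  create_slab_system(rho, c(L, L, 2 * L), T_target, mode = "lv",
                     forcefield = force_field("lv"),
                     steps_bulk = steps_bulk, steps_slab = steps_slab,
                     seed = seed)
}

#' @rdname desk_couette_system
#' @param n Block size of the symmetric H_n T_n diblock.
#' @param count Number of chains (split over the two interfaces).
#' @param Lz Box height (sigma).
#' @export
desk_interface_system <- function(n = 5, count = 12, L = 12, Lz = 24,
                                  rho = 0.7, T_target = 1.0, seed = 1L,
                                  steps_slab = 6000, steps_equil = 6000) {
  ff <- force_field("nemd")
  sys <- create_slab_system(rho, c(L, L, Lz), T_target, mode = "ll",
                            forcefield = ff, steps_bulk = 0,
                            steps_slab = steps_slab, seed = seed)
  ins <- insert_copolymers_by_identity_swap(
    sys, sprintf("H%dT%d", n, n), count, seed = seed + 7L,
    forcefield = ff, bond = "fene")
  if (steps_equil > 0) {
    run <- md_run(ins$system, ff, ins$topology, nsteps = steps_equil,
                  thermostat = "langevin", T_target = T_target,
                  seed = seed + 11L, sample_every = steps_equil)
    ins$system <- run$system
    ins$system$slab <- TRUE
  }
  list(system = ins$system, topology = ins$topology, forcefield = ff)
}
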