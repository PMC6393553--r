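#' Run coarse-grained molecular dynamics
#'
#' Velocity-Verlet integration (BAOAB splitting when the Langevin thermostat
#' is on) of a bead-spring system, optionally under Lees-Edwards sliding-brick
#' shear.  Under shear the thermostat acts only on the velocity components
#' transverse to the flow (y, z), so the streaming profile is not biased.
#'
#' @param system A [particle_system()].
#' @param forcefield A [force_field()].
#' @param topology A [topology()] or `NULL`.
#' @param nsteps Number of time steps.
#' @param dt Time step (sigma sqrt(m/epsilon)); default 0.006.
#' @param thermostat `"langevin"` (canonical ensemble) or `"none"` (NVE).
#' @param T_target Thermostat temperature (epsilon/kB).
#' @param damping Langevin damping time (time units); default 1.
#' @param seed Integer seed for the thermostat noise stream; runs are
#'   bit-reproducible for identical inputs and seed.
#' @param shear_rate Lees-Edwards shear rate (1/time); 0 for equilibrium.
#' @param sample_every Diagnostics sampling interval (steps).
#' @param store_frames Keep position/velocity frames at sample points
#'   (after `frames_from`).
#' @param frames_from First step index from which frames are stored.
#' @param xshift Initial Lees-Edwards offset (sigma).
#' @return An object of class `"md_run"`: final `system`, a `samples` data
#'   frame (step, ke, pe, total energy, kinetic temperature, pressure-tensor
#'   components), optional `frames`, the final Lees-Edwards `xshift`, and the
#'   run parameters.
#' @export
md_run <- function(system, forcefield, topology = NULL, nsteps, dt = 0.006,
                   thermostat = c("langevin", "none"), T_target = 1.0,
                   damping = 1.0, seed = 1L, shear_rate = 0,
                   sample_every = 50L, store_frames = FALSE, frames_from = 0L,
                   xshift = 0) {
  thermostat <- match.arg(thermostat)
  if (thermostat == "langevin" && damping <= 0)
    stop("damping must be positive", call. = FALSE)
  if (thermostat == "langevin" && T_target <= 0)
    stop("T_target must be positive", call. = FALSE)
  ea <- engine_args(system, forcefield, topology)
  rcmax <- max(forcefield$rcut[forcefield$eps > 0], 1)
  if (any(system$box < 2 * rcmax))
    stop("box smaller than twice the interaction cutoff", call. = FALSE)
  if (shear_rate != 0 && abs(shear_rate) * system$box[3] * dt > rcmax / 2)
    stop("stability error: shear displacement per step exceeds half a cell",
         call. = FALSE)
  n <- nrow(system$positions)
  pos <- system$positions
  vel <- system$velocities
  sample_every <- max(1L, as.integer(sample_every))
  n_chunks <- ceiling(nsteps / sample_every)
  samples <- vector("list", n_chunks)
  frames <- if (store_frames) vector("list", n_chunks) else NULL
  vol <- prod(system$box)
  step_now <- 0L
  for (ch in seq_len(n_chunks)) {
    todo <- min(sample_every, nsteps - step_now)
    out <- cpp_run_chunk(pos, vel, ea$species, ea$box, ea$eps, ea$rcut,
                         ea$bonds, ea$bond_kind, ea$bond_k, ea$bond_l0,
                         ea$angles, ea$angle_k, ea$angle_theta0,
                         ea$dihedrals, ea$dih_k, ea$dih_d,
                         as.integer(todo), dt,
                         if (thermostat == "langevin") 1L else 0L,
                         T_target, damping, shear_rate, xshift,
                         shear_rate != 0, as.numeric(seed) * 2^20 + ch)
    pos <- out$pos; vel <- out$vel; xshift <- out$xshift
    step_now <- step_now + todo
    K <- crossprod(vel)  # sum of m v_a v_b
    P <- (K + out$virial) / vol
    samples[[ch]] <- c(step = step_now, ke = out$ke, pe = out$pe,
                       etot = out$ke + out$pe,
                       temperature = 2 * out$ke / (3 * n),
                       Pxx = P[1, 1], Pyy = P[2, 2], Pzz = P[3, 3],
                       Pxy = P[1, 2], Pxz = P[1, 3], Pyz = P[2, 3])
    if (store_frames && step_now >= frames_from)
      frames[[ch]] <- list(step = step_now, pos = pos, vel = vel)
  }
  samples <- as.data.frame(do.call(rbind, samples))
  if (store_frames) frames <- Filter(Negate(is.null), frames)
  final <- particle_system(pos, system$species, system$box, vel,
                           slab = isTRUE(system$slab))
  structure(list(system = final, samples = samples, frames = frames,
                 box = system$box, xshift = xshift, dt = dt,
                 thermostat = thermostat, T_target = T_target,
                 damping = damping, shear_rate = shear_rate, nsteps = nsteps,
                 seed = seed, species = system$species),
            class = "md_run")
}

#' @export
print.md_run <- function(x, ...) {
  cat(sprintf("MD run: %d steps, dt = %g, %s%s\n", x$nsteps, x$dt,
              if (x$thermostat == "none") "NVE"
              else sprintf("Langevin T = %g (damping %g)", x$T_target, x$damping),
              if (x$shear_rate != 0)
                sprintf(", Lees-Edwards shear rate %g", x$shear_rate) else ""))
  s <- x$samples
  cat(sprintf("  final E = %.6g (ke %.4g, pe %.4g), <T_kin> = %.4g\n",
              s$etot[nrow(s)], s$ke[nrow(s)], s$pe[nrow(s)],
              mean(s$temperature)))
  invisible(x)
}

#' Forces, potential energy and virial of a configuration
#'
#' Single-point evaluation with the same kernel the integrator uses.
#'
#' @inheritParams md_run
#' @param xshift Lees-Edwards offset (sigma).
#' @return List with `forces` (N x 3), `pe`, and the 3 x 3 configurational
#'   `virial` tensor.
#' @export
compute_forces <- function(system, forcefield, topology = NULL, xshift = 0) {
  ea <- engine_args(system, forcefield, topology)
  cpp_forces(system$positions, ea$species, ea$box, ea$eps, ea$rcut,
             ea$bonds, ea$bond_kind, ea$bond_k, ea$bond_l0,
             ea$angles, ea$angle_k, ea$angle_theta0,
             ea$dihedrals, ea$dih_k, ea$dih_d, xshift)
}

#' Instantaneous virial pressure tensor
#'
#' `P = (sum_i m v_i (x) v_i + W) / V` with `W` the configurational virial
#' (pairwise plus bonded contributions).
#'
#' @inheritParams compute_forces
#' @return 3 x 3 pressure tensor (epsilon/sigma^3).
#' @export
pressure_tensor <- function(system, forcefield, topology = NULL, xshift = 0) {
  f <- compute_forces(system, forcefield, topology, xshift)
  (crossprod(system$velocities) + f$virial) / prod(system$box)
}

#' Neighbor pairs within a cutoff (cell list)
#'
#' Every unique pair within `cutoff + skin`, minimum-image convention, using
#' a linked-cell search (falling back to an all-pairs scan for boxes smaller
#' than three cells per dimension).
#'
#' @param system A [particle_system()].
#' @param cutoff Interaction cutoff (sigma).
#' @param skin Extra margin (sigma).
#' @return Two-column integer matrix of 1-based pair indices, each pair once.
#' @export
build_cell_list <- function(system, cutoff, skin = 0) {
  if (any(system$box < 2 * (cutoff + skin)))
    stop("box smaller than 2 x (cutoff + skin)", call. = FALSE)
  cpp_neighbor_pairs(system$positions, system$box, cutoff + skin, 0)
}

#' Kirkwood-Buff surface tension of a slab system
#'
#' For a slab with `n_interfaces` interfaces normal to z,
#' `gamma = (Lz / n_interfaces) * (<Pzz> - (<Pxx> + <Pyy>) / 2)`.
#'
#' @param run An [md_run()] of a slab system, or a 3 x 3 pressure tensor.
#' @param Lz Box height (sigma); taken from `run` when available.
#' @param n_interfaces Number of interfaces (2 for a periodic slab).
#' @param warmup_fraction Fraction of samples discarded as equilibration when
#'   `run` is an `md_run`.
#' @return List with `gamma` (epsilon/sigma^2), its standard error `se`
#'   (batch-mean estimate; `NA` for a single tensor), and the mean normal and
#'   transverse pressures.
#' @export
surface_tension_kirkwood_buff <- function(run, Lz = NULL, n_interfaces = 2,
                                          warmup_fraction = 0.5) {
  if (inherits(run, "md_run")) {
    if (!isTRUE(run$system$slab))
      stop("non-slab geometry: Kirkwood-Buff route requires interfaces normal to z",
           call. = FALSE)
    Lz <- run$box[3]
    s <- run$samples
    s <- s[s$step > warmup_fraction * max(s$step), , drop = FALSE]
    g_t <- (Lz / n_interfaces) * (s$Pzz - (s$Pxx + s$Pyy) / 2)
    nb <- max(2, min(10, floor(nrow(s) / 5)))
    batches <- tapply(g_t, cut(seq_along(g_t), nb), mean)
    list(gamma = mean(g_t), se = stats::sd(batches) / sqrt(length(batches)),
         Pzz = mean(s$Pzz), Ptrans = mean((s$Pxx + s$Pyy) / 2))
  } else {
    P <- as.matrix(run)
    stopifnot(dim(P) == c(3, 3))
    if (is.null(Lz)) stop("Lz required when passing a pressure tensor", call. = FALSE)
    list(gamma = (Lz / n_interfaces) * (P[3, 3] - (P[1, 1] + P[2, 2]) / 2),
         se = NA_real_, Pzz = P[3, 3], Ptrans = (P[1, 1] + P[2, 2]) / 2)
  }
}
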