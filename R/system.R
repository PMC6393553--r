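SPECIES <- c("W", "H", "T", "O")

#' Coarse-grained particle system
#'
#' Positions, velocities, species labels and an orthorhombic periodic box, in
#' reduced Lennard-Jones units (epsilon = sigma = m = kB = 1).  Species are
#' `W` (water-like solvent), `H` (hydrophilic block), `T` (hydrophobic
#' block), `O` (oil-like solvent).
#'
#' @param positions N x 3 numeric matrix (sigma); wrapped into the box.
#' @param species Character vector of length N with values in
#'   `c("W","H","T","O")`.
#' @param box Box lengths `c(Lx, Ly, Lz)` (sigma).
#' @param velocities Optional N x 3 matrix (sigma per time unit); defaults to
#'   zeros.
#' @param slab Logical: does the system contain interfaces normal to z
#'   (liquid slab / liquid-liquid sandwich)?
#' @return An object of class `"particle_system"`.
#' @export
particle_system <- function(positions, species, box, velocities = NULL,
                            slab = FALSE) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(box) == 3, all(box > 0))
  n <- nrow(positions)
  if (length(species) != n) stop("species must have one label per particle", call. = FALSE)
  if (!all(species %in% SPECIES))
    stop("species labels must be in {W, H, T, O}", call. = FALSE)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  stopifnot(nrow(velocities) == n, ncol(velocities) == 3)
  dimnames(positions) <- NULL
  dimnames(velocities) <- NULL
  species <- as.character(species)
  for (d in 1:3) positions[, d] <- positions[, d] %% box[d]
  structure(list(positions = positions, velocities = velocities,
                 species = species, box = as.numeric(box), slab = slab),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("Particle system: N = %d in box %.4g x %.4g x %.4g sigma%s\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3],
              if (x$slab) " (slab, interfaces normal to z)" else ""))
  print(table(factor(x$species, levels = SPECIES)))
  invisible(x)
}

species_codes <- function(system) match(system$species, SPECIES)

#' Pair force field for the bead-spring model
#'
#' Symmetric matrices of Lennard-Jones well depths and cutoffs over the four
#' species, plus default bonded parameters.  Cutoff `2.5` sigma keeps the
#' attractive branch; `2^(1/6)` sigma is purely repulsive (WCA).
#'
#' `preset = "nemd"` follows the symmetric liquid-liquid surfactant rule:
#' all well depths equal, identical pairs plus H-W and T-O attractive
#' (cutoff 2.5), all other pairs purely repulsive.  `preset = "lv"` is the
#' package's convention for the liquid-vapor amphiphile systems: identical
#' pairs and H-W attractive, T-W and H-T repulsive.
#'
#' @param preset `"lv"`, `"nemd"`, or `"custom"`.
#' @param eps,rcut Optional 4 x 4 matrices (species order W, H, T, O)
#'   overriding the preset.
#' @param bond_k,bond_l0 Harmonic bond constants (epsilon/sigma^2, sigma).
#' @param fene_k,fene_l0 FENE bond constants.
#' @param angle_k,angle_theta0 Harmonic angle constants (epsilon/rad^2, rad).
#' @param dih_k,dih_d Dihedral constants (epsilon, +-1).
#' @return An object of class `"force_field"`.
#' @export
force_field <- function(preset = c("lv", "nemd", "custom"), eps = NULL,
                        rcut = NULL, bond_k = 1000, bond_l0 = 1,
                        fene_k = 30, fene_l0 = 1.5,
                        angle_k = 50, angle_theta0 = pi, dih_k = 5, dih_d = 1) {
  preset <- match.arg(preset)
  wca <- 2^(1 / 6)
  if (is.null(eps)) eps <- matrix(1, 4, 4, dimnames = list(SPECIES, SPECIES))
  if (is.null(rcut)) {
    rcut <- matrix(wca, 4, 4, dimnames = list(SPECIES, SPECIES))
    attractive <- switch(preset,
      lv = list(c("W", "W"), c("H", "H"), c("T", "T"), c("O", "O"), c("W", "H")),
      nemd = list(c("W", "W"), c("H", "H"), c("T", "T"), c("O", "O"),
                  c("W", "H"), c("T", "O")),
      custom = list())
    for (p in attractive) {
      rcut[p[1], p[2]] <- 2.5
      rcut[p[2], p[1]] <- 2.5
    }
  }
  eps <- as.matrix(eps); rcut <- as.matrix(rcut)
  stopifnot(dim(eps) == c(4, 4), dim(rcut) == c(4, 4))
  if (any(abs(eps - t(eps)) > 1e-12) || any(abs(rcut - t(rcut)) > 1e-12))
    stop("eps and rcut matrices must be symmetric", call. = FALSE)
  structure(list(eps = eps, rcut = rcut, bond_k = bond_k, bond_l0 = bond_l0,
                 fene_k = fene_k, fene_l0 = fene_l0, angle_k = angle_k,
                 angle_theta0 = angle_theta0, dih_k = dih_k, dih_d = dih_d,
                 preset = preset),
            class = "force_field")
}

#' Bonded topology
#'
#' Bond/angle/dihedral lists for the copolymer chains, with per-interaction
#' constants.  Created empty and grown by
#' [insert_copolymers_by_identity_swap()].
#'
#' @return An object of class `"topology"`.
#' @export
topology <- function() {
  structure(list(bonds = matrix(0L, 0, 2), bond_kind = integer(0),
                 bond_k = numeric(0), bond_l0 = numeric(0),
                 angles = matrix(0L, 0, 3), angle_k = numeric(0),
                 angle_theta0 = numeric(0),
                 dihedrals = matrix(0L, 0, 4), dih_k = numeric(0),
                 dih_d = numeric(0), molecule = list()),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("Topology: %d bonds, %d angles, %d dihedrals, %d molecules\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              length(x$molecule)))
  invisible(x)
}

empty_or <- function(topo) topo %||% topology()

# argument bundle for the C++ kernel
engine_args <- function(system, forcefield, topo = NULL) {
  topo <- empty_or(topo)
  list(species = as.integer(species_codes(system)),
       box = system$box, eps = forcefield$eps, rcut = forcefield$rcut,
       bonds = matrix(as.integer(topo$bonds), ncol = 2),
       bond_kind = as.integer(topo$bond_kind),
       bond_k = as.numeric(topo$bond_k), bond_l0 = as.numeric(topo$bond_l0),
       angles = matrix(as.integer(topo$angles), ncol = 3),
       angle_k = as.numeric(topo$angle_k),
       angle_theta0 = as.numeric(topo$angle_theta0),
       dihedrals = matrix(as.integer(topo$dihedrals), ncol = 4),
       dih_k = as.numeric(topo$dih_k), dih_d = as.numeric(topo$dih_d))
}

#' Maxwell-Boltzmann velocities
#'
#' Draws velocities at temperature `T_target` and removes the centre-of-mass
#' drift.
#'
#' @param n Number of particles.
#' @param T_target Temperature (epsilon/kB).
#' @param seed Integer seed.
#' @return n x 3 matrix.
#' @export
init_velocities <- function(n, T_target, seed = 1L) {
  v <- with_seed(seed, matrix(stats::rnorm(3 * n, sd = sqrt(T_target)), n, 3))
  sweep(v, 2, colMeans(v))
}

#' Build an equilibrated bulk Lennard-Jones liquid
#'
#' Particles start on a simple-cubic lattice at the target density and are
#' relaxed with a Langevin thermostat.
#'
#' @param rho Number density (sigma^-3).
#' @param box Box lengths `c(Lx, Ly, Lz)` (sigma).
#' @param T_target Temperature (epsilon/kB).
#' @param species Species label for all particles.
#' @param forcefield A [force_field()]; defaults to the `"lv"` preset.
#' @param steps Equilibration steps.
#' @param seed Integer seed.
#' @param dt Time step.
#' @return A [particle_system()].
#' @export
create_bulk_system <- function(rho, box, T_target = 0.723, species = "W",
                               forcefield = force_field("lv"), steps = 3000,
                               seed = 1L, dt = 0.006) {
  box <- as.numeric(box)
  n <- round(rho * prod(box))
  m <- ceiling(n^(1 / 3))
  grid <- as.matrix(expand.grid(x = (seq_len(m) - 0.5) / m,
                                y = (seq_len(m) - 0.5) / m,
                                z = (seq_len(m) - 0.5) / m))
  idx <- with_seed(seed, sample.int(nrow(grid), n))
  pos <- sweep(grid[idx, , drop = FALSE], 2, box, `*`)
  sys <- particle_system(pos, rep(species, n), box,
                         init_velocities(n, T_target, seed))
  if (steps > 0) {
    run <- md_run(sys, forcefield, nsteps = steps, dt = dt,
                  thermostat = "langevin", T_target = T_target,
                  damping = 1, seed = seed, sample_every = steps)
    sys <- run$system
  }
  sys
}

#' Build an equilibrated slab system with two interfaces normal to z
#'
#' In liquid-vapor mode (`"lv"`), a bulk liquid is equilibrated in a box of
#' height `Lz/2` which is then extended to `Lz`, leaving a liquid slab in the
#' middle of the box with two liquid-vapor interfaces.  In liquid-liquid mode
#' (`"ll"`), the whole box is filled at the target density with an O slab
#' sandwiched between two W slabs of equal total particle count, giving two
#' W-O interfaces.
#'
#' @param rho Liquid number density (sigma^-3): around 0.8 for the
#'   liquid-vapor systems at T = 0.723, around 0.7 for the liquid-liquid
#'   systems at T = 1.0.
#' @param box Final box `c(Lx, Ly, Lz)` (sigma).
#' @param T_target Temperature (epsilon/kB).
#' @param mode `"lv"` or `"ll"`.
#' @param forcefield A [force_field()]; defaults to the preset matching
#'   `mode`.
#' @param steps_bulk,steps_slab Equilibration steps before and after creating
#'   the interfaces.
#' @param seed Integer seed.
#' @param dt Time step.
#' @return A [particle_system()] with `slab = TRUE`.
#' @export
create_slab_system <- function(rho, box, T_target = 0.723,
                               mode = c("lv", "ll"), forcefield = NULL,
                               steps_bulk = 4000, steps_slab = 8000,
                               seed = 1L, dt = 0.006) {
  mode <- match.arg(mode)
  box <- as.numeric(box)
  if (is.null(forcefield))
    forcefield <- force_field(if (mode == "lv") "lv" else "nemd")
  if (round(rho * prod(box)) < 8)
    stop("density incompatible with box: too few particles", call. = FALSE)
  if (mode == "lv") {
    half <- c(box[1], box[2], box[3] / 2)
    sys <- create_bulk_system(rho, half, T_target, "W", forcefield,
                              steps = steps_bulk, seed = seed, dt = dt)
    # extend the box along z, liquid slab centred
    pos <- sys$positions
    pos[, 3] <- pos[, 3] + box[3] / 4
    sys <- particle_system(pos, sys$species, box, sys$velocities, slab = TRUE)
  } else {
    n <- 2 * floor(rho * prod(box) / 2)  # equal W and O counts
    cbrt <- (n / prod(box))^(1 / 3)
    mx <- ceiling(cbrt * box[1]); my <- ceiling(cbrt * box[2])
    mz <- ceiling(n / (mx * my))
    while (mx * my * mz < n) mz <- mz + 1
    grid <- as.matrix(expand.grid(x = (seq_len(mx) - 0.5) / mx * box[1],
                                  y = (seq_len(my) - 0.5) / my * box[2],
                                  z = (seq_len(mz) - 0.5) / mz * box[3]))
    sel <- grid[round(seq(1, nrow(grid), length.out = n)), , drop = FALSE]
    # O slab in the middle of the box, W above and below (wrapping through
    # the periodic z faces): split by distance from the slab centre
    ord <- order(abs(sel[, 3] - box[3] / 2))
    spc <- rep("W", n)
    spc[ord[seq_len(n %/% 2)]] <- "O"
    sys <- particle_system(sel, spc, box, init_velocities(n, T_target, seed),
                           slab = TRUE)
  }
  if (steps_slab > 0) {
    run <- md_run(sys, forcefield, nsteps = steps_slab, dt = dt,
                  thermostat = "langevin", T_target = T_target, damping = 1,
                  seed = seed + 1L, sample_every = steps_slab)
    sys <- run$system
    sys$slab <- TRUE
  }
  sys
}
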