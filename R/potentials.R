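#' Truncated-and-shifted Lennard-Jones pair potential
#'
#' Energy is `4*eps*((1/r)^12 - (1/r)^6)` minus the same expression evaluated
#' at `rcut`, for `r <= rcut`, and 0 beyond; the shift makes the energy
#' continuous (zero) at the cutoff.  The force is the negative radial
#' derivative of the unshifted form for `r <= rcut`, else 0.  Lengths in
#' sigma, energies in epsilon (reduced units, sigma = 1).  A cutoff of
#' `2^(1/6)` truncates at the potential minimum, leaving a purely repulsive
#' (WCA-type) interaction.
#'
#' @param r Pair distance (sigma), positive; vectorized.
#' @param eps Well depth (epsilon).
#' @param rcut Cutoff distance (sigma).
#' @return A list with `energy` and `force` (radial force magnitude on the
#'   pair, positive = repulsive), each the length of `r`.
#' @export
#' @examples
#' lj_truncated_shifted(2^(1/6), rcut = 2^(1/6))  # energy 0, force 0
lj_truncated_shifted <- function(r, eps = 1, rcut = 2.5) {
  if (any(r <= 0)) stop("singular overlap: r must be positive", call. = FALSE)
  i6 <- (1 / r)^6
  i6c <- (1 / rcut)^6
  u <- 4 * eps * (i6^2 - i6) - 4 * eps * (i6c^2 - i6c)
  f <- 24 * eps * (2 * i6^2 - i6) / r
  out <- r > rcut
  u[out] <- 0
  f[out] <- 0
  list(energy = u, force = f)
}

#' Harmonic bond potential
#'
#' `u = (k/2) (l - l0)^2`.
#'
#' @param l Bond length (sigma), non-negative.
#' @param k Spring constant (epsilon/sigma^2).
#' @param l0 Equilibrium length (sigma).
#' @return Energy (epsilon).
#' @export
harmonic_bond <- function(l, k = 1000, l0 = 1) {
  if (any(l < 0)) stop("bond length must be non-negative", call. = FALSE)
  0.5 * k * (l - l0)^2
}

#' FENE bond potential
#'
#' Finitely extensible nonlinear elastic spring,
#' `u = -(k/2) l0^2 log(1 - (l/l0)^2)`, diverging at the maximum extension
#' `l0`.  Defaults are the bead-spring standard `k = 30 epsilon/sigma^2`,
#' `l0 = 1.5 sigma`.
#'
#' @param l Bond length (sigma), in `[0, l0)`.
#' @param k Spring constant (epsilon/sigma^2).
#' @param l0 Maximum extension (sigma).
#' @return Energy (epsilon).
#' @export
#' @examples
#' fene_bond(1.0)  # about 19.84 epsilon
fene_bond <- function(l, k = 30, l0 = 1.5) {
  if (any(l < 0)) stop("bond length must be non-negative", call. = FALSE)
  if (any(l >= l0)) stop("overstretched bond: l >= l0", call. = FALSE)
  -0.5 * k * l0^2 * log(1 - (l / l0)^2)
}

#' Harmonic angle potential
#'
#' `u = (k/2) (theta - theta0)^2`, angles in radians.
#'
#' @param theta Bond angle (radians).
#' @param k Stiffness (epsilon/rad^2).
#' @param theta0 Equilibrium angle (radians).
#' @return Energy (epsilon).
#' @export
harmonic_angle <- function(theta, k = 50, theta0 = pi) {
  0.5 * k * (theta - theta0)^2
}

#' Cosine dihedral potential
#'
#' `u = k * (1 + d * cos(phi))`, phi in radians (cis convention, phi = 0).
#'
#' @param phi Dihedral angle (radians).
#' @param k Barrier parameter (epsilon).
#' @param d Phase sign, +1 or -1.
#' @return Energy (epsilon).
#' @export
dihedral <- function(phi, k = 5, d = 1) {
  k * (1 + d * cos(phi))
}
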