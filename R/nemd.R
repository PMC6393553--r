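new_slab_profiles <- function(z, density, vx, vx_se, counts, box, n_frames) {
  structure(list(z = z, density = density, vx = vx, vx_se = vx_se,
                 counts = counts, box = box, n_frames = n_frames,
                 empty = counts == 0 | rowSums(density) == 0),
            class = "slab_profiles")
}

# single-configuration density profile (used for interface location during
# system construction)
density_profile_system <- function(system, n_bins = 40) {
  box <- system$box
  edges <- seq(0, box[3], length.out = n_bins + 1)
  binvol <- box[1] * box[2] * diff(edges)[1]
  bin <- pmin(pmax(findInterval(system$positions[, 3] %% box[3], edges,
                                rightmost.closed = TRUE), 1L), n_bins)
  dens <- sapply(SPECIES, function(s)
    tabulate(bin[system$species == s], nbins = n_bins) / binvol)
  counts <- tabulate(bin, nbins = n_bins)
  new_slab_profiles(z = (edges[-1] + edges[-length(edges)]) / 2,
                    density = dens, vx = rep(NA_real_, n_bins),
                    vx_se = rep(NA_real_, n_bins), counts = counts,
                    box = box, n_frames = 1L)
}

#' Per-bin density and velocity profiles along the interface normal
#'
#' Bins the stored frames of a run into slabs along z and computes per-bin,
#' per-species number densities and the mean x-velocity with its standard
#' error (frame-to-frame scatter of the bin mean).  Bins never occupied are
#' flagged in `$empty`, not silently zeroed.
#'
#' @param run An [md_run()] (or the object returned by [run_shear()]) with
#'   stored frames.
#' @param n_bins Number of z bins.
#' @param warmup_fraction Frames from the first `warmup_fraction` of the run
#'   are discarded (steady-state sampling).
#' @return An object of class `"slab_profiles"`: bin centres `z`, `density`
#'   (bins x species, sigma^-3), `vx`, `vx_se`, `counts`, `empty`.
#' @export
velocity_profile <- function(run, n_bins = 40, warmup_fraction = 0) {
  if (inherits(run, "shear_run")) run <- run$run
  stopifnot(inherits(run, "md_run"))
  if (is.null(run$frames) || !length(run$frames))
    stop("run has no stored frames; rerun with store_frames = TRUE", call. = FALSE)
  box <- run$box
  frames <- run$frames
  steps <- vapply(frames, `[[`, numeric(1), "step")
  frames <- frames[steps > warmup_fraction * max(steps)]
  nf <- length(frames)
  edges <- seq(0, box[3], length.out = n_bins + 1)
  binvol <- box[1] * box[2] * diff(edges)[1]
  spc <- run$species
  dens_acc <- matrix(0, n_bins, length(SPECIES), dimnames = list(NULL, SPECIES))
  counts <- integer(n_bins)
  vx_frame <- matrix(NA_real_, n_bins, nf)
  for (f in seq_len(nf)) {
    pos <- frames[[f]]$pos; vel <- frames[[f]]$vel
    bin <- pmin(pmax(findInterval(pos[, 3] %% box[3], edges,
                                  rightmost.closed = TRUE), 1L), n_bins)
    counts <- counts + tabulate(bin, nbins = n_bins)
    for (s in SPECIES)
      dens_acc[, s] <- dens_acc[, s] + tabulate(bin[spc == s], nbins = n_bins)
    sums <- tapply(vel[, 1], factor(bin, levels = seq_len(n_bins)), mean)
    vx_frame[, f] <- as.numeric(sums)
  }
  vx <- rowMeans(vx_frame, na.rm = TRUE)
  nocc <- rowSums(!is.na(vx_frame))
  vx_se <- apply(vx_frame, 1, stats::sd, na.rm = TRUE) / sqrt(pmax(nocc, 1))
  vx[nocc == 0] <- NA_real_
  new_slab_profiles(z = (edges[-1] + edges[-length(edges)]) / 2,
                    density = dens_acc / (binvol * nf), vx = vx, vx_se = vx_se,
                    counts = counts, box = box, n_frames = nf)
}

#' @export
print.slab_profiles <- function(x, ...) {
  cat(sprintf("Slab profiles: %d bins over Lz = %.4g sigma, %d frame(s)\n",
              length(x$z), x$box[3], x$n_frames))
  if (any(x$empty)) cat(sprintf("  %d empty bin(s) flagged\n", sum(x$empty)))
  invisible(x)
}

#' Locate the interfaces in a slab density profile
#'
#' For a liquid-vapor slab, returns the two z positions where the solvent
#' density crosses the equimolar value (midway between the liquid and vapor
#' plateaus): the Gibbs dividing planes.  For a liquid-liquid (W|O|W) system,
#' returns the two W/O density-crossing planes.
#'
#' @param profiles A `"slab_profiles"` object.
#' @param mode `"auto"` (liquid-liquid when an O phase is present), `"lv"`,
#'   or `"ll"`.
#' @return Numeric vector of two interface z positions (sigma), sorted.
#' @export
locate_interface <- function(profiles, mode = c("auto", "lv", "ll")) {
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (sum(profiles$density[, "O"]) > 0) "ll" else "lv"
  z <- profiles$z
  f <- if (mode == "lv") {
    dw <- rowSums(profiles$density[, c("W", "H", "T"), drop = FALSE])
    dw - (max(dw) + min(dw)) / 2
  } else {
    dw <- profiles$density[, "W"] + profiles$density[, "H"]
    doo <- profiles$density[, "O"] + profiles$density[, "T"]
    dw - doo
  }
  s <- which(f[-length(f)] * f[-1] < 0)
  if (!length(s))
    stop("no density transition found in the profile", call. = FALSE)
  zc <- vapply(s, function(i)
    z[i] + (z[i + 1] - z[i]) * f[i] / (f[i] - f[i + 1]), numeric(1))
  if (length(zc) > 2) {
    # keep the two steepest crossings
    steep <- order(abs(f[s + 1] - f[s]), decreasing = TRUE)[1:2]
    zc <- zc[steep]
  }
  sort(zc)
}

#' Steady-state shear stress from the off-diagonal virial
#'
#' `sigma_xz = -<P_xz>` averaged over the steady-state samples, with a
#' batch-mean standard error.
#'
#' @param run An [md_run()] or [run_shear()] result.
#' @param warmup_fraction Fraction of the run discarded as transient.
#' @return List with `sigma_xz` and `se` (epsilon/sigma^3).
#' @export
shear_stress <- function(run, warmup_fraction = 2 / 3) {
  if (inherits(run, "shear_run")) run <- run$run
  s <- run$samples
  s <- s[s$step > warmup_fraction * max(s$step), , drop = FALSE]
  x <- -s$Pxz
  nb <- max(2, min(10, floor(length(x) / 5)))
  batches <- tapply(x, cut(seq_along(x), nb), mean)
  list(sigma_xz = mean(x), se = stats::sd(batches) / sqrt(length(batches)))
}

#' Shear an interfacial system with Lees-Edwards boundaries
#'
#' Imposes the shear rate through sliding-brick periodic images (gradient
#' along z, flow along x); the Langevin thermostat acts only on the y and z
#' velocity components so the streaming velocity is unbiased.  Sampling
#' (profiles, shear stress) uses the final third of the run by default; the
#' first two thirds are treated as the approach to steady state.
#'
#' @inheritParams md_run
#' @param steps Number of time steps.
#' @param n_bins Bins for the velocity/density profiles.
#' @param warmup_fraction Fraction of the run discarded before sampling.
#' @return An object of class `"shear_run"`: the underlying `run`, steady
#'   `profiles`, and `sigma_xz` (with standard error).
#' @export
run_shear <- function(system, forcefield, topology = NULL, shear_rate, steps,
                      seed = 1L, T_target = 1.0, damping = 1.0, dt = 0.006,
                      sample_every = 50L, n_bins = 40,
                      warmup_fraction = 2 / 3) {
  run <- md_run(system, forcefield, topology, nsteps = steps, dt = dt,
                thermostat = "langevin", T_target = T_target,
                damping = damping, seed = seed, shear_rate = shear_rate,
                sample_every = sample_every, store_frames = TRUE,
                frames_from = ceiling(warmup_fraction * steps))
  prof <- velocity_profile(run, n_bins = n_bins)
  st <- shear_stress(run, warmup_fraction)
  structure(list(run = run, profiles = prof, sigma_xz = st$sigma_xz,
                 sigma_xz_se = st$se, shear_rate = shear_rate),
            class = "shear_run")
}

#' @export
print.shear_run <- function(x, ...) {
  cat(sprintf("NEMD shear run: rate %g, sigma_xz = %.4g +- %.2g eps/sigma^3\n",
              x$shear_rate, x$sigma_xz, x$sigma_xz_se))
  invisible(x)
}

#' Bulk-interface momentum-transfer (friction) coefficient
#'
#' At a sheared interface the steady shear stress and the velocity jump
#' between the bulk phase and the interfacial film obey
#' `sigma_xz = zeta_xx * (v_x - v_x^s)`, where `v_x` is the bulk velocity
#' profile linearly extrapolated to the interface plane and `v_x^s` the
#' (nearly z-independent) film velocity.  This computes `zeta_xx` with
#' propagated uncertainty from one interface of a `"slab_profiles"` object.
#'
#' @param profiles A `"slab_profiles"` object from a steady sheared run.
#' @param interface_z Interface plane (sigma), e.g. from [locate_interface()].
#' @param sigma_xz Steady shear stress (epsilon/sigma^3), e.g. from
#'   [shear_stress()].
#' @param sigma_xz_se Its standard error.
#' @param bulk_fit_region Two-element z range used for the linear bulk fit;
#'   default `interface_z + direction * c(3, 10)` where `direction` points
#'   away from the film into the W bulk.
#' @param surface_region Two-element z range averaged for the film velocity;
#'   default: a bead-scale band (plus/minus 1.5 sigma, or one bin if wider)
#'   centred on the interface plane.
#' @param direction +1 if the W bulk lies above the interface, -1 below;
#'   guessed from the density profiles when `NULL`.
#' @return An object of class `"friction_estimate"`: `zeta_xx`, `zeta_se`,
#'   `sigma_xz`, `v_bulk_extrapolated`, `v_surface`, their uncertainties,
#'   `unresolved` (TRUE when the velocity jump is below its own uncertainty:
#'   the perfect-coupling limit, zeta unresolved).
#' @export
friction_coefficient <- function(profiles, interface_z, sigma_xz,
                                 sigma_xz_se = 0, bulk_fit_region = NULL,
                                 surface_region = NULL, direction = NULL) {
  stopifnot(inherits(profiles, "slab_profiles"))
  z <- profiles$z
  film <- profiles$density[, "H"] + profiles$density[, "T"]
  if (is.null(direction)) {
    dw <- profiles$density[, "W"]
    up <- mean(dw[z > interface_z & z < interface_z + 5], na.rm = TRUE)
    dn <- mean(dw[z < interface_z & z > interface_z - 5], na.rm = TRUE)
    direction <- if (isTRUE(up >= dn) || is.nan(dn)) 1 else -1
  }
  dz_bin <- diff(z)[1]
  if (is.null(surface_region)) {
    # the interfacial layer: a bead-scale band centred on the dividing plane
    # (the copolymer tails smear the film density into the solvent phases, so
    # a film-density-peak construction is unreliable on small boxes)
    surface_region <- interface_z + c(-1, 1) * max(1.5, dz_bin)
  }
  if (is.null(bulk_fit_region)) {
    bulk_fit_region <- sort(interface_z + direction * c(3, 10))
    # the Lees-Edwards image velocity is discontinuous across the z boundary,
    # so the bulk fit never crosses it
    bulk_fit_region <- pmin(pmax(bulk_fit_region, 0), profiles$box[3])
    inb <- z >= bulk_fit_region[1] & z <= bulk_fit_region[2] &
      !is.na(profiles$vx)
    if (sum(inb) < 3) {
      # desk-scale boxes leave little bulk between film and box face: widen
      # the fit region toward the interface, staying just clear of the film
      inner <- if (direction > 0)
        max(interface_z + 1.5, max(surface_region) + dz_bin)
      else
        min(interface_z - 1.5, min(surface_region) - dz_bin)
      outer <- if (direction > 0) bulk_fit_region[2] else bulk_fit_region[1]
      bulk_fit_region <- sort(c(inner, outer))
    }
  }
  if (max(min(bulk_fit_region), min(surface_region)) <
      min(max(bulk_fit_region), max(surface_region)))
    stop("bulk_fit_region and surface_region overlap", call. = FALSE)

  inb <- z >= bulk_fit_region[1] & z <= bulk_fit_region[2] & !is.na(profiles$vx)
  if (sum(inb) < 3) stop("too few bins in the bulk fit region", call. = FALSE)
  fit <- stats::lm(vx ~ z, data = data.frame(z = z[inb], vx = profiles$vx[inb]),
                   weights = profiles$counts[inb])
  pr <- stats::predict(fit, newdata = data.frame(z = interface_z), se.fit = TRUE)
  v_bulk <- unname(pr$fit); v_bulk_se <- unname(pr$se.fit)

  ins <- z >= surface_region[1] & z <= surface_region[2] & !is.na(profiles$vx)
  if (!any(ins)) stop("no occupied bins in the surface region", call. = FALSE)
  v_surf <- mean(profiles$vx[ins])
  v_surf_se <- sqrt(sum(profiles$vx_se[ins]^2)) / sum(ins)

  dv <- v_bulk - v_surf
  dv_se <- sqrt(v_bulk_se^2 + v_surf_se^2)
  unresolved <- abs(dv) <= dv_se
  zeta <- if (unresolved) NA_real_ else sigma_xz / dv
  zeta_se <- if (unresolved) NA_real_ else
    abs(zeta) * sqrt((sigma_xz_se / sigma_xz)^2 + (dv_se / dv)^2)
  structure(list(zeta_xx = zeta, zeta_se = zeta_se, sigma_xz = sigma_xz,
                 sigma_xz_se = sigma_xz_se, v_bulk_extrapolated = v_bulk,
                 v_bulk_se = v_bulk_se, v_surface = v_surf,
                 v_surface_se = v_surf_se, dv = dv, dv_se = dv_se,
                 interface_z = interface_z,
                 bulk_fit_region = bulk_fit_region,
                 surface_region = surface_region, unresolved = unresolved),
            class = "friction_estimate")
}

#' @export
print.friction_estimate <- function(x, ...) {
  if (x$unresolved) {
    cat("Friction estimate: perfect-coupling limit, zeta unresolved\n")
    cat(sprintf("  velocity jump %.3g +- %.3g below its uncertainty\n",
                x$dv, x$dv_se))
  } else {
    cat(sprintf("zeta_xx = %.4g +- %.2g eps/(sigma^3 v) at z = %.3g\n",
                x$zeta_xx, x$zeta_se, x$interface_z))
    cat(sprintf("  sigma_xz = %.4g, v_bulk(z_int) = %.4g, v_surface = %.4g\n",
                x$sigma_xz, x$v_bulk_extrapolated, x$v_surface))
  }
  invisible(x)
}

#' Friction coefficient averaged over the two interfaces of a sheared slab
#'
#' Convenience wrapper: locates both interfaces, estimates `zeta_xx` at each
#' (bulk side outward from the film), and combines the two by inverse-variance
#' weighting.
#'
#' @param sr A [run_shear()] result on a W|O|W film system.
#' @return List with `zeta_xx`, `zeta_se`, and the per-interface
#'   `"friction_estimate"` objects.
#' @export
estimate_friction <- function(sr) {
  stopifnot(inherits(sr, "shear_run"))
  prof <- sr$profiles
  zint <- locate_interface(prof)
  Lz <- prof$box[3]
  # W bulk wraps through the periodic z boundary: lower interface has W below,
  # upper has W above.  On small boxes one side may lack enough clean bulk
  # bins for the linear fit; a failed side is dropped rather than fatal.
  try_est <- function(zi, dir)
    tryCatch(friction_coefficient(prof, zi, sr$sigma_xz, sr$sigma_xz_se,
                                  direction = dir),
             error = function(e) list(unresolved = TRUE, error = conditionMessage(e)))
  ests <- list(lower = try_est(zint[1], -1), upper = try_est(zint[2], +1))
  ok <- !vapply(ests, `[[`, logical(1), "unresolved")
  if (!any(ok))
    return(list(zeta_xx = NA_real_, zeta_se = NA_real_, interfaces = ests,
                unresolved = TRUE))
  zs <- vapply(ests[ok], function(e) abs(e$zeta_xx), numeric(1))
  ws <- vapply(ests[ok], function(e) 1 / max(e$zeta_se, 1e-12)^2, numeric(1))
  list(zeta_xx = sum(zs * ws) / sum(ws),
       zeta_se = sqrt(1 / sum(ws)), interfaces = ests, unresolved = FALSE)
}
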