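#' Deformation protocol for a synthetic tensiometry run
#'
#' Describes the drop-tensiometer protocol a synthetic trace emulates: an
#' adsorption/aging phase, an area step applied over a short actuator ramp,
#' and a post-step observation window.
#'
#' @param equilibration_s Adsorption-phase duration (s).  Tensiometry practice
#'   for these stabilizers ranges from ~1000 s to several hours; values in
#'   [1000, 21600] are accepted.
#' @param step_fraction Signed relative area change (e.g. `+0.10`, `-0.20`).
#' @param step_duration_s Ramp time of the step (s), default 2.
#' @param hold_s Post-step observation window (s).
#' @param sample_interval_s Sampling interval (s), default 1.
#' @return An object of class `"deformation_protocol"`.
#' @export
deformation_protocol <- function(equilibration_s = 1000, step_fraction = 0.10,
                                 step_duration_s = 2, hold_s = 1500,
                                 sample_interval_s = 1) {
  if (any(!is.finite(c(equilibration_s, step_duration_s, hold_s, sample_interval_s))) ||
      equilibration_s < 0 || step_duration_s <= 0 || hold_s <= 0 ||
      sample_interval_s <= 0)
    stop("protocol error: durations must be positive", call. = FALSE)
  if (equilibration_s > 0 && (equilibration_s < 1000 || equilibration_s > 21600))
    stop("protocol error: equilibration_s outside tensiometry practice [1000, 21600] s",
         call. = FALSE)
  if (!is.finite(step_fraction) || abs(step_fraction) <= 0 || abs(step_fraction) >= 1)
    stop("protocol error: |step_fraction| must lie in (0, 1)", call. = FALSE)
  structure(list(equilibration_s = equilibration_s, step_fraction = step_fraction,
                 step_duration_s = step_duration_s, hold_s = hold_s,
                 sample_interval_s = sample_interval_s),
            class = "deformation_protocol")
}

#' Generation spec for a synthetic relaxation trace
#'
#' @param relax_params [kww_params()] truth for the post-step relaxation.
#' @param adsorption_amplitude,adsorption_tau Amplitude (mN/m) and time scale
#'   (s) of the pre-step aging decay `amp * exp(-t/tau)` riding on the
#'   baseline.  Adsorption/aging of these films has very long time tails, so
#'   the default time scale (2000 s) is much longer than the KWW time.
#' @param noise_sd Gaussian measurement-noise standard deviation (mN/m),
#'   non-negative; drop tensiometers resolve ~0.01-0.1 mN/m.
#' @param seed Integer RNG seed; identical spec + seed gives a bit-identical
#'   trace.
#' @return An object of class `"trace_spec"`.
#' @export
trace_spec <- function(relax_params, adsorption_amplitude = 5,
                       adsorption_tau = 2000, noise_sd = 0, seed = 1L) {
  validate_kww_params(relax_params)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be non-negative", call. = FALSE)
  if (!is.finite(adsorption_tau) || adsorption_tau <= 0)
    stop("adsorption_tau must be positive", call. = FALSE)
  structure(list(relax_params = relax_params,
                 adsorption_amplitude = adsorption_amplitude,
                 adsorption_tau = adsorption_tau,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "trace_spec")
}

# Noise-free trace values on a given grid (exported through noise_sd = 0).
synthetic_trace_mean <- function(spec, protocol, t) {
  p <- spec$relax_params
  t_step <- protocol$equilibration_s
  t_end <- t_step + protocol$step_duration_s
  # adsorption baseline tends to the post-relaxation plateau c + b, with an
  # aging transient on top
  baseline <- function(tt) p$c + p$b +
    spec$adsorption_amplitude * exp(-tt / spec$adsorption_tau)
  peak <- kww_aging(p, 0)                    # a + b + c at the step end
  g <- numeric(length(t))
  pre <- t < t_step
  ramp <- t >= t_step & t < t_end
  post <- t >= t_end
  g[pre] <- baseline(t[pre])
  g0 <- baseline(t_step)
  g[ramp] <- g0 + (peak - g0) * (t[ramp] - t_step) / protocol$step_duration_s
  g[post] <- kww_aging(p, t[post] - t_end)
  g
}

#' Generate a synthetic drop-tensiometry trace
#'
#' Emulates a step-dilatation experiment: an adsorption/aging decay toward the
#' film's quasi-equilibrium surface stress, a linear actuator ramp of the area
#' step over `step_duration_s`, then KWW-plus-aging relaxation with time
#' zeroed at the step end, with additive Gaussian measurement noise.
#'
#' The sign of the relaxation amplitude must match the step direction: the
#' surface stress overshoots upward on expansion (`a > 0`) and undershoots on
#' compression (`a < 0`).
#'
#' @param spec A [trace_spec()].
#' @param protocol A [deformation_protocol()].
#' @return A [relaxation_trace()] with `truth` set to the generating
#'   parameters.
#' @export
#' @examples
#' p <- kww_params(a = 5, tau1 = 19.5, beta = 0.55, b = 1, tau2 = 2000, c = 50)
#' tr <- generate_trace(trace_spec(p, noise_sd = 0.05, seed = 7),
#'                      deformation_protocol())
generate_trace <- function(spec, protocol) {
  stopifnot(inherits(spec, "trace_spec"), inherits(protocol, "deformation_protocol"))
  if (sign(spec$relax_params$a) != sign(protocol$step_fraction) &&
      spec$relax_params$a != 0)
    stop("protocol error: sign of relaxation amplitude a must match step_fraction",
         call. = FALSE)
  t <- seq(0, protocol$equilibration_s + protocol$step_duration_s + protocol$hold_s,
           by = protocol$sample_interval_s)
  g <- synthetic_trace_mean(spec, protocol, t)
  if (spec$noise_sd > 0)
    g <- g + with_seed(spec$seed, stats::rnorm(length(t), sd = spec$noise_sd))
  relaxation_trace(t, g,
                   step_time = protocol$equilibration_s,
                   step_fraction = protocol$step_fraction,
                   step_duration = protocol$step_duration_s,
                   phase_label = if (protocol$step_fraction > 0) "expansion" else "compression",
                   truth = spec$relax_params)
}

#' Generate a paired expansion/compression experiment
#'
#' Two traces sharing the same adsorption baseline, as in the experimental
#' protocol where the droplet is first expanded and later compressed by the
#' same fraction.  Suitable for end-to-end asymmetry analyses.
#'
#' @param spec_exp,spec_comp [trace_spec()] objects for the expansion and
#'   compression phases; the relaxation amplitudes must have opposite signs.
#' @param protocol A [deformation_protocol()]; its `step_fraction` magnitude is
#'   used with `+` for expansion and `-` for compression.
#' @return A list with elements `expansion` and `compression`, both
#'   [relaxation_trace()] objects.
#' @export
generate_paired_experiment <- function(spec_exp, spec_comp, protocol) {
  a_e <- spec_exp$relax_params$a; a_c <- spec_comp$relax_params$a
  if (a_e < 0 || a_c > 0)
    stop("protocol error: expansion amplitude must be >= 0 and compression amplitude <= 0",
         call. = FALSE)
  frac <- abs(protocol$step_fraction)
  proto_e <- protocol; proto_e$step_fraction <- frac
  proto_c <- protocol; proto_c$step_fraction <- -frac
  # zero-amplitude pairs are allowed (flat post-step traces)
  make <- function(sp, pr) {
    if (sp$relax_params$a == 0) {
      t <- seq(0, pr$equilibration_s + pr$step_duration_s + pr$hold_s,
               by = pr$sample_interval_s)
      g <- synthetic_trace_mean(sp, pr, t)
      if (sp$noise_sd > 0)
        g <- g + with_seed(sp$seed, stats::rnorm(length(t), sd = sp$noise_sd))
      relaxation_trace(t, g, pr$equilibration_s, pr$step_fraction,
                       pr$step_duration_s,
                       if (pr$step_fraction > 0) "expansion" else "compression",
                       truth = sp$relax_params)
    } else generate_trace(sp, pr)
  }
  e <- make(spec_exp, proto_e)
  co <- make(spec_comp, proto_c)
  # both phases observe the same physical drop, so they share the adsorption
  # baseline (taken from the expansion spec)
  pre <- co$t < protocol$equilibration_s
  co$gamma[pre] <- e$gamma[pre]
  list(expansion = e, compression = co)
}
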