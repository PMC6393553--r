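#' Locate the post-step surface-stress extremum
#'
#' Fitting starts from the maximum (minimum) value of the surface stress after
#' the step in extension (compression).  The extremum is searched within
#' `[step_time, step_time + search_window]`.
#'
#' @param trace A [relaxation_trace()].
#' @param search_window Width of the search window (s); defaults to 3x the
#'   step duration.
#' @return Sample index (into `trace$t`) of the extremum.
#' @export
locate_step_extremum <- function(trace, search_window = 3 * trace$step_duration) {
  stopifnot(inherits(trace, "relaxation_trace"))
  idx <- which(trace$t >= trace$step_time & trace$t <= trace$step_time + search_window)
  if (length(idx) == 0L)
    stop("empty window: no samples at or after step_time", call. = FALSE)
  k <- if (trace$phase_label == "compression") which.min(trace$gamma[idx])
       else which.max(trace$gamma[idx])
  idx[k]
}

# model on the internal optimizer scale:
# p = (a, log tau1, beta, b, r, c) with tau2 = 5 * tau1 * exp(r), r >= 0,
# which enforces the identifiability constraint tau2 >= 5 tau1 exactly.
kww_model_internal <- function(p, t) {
  tau1 <- exp(p[2]); tau2 <- 5 * tau1 * exp(p[5])
  p[1] * exp(-(t / tau1)^p[3]) + p[4] * exp(-t / tau2) + p[6]
}

internal_to_params <- function(p) {
  tau1 <- exp(p[2])
  kww_params(a = p[1], tau1 = tau1, beta = min(p[3], 1), b = p[4],
             tau2 = 5 * tau1 * exp(p[5]), c = p[6])
}

# standard errors on the natural scale from a central-difference Jacobian of
# the model at the optimum: cov = s^2 * (J'J)^+ (pseudo-inverse; the aging
# term can be weakly identified on short windows)
kww_param_se <- function(params, t, rss, n) {
  th <- unlist(params[c("a", "tau1", "beta", "b", "tau2", "c")])
  f <- function(v) {
    q <- as.list(v); names(q) <- names(th)
    q$a * exp(-(t / q$tau1)^q$beta) + q$b * exp(-t / q$tau2) + q$c
  }
  J <- matrix(0, length(t), 6L)
  for (j in seq_len(6L)) {
    h <- max(1e-7, 1e-7 * abs(th[j]))
    up <- th; up[j] <- up[j] + h
    dn <- th; dn[j] <- dn[j] - h
    J[, j] <- (f(up) - f(dn)) / (2 * h)
  }
  dof <- max(n - 6L, 1L)
  s2 <- rss / dof
  sv <- svd(crossprod(J))
  pos <- sv$d > max(sv$d) * 1e-12
  cov <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos]) * s2
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- names(th)
  se
}

#' Fit the KWW-plus-aging model to a relaxation trace
#'
#' Least-squares fit of the six-parameter stretched-exponential-plus-aging
#' model to the post-step portion of a surface-stress trace.  Following
#' step-dilatation practice, the fit uses samples from the post-step extremum
#' (maximum in extension, minimum in compression) through `window` seconds
#' later, with time re-zeroed at the extremum.
#'
#' KWW least-squares surfaces are multi-modal, so the optimizer (bounded
#' Levenberg-Marquardt) is restarted from a grid of initial values: `tau1`
#' log-spaced in `[1, window/2]` crossed with `beta` in {0.4, 0.6, 0.8, 1.0};
#' the aging time starts at 10x the window (aging is the slow background).
#' Bounds are `0.05 <= beta <= 1`, `tau1, tau2 > 0`, and the identifiability
#' constraint `tau2 >= 5 tau1` is enforced throughout.  Among converged
#' restarts the fit with the lowest residual sum of squares wins; near-ties
#' are resolved toward the largest `beta` (the less-stretched explanation).
#'
#' @param trace A [relaxation_trace()].
#' @param window Fit-window length (s) measured from the extremum; default
#'   1000 s.
#' @param restarts Number of optimizer restarts (>= 1).  The first 16 come
#'   from the deterministic grid; extra restarts jitter the grid using `seed`.
#' @param seed Integer seed for jittered restarts (only used when
#'   `restarts > 16`).
#' @return An object of class `"kwwfit"` with components `params`
#'   ([kww_params()]), `se` (per-parameter standard errors), `residual_rms`
#'   (mN/m), `window` (`[t_start, t_end]` actually used, s),
#'   `extremum_index`, `converged`, `n_restarts_used`, `truncated`,
#'   `n`, `t` (re-zeroed), `gamma`, `fitted`, `phase_label`, `trace`.
#' @seealso [asymmetry_report()], [locate_step_extremum()]
#' @export
#' @examples
#' p <- kww_params(a = 5, tau1 = 19.5, beta = 0.55, b = 1, tau2 = 2000, c = 50)
#' tr <- generate_trace(trace_spec(p), deformation_protocol())
#' fit <- kwwfit(tr)
#' coef(fit)
kwwfit <- function(trace, window = 1000, restarts = 16L, seed = 1L) {
  stopifnot(inherits(trace, "relaxation_trace"))
  i0 <- locate_step_extremum(trace)
  t0 <- trace$t[i0]
  keep <- which(trace$t >= t0 & trace$t <= t0 + window)
  truncated <- (t0 + window) > trace$t[length(trace$t)] + 1e-9
  warn <- if (truncated) "window extends past trace end; fit truncated" else NULL
  if (truncated) warning(warn, call. = FALSE)
  if (length(keep) < 30L)
    stop("need at least 30 samples inside the fit window", call. = FALSE)
  tt <- trace$t[keep] - t0
  gg <- trace$gamma[keep]

  # initial values: offset from the trace tail, amplitude split 80/20 between
  # the stretched and aging terms
  c0 <- mean(gg[max(1, length(gg) - 9):length(gg)])
  amp <- gg[1] - c0
  tau1_grid <- exp(seq(log(1), log(window / 2), length.out = 4))
  beta_grid <- c(0.4, 0.6, 0.8, 1.0)
  starts <- expand.grid(tau1 = tau1_grid, beta = beta_grid)
  starts <- starts[seq_len(min(nrow(starts), max(1L, restarts))), , drop = FALSE]
  n_extra <- max(0L, restarts - nrow(starts))
  if (n_extra > 0L) {
    extra <- with_seed(seed, data.frame(
      tau1 = exp(stats::runif(n_extra, log(1), log(window / 2))),
      beta = stats::runif(n_extra, 0.3, 1.0)))
    starts <- rbind(starts, extra)
  }
  tau2_init <- 10 * window

  lower <- c(-Inf, log(1e-3), 0.05, -Inf, 0, -Inf)
  upper <- c(Inf, log(1e6), 1, Inf, log(1e7), Inf)
  resid_fn <- function(p) kww_model_internal(p, tt) - gg

  best <- NULL; n_used <- 0L
  for (k in seq_len(nrow(starts))) {
    p0 <- c(0.8 * amp, log(starts$tau1[k]), starts$beta[k], 0.2 * amp,
            max(0, log(tau2_init / (5 * starts$tau1[k]))), c0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    n_used <- n_used + 1L
    if (is.null(fit) || !fit$info %in% 1:4 || any(!is.finite(fit$par))) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr * (1 - 1e-8) ||
        (abs(ssr - best$ssr) <= best$ssr * 1e-8 + 1e-300 &&
         fit$par[3] > best$par[3])) {
      best <- list(par = fit$par, ssr = ssr)
    }
  }

  if (is.null(best)) {
    out <- structure(list(params = NULL, se = NULL, residual_rms = NA_real_,
                          window = c(t0, t0 + window), extremum_index = i0,
                          converged = FALSE, n_restarts_used = n_used,
                          truncated = truncated, warning = warn,
                          n = length(tt), t = tt, gamma = gg, fitted = NULL,
                          phase_label = trace$phase_label, trace = trace),
                     class = "kwwfit")
    return(out)
  }

  params <- internal_to_params(best$par)
  fitted <- kww_aging(params, tt)
  rss <- sum((gg - fitted)^2)
  se <- kww_param_se(params, tt, rss, length(tt))
  structure(list(params = params, se = se,
                 residual_rms = sqrt(rss / length(tt)),
                 window = c(t0, min(t0 + window, trace$t[length(trace$t)])),
                 extremum_index = i0, converged = TRUE,
                 n_restarts_used = n_used, truncated = truncated, warning = warn,
                 n = length(tt), t = tt, gamma = gg, fitted = fitted,
                 phase_label = trace$phase_label, trace = trace),
            class = "kwwfit")
}

#' @export
coef.kwwfit <- function(object, ...) {
  if (!object$converged) return(stats::setNames(rep(NA_real_, 6),
                                                c("a", "tau1", "beta", "b", "tau2", "c")))
  unlist(object$params[c("a", "tau1", "beta", "b", "tau2", "c")])
}

#' @export
residuals.kwwfit <- function(object, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  object$gamma - object$fitted
}

#' @export
fitted.kwwfit <- function(object, ...) object$fitted

#' @export
predict.kwwfit <- function(object, t = NULL, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  if (is.null(t)) return(object$fitted)
  kww_aging(object$params, t)
}

#' @export
print.kwwfit <- function(x, ...) {
  cat(sprintf("KWW + aging fit (%s)\n", x$phase_label))
  if (!x$converged) {
    cat(sprintf("  NOT CONVERGED after %d restarts\n", x$n_restarts_used))
    return(invisible(x))
  }
  cf <- coef(x)
  cat(sprintf("  beta = %.4g (se %.2g), tau1 = %.4g s (se %.2g)\n",
              cf["beta"], x$se["beta"], cf["tau1"], x$se["tau1"]))
  cat(sprintf("  a = %.4g, b = %.4g, tau2 = %.4g, c = %.4g mN/m\n",
              cf["a"], cf["b"], cf["tau2"], cf["c"]))
  cat(sprintf("  residual RMS %.3g mN/m on %d samples, window [%.4g, %.4g] s\n",
              x$residual_rms, x$n, x$window[1], x$window[2]))
  if (x$truncated) cat("  note: window extended past trace end (truncated)\n")
  invisible(x)
}

#' @export
summary.kwwfit <- function(object, ...) {
  out <- list(fit = object,
              table = if (object$converged)
                cbind(estimate = coef(object), std.error = object$se) else NULL,
              mean_relaxation_time = if (object$converged)
                kww_mean_relaxation_time(object$params$tau1, object$params$beta)
                else NA_real_,
              heterogeneous = if (object$converged)
                (1 - object$params$beta) > object$se["beta"] else NA)
  class(out) <- "summary.kwwfit"
  out
}

#' @export
print.summary.kwwfit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$table)) {
    cat("\nParameter table:\n")
    print(round(x$table, 6))
    cat(sprintf("\nMean KWW relaxation time <tau> = %.4g s\n", x$mean_relaxation_time))
    cat(sprintf("Dynamic heterogeneity (beta < 1 beyond its se): %s\n",
                x$heterogeneous))
  }
  invisible(x)
}

#' @export
plot.kwwfit <- function(x, ...) {
  if (!x$converged) stop("fit did not converge", call. = FALSE)
  graphics::plot(x$t, x$gamma, pch = 16, cex = 0.4, col = "grey40",
                 xlab = "time since extremum (s)",
                 ylab = "surface stress (mN/m)", ...)
  graphics::lines(x$t, x$fitted, col = "firebrick", lwd = 2)
  graphics::legend("topright", c("data", "KWW + aging fit"),
                   col = c("grey40", "firebrick"), pch = c(16, NA),
                   lty = c(NA, 1), bty = "n")
  invisible(x)
}

#' Simulate new traces from a fitted relaxation model
#'
#' Draws synthetic step-dilatation traces whose post-step phase follows the
#' fitted parameters, with Gaussian noise at the fitted residual RMS.
#'
#' @param object A converged [kwwfit()].
#' @param nsim Number of traces.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of [relaxation_trace()] objects.
#' @export
simulate.kwwfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  tr <- object$trace
  proto <- deformation_protocol(
    equilibration_s = max(1000, tr$step_time),
    step_fraction = tr$step_fraction,
    step_duration_s = tr$step_duration,
    hold_s = max(diff(object$window), 10),
    sample_interval_s = stats::median(diff(tr$t)))
  base_seed <- if (is.null(seed)) 1L else as.integer(seed)
  lapply(seq_len(nsim), function(i)
    generate_trace(trace_spec(object$params, noise_sd = object$residual_rms,
                              seed = base_seed + i - 1L), proto))
}

#' Expansion/compression asymmetry of the relaxation dynamics
#'
#' Complex interfaces relax with a smaller stretch exponent in extension than
#' in compression; this quantifies that asymmetry from two fits.  The
#' "dynamic heterogeneity" flag is raised, separately per phase, when the
#' fitted `beta` falls below 1 by more than its standard error.
#'
#' @param fit_expansion,fit_compression Converged [kwwfit()] objects.
#' @return A list: `delta_beta` (`beta_compression - beta_expansion`),
#'   `tau1_ratio` (`tau1_compression / tau1_expansion`),
#'   `heterogeneous_expansion`, `heterogeneous_compression`, and the two
#'   (beta, se) pairs.
#' @export
asymmetry_report <- function(fit_expansion, fit_compression) {
  stopifnot(inherits(fit_expansion, "kwwfit"), inherits(fit_compression, "kwwfit"))
  failed <- c(if (!fit_expansion$converged) "expansion",
              if (!fit_compression$converged) "compression")
  if (length(failed))
    stop(sprintf("unconverged fit on the %s side", paste(failed, collapse = " and ")),
         call. = FALSE)
  be <- fit_expansion$params$beta; bc <- fit_compression$params$beta
  list(delta_beta = bc - be,
       tau1_ratio = fit_compression$params$tau1 / fit_expansion$params$tau1,
       heterogeneous_expansion = (1 - be) > fit_expansion$se["beta"][[1]],
       heterogeneous_compression = (1 - bc) > fit_compression$se["beta"][[1]],
       beta_expansion = be, se_beta_expansion = fit_expansion$se[["beta"]],
       beta_compression = bc, se_beta_compression = fit_compression$se[["beta"]])
}
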