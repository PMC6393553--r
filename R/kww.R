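#' Parameter set for the stretched-exponential-plus-aging relaxation model
#'
#' The surface-stress relaxation of a complex fluid-fluid interface after a
#' step dilatation is described by
#' \deqn{\gamma(t) = a\,e^{-(t/\tau_1)^\beta} + b\,e^{-t/\tau_2} + c,}
#' a Kohlrausch-Williams-Watts (KWW) stretched exponential (amplitude `a`,
#' relaxation time `tau1`, stretch exponent `beta`) superposed on a regular
#' exponential aging term (amplitude `b`, time `tau2`) and a stress offset
#' `c`.  `beta < 1` is the signature of dynamic heterogeneity: relaxation
#' through a broad distribution of local relaxation times.  The aging term
#' describes the slow post-adsorption rearrangement of the interfacial film,
#' present even without deformation.
#'
#' Stress amplitudes are in mN/m and times in seconds.  `a` and `b` may be
#' negative: on compression the surface stress undershoots and relaxes
#' upwards, so the fitted amplitudes flip sign relative to expansion.
#'
#' @param a Stretched-term amplitude (mN/m).
#' @param tau1 KWW relaxation time (s); must be positive.
#' @param beta Stretch exponent, in (0, 1].
#' @param b Aging amplitude (mN/m).
#' @param tau2 Aging time (s); must be positive.
#' @param c Stress offset (mN/m).
#' @return An object of class `"kww_params"`: a named list with the six
#'   fields above.
#' @seealso [kww_aging()], [kwwfit()], [kww_params_to_json()]
#' @export
#' @examples
#' kww_params(a = 5, tau1 = 19.5, beta = 0.55, b = 1, tau2 = 2000, c = 50)
kww_params <- function(a, tau1, beta, b, tau2, c) {
  p <- list(a = a, tau1 = tau1, beta = beta, b = b, tau2 = tau2, c = c)
  validate_kww_params(p)
  structure(p, class = "kww_params")
}

validate_kww_params <- function(p) {
  vals <- unlist(p[c("a", "tau1", "beta", "b", "tau2", "c")])
  if (length(vals) != 6L || !all(is.finite(vals)))
    stop("invalid parameters: all six of a, tau1, beta, b, tau2, c must be finite numbers",
         call. = FALSE)
  if (p$tau1 <= 0 || p$tau2 <= 0)
    stop("invalid parameters: tau1 and tau2 must be positive", call. = FALSE)
  if (p$beta <= 0 || p$beta > 1)
    stop("invalid parameters: beta must lie in (0, 1]", call. = FALSE)
  invisible(p)
}

#' @export
print.kww_params <- function(x, ...) {
  cat("KWW + aging relaxation parameters\n")
  cat(sprintf("  stretched term: a = %.4g mN/m, tau1 = %.4g s, beta = %.4g\n",
              x$a, x$tau1, x$beta))
  cat(sprintf("  aging term:     b = %.4g mN/m, tau2 = %.4g s\n", x$b, x$tau2))
  cat(sprintf("  offset:         c = %.4g mN/m\n", x$c))
  invisible(x)
}

#' Evaluate the KWW-plus-aging relaxation model
#'
#' Computes `a*exp(-(t/tau1)^beta) + b*exp(-t/tau2) + c` elementwise over a
#' time grid, time measured from the end of the area step.
#'
#' @param params A [kww_params()] object (or plain named list with the same
#'   six fields).
#' @param t Time (s), scalar or vector; must be non-negative.
#' @return Surface stress (mN/m), same length as `t`.
#' @export
#' @examples
#' p <- kww_params(a = 1, tau1 = 10, beta = 0.5, b = 0, tau2 = 100, c = 0)
#' kww_aging(p, 0)   # a + b + c = 1
#' kww_aging(p, 10)  # exp(-1)
kww_aging <- function(params, t) {
  validate_kww_params(params)
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("t must be finite numeric", call. = FALSE)
  if (any(t < 0))
    stop("t must be non-negative (time is measured from the step end)", call. = FALSE)
  params$a * exp(-(t / params$tau1)^params$beta) +
    params$b * exp(-t / params$tau2) + params$c
}

#' Mean relaxation time of a stretched exponential
#'
#' The integral mean of `exp(-(t/tau1)^beta)` over t in (0, Inf):
#' `<tau> = (tau1 / beta) * Gamma(1 / beta)`.  For `beta = 1` this reduces to
#' `tau1`; for `beta < 1` the broad tail of the underlying relaxation-time
#' distribution makes `<tau>` exceed `tau1`.
#'
#' @param tau1 KWW relaxation time (s), positive.
#' @param beta Stretch exponent in (0, 1].
#' @return Mean relaxation time (s).
#' @export
#' @examples
#' kww_mean_relaxation_time(7, 1)      # 7
#' kww_mean_relaxation_time(1, 0.5)    # 2
kww_mean_relaxation_time <- function(tau1, beta) {
  if (!is.numeric(beta) || any(!is.finite(beta)) || any(beta <= 0) || any(beta > 1))
    stop("beta must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(tau1) || any(!is.finite(tau1)) || any(tau1 <= 0))
    stop("tau1 must be positive", call. = FALSE)
  (tau1 / beta) * gamma(1 / beta)
}

#' Surface pressure of a stabilized interface
#'
#' `pi = gamma0 - gamma_t`: the reduction of the bare-interface surface
#' tension by the adsorbed film.
#'
#' @param gamma0 Surface tension of the bare fluid-fluid interface (mN/m).
#' @param gamma_t Measured surface stress of the stabilized interface (mN/m).
#' @return Surface pressure (mN/m).
#' @export
#' @examples
#' surface_pressure(72, 57)  # 15 mN/m
surface_pressure <- function(gamma0, gamma_t) {
  if (any(!is.finite(gamma0)) || any(!is.finite(gamma_t)))
    stop("gamma0 and gamma_t must be finite", call. = FALSE)
  gamma0 - gamma_t
}

#' Serialize KWW parameters to/from JSON
#'
#' Parameter sets serialize to a flat JSON record with exactly the six keys
#' `a`, `tau1`, `beta`, `b`, `tau2`, `c`.
#'
#' @param params A [kww_params()] object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `kww_params_to_json()`: the JSON string (invisibly, if written to
#'   file).  `kww_params_from_json()`: a [kww_params()] object.
#' @export
kww_params_to_json <- function(params, path = NULL) {
  validate_kww_params(params)
  js <- jsonlite::toJSON(params[c("a", "tau1", "beta", "b", "tau2", "c")],
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' @rdname kww_params_to_json
#' @param json A JSON string or path to a JSON file.
#' @export
kww_params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  need <- c("a", "tau1", "beta", "b", "tau2", "c")
  if (!all(need %in% names(x)))
    stop("JSON record must contain exactly the fields a, tau1, beta, b, tau2, c",
         call. = FALSE)
  do.call(kww_params, as.list(x[need]))
}
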