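#' Surface-stress relaxation trace
#'
#' A sampled surface-stress-vs-time signal from a step-dilatation drop
#' tensiometry experiment, together with the deformation-protocol metadata
#' needed to analyse it: when the area step started, its signed relative
#' magnitude, and how long the actuator took to apply it.
#'
#' @param t Time grid (s), strictly increasing.
#' @param gamma Surface stress samples (mN/m), same length as `t`.
#' @param step_time Instant the area step begins (s).
#' @param step_fraction Signed relative area change, e.g. `+0.10` for a 10%
#'   expansion, `-0.20` for a 20% compression; `|step_fraction|` in (0, 1).
#' @param step_duration Time over which the step is applied (s), positive;
#'   tensiometer protocols here use 2 s.
#' @param phase_label One of `"adsorption"`, `"expansion"`, `"compression"`.
#'   For traces carrying a step this is the step direction; it decides whether
#'   the post-step extremum is a maximum or a minimum.
#' @param truth Optional [kww_params()] holding generation truth for synthetic
#'   traces (kept as metadata; never used by the fitter).
#' @return An object of class `"relaxation_trace"`.
#' @seealso [kwwfit()], [generate_trace()], [read_trace_csv()]
#' @export
relaxation_trace <- function(t, gamma, step_time, step_fraction, step_duration,
                             phase_label = c("expansion", "compression", "adsorption"),
                             truth = NULL) {
  phase_label <- match.arg(phase_label)
  t <- as.numeric(t); gamma <- as.numeric(gamma)
  if (length(t) != length(gamma))
    stop("t and gamma must have the same length", call. = FALSE)
  if (length(t) < 2L || any(diff(t) <= 0))
    stop("t must be strictly increasing with at least 2 samples", call. = FALSE)
  if (!is.finite(step_duration) || step_duration <= 0)
    stop("step_duration must be positive", call. = FALSE)
  if (!is.finite(step_fraction) || abs(step_fraction) <= 0 || abs(step_fraction) >= 1)
    stop("|step_fraction| must lie in (0, 1)", call. = FALSE)
  if (phase_label == "expansion" && step_fraction < 0)
    stop("expansion requires step_fraction > 0", call. = FALSE)
  if (phase_label == "compression" && step_fraction > 0)
    stop("compression requires step_fraction < 0", call. = FALSE)
  structure(list(t = t, gamma = gamma, step_time = step_time,
                 step_fraction = step_fraction, step_duration = step_duration,
                 phase_label = phase_label, truth = truth),
            class = "relaxation_trace")
}

#' @export
print.relaxation_trace <- function(x, ...) {
  cat(sprintf("Relaxation trace: %d samples, t in [%.4g, %.4g] s\n",
              length(x$t), x$t[1], x$t[length(x$t)]))
  cat(sprintf("  %s step of %+.0f%% at t = %.4g s, applied over %.4g s\n",
              x$phase_label, 100 * x$step_fraction, x$step_time, x$step_duration))
  if (!is.null(x$truth)) cat("  carries synthetic generation truth\n")
  invisible(x)
}

#' Read / write relaxation traces as CSV
#'
#' Traces are stored as a two-column CSV (`time_s`, `gamma_mN_per_m`) with a
#' JSON sidecar (`<path>.json`) holding the deformation-protocol metadata and,
#' for synthetic traces, the generation truth.  Write-then-read reproduces the
#' samples bit-exactly.
#'
#' @param path CSV file path.
#' @param sidecar Sidecar path; defaults to `paste0(path, ".json")`.  On read,
#'   a missing sidecar yields a trace with default protocol metadata (step at
#'   time 0, +10% over 2 s).
#' @return `read_trace_csv()`: a [relaxation_trace()].
#' @export
read_trace_csv <- function(path, sidecar = paste0(path, ".json")) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L)
    stop("trace CSV must have two columns: time_s, gamma_mN_per_m", call. = FALSE)
  tt <- as.numeric(df[[1]]); gg <- as.numeric(df[[2]])
  bad <- which(diff(tt) <= 0)
  if (length(bad))
    stop(sprintf("time column not strictly increasing at row %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  meta <- list(step_time = 0, step_fraction = 0.10, step_duration = 2,
               phase_label = "expansion", truth = NULL)
  if (file.exists(sidecar)) {
    side <- jsonlite::fromJSON(sidecar)
    for (k in c("step_time", "step_fraction", "step_duration"))
      if (!is.null(side[[k]])) meta[[k]] <- as.numeric(side[[k]])
    if (!is.null(side$phase_label)) meta$phase_label <- side$phase_label
    if (!is.null(side$truth)) meta$truth <- do.call(kww_params, as.list(side$truth))
  }
  relaxation_trace(tt, gg, meta$step_time, meta$step_fraction,
                   meta$step_duration, meta$phase_label, truth = meta$truth)
}

#' @rdname read_trace_csv
#' @param trace A [relaxation_trace()].
#' @export
write_trace_csv <- function(trace, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(trace, "relaxation_trace"))
  writeLines(c("time_s,gamma_mN_per_m",
               sprintf("%.17g,%.17g", trace$t, trace$gamma)), path)
  side <- list(step_time = trace$step_time, step_fraction = trace$step_fraction,
               step_duration = trace$step_duration, phase_label = trace$phase_label)
  if (!is.null(trace$truth))
    side$truth <- trace$truth[c("a", "tau1", "beta", "b", "tau2", "c")]
  writeLines(as.character(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA)),
             sidecar)
  invisible(path)
}
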