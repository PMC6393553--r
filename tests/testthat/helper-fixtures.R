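# Shared fixtures: parameter sets mirroring the tensiometry study conditions
# and small oracles used across test files.

nanosphere_exp_params <- function()
  kww_params(a = 5, tau1 = 19.5, beta = 0.55, b = 1, tau2 = 2000, c = 50)

fixture_params <- function(beta, tau1, a = 5)
  kww_params(a = a, tau1 = tau1, beta = beta, b = 1, tau2 = 2000, c = 50)

default_protocol <- function(...) deformation_protocol(...)

# O(N^2) minimum-image pair enumeration, independent of the C++ cell list
brute_force_pairs <- function(pos, box, cutoff) {
  n <- nrow(pos)
  out <- vector("list", n)
  for (i in seq_len(n - 1)) {
    d <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    hit <- which(rowSums(d^2) <= cutoff^2)
    if (length(hit)) out[[i]] <- cbind(i, i + hit)
  }
  m <- do.call(rbind, out)
  if (is.null(m)) matrix(integer(0), 0, 2) else m
}

pair_key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))

# central-difference force oracle against the engine's potential energy
fd_force_error <- function(sys, topo, ff, h = 1e-6) {
  f <- compute_forces(sys, ff, topo)
  num <- matrix(0, nrow(sys$positions), 3)
  for (i in seq_len(nrow(sys$positions))) {
    for (d in 1:3) {
      up <- sys; up$positions[i, d] <- up$positions[i, d] + h
      dn <- sys; dn$positions[i, d] <- dn$positions[i, d] - h
      num[i, d] <- -(compute_forces(up, ff, topo)$pe -
                     compute_forces(dn, ff, topo)$pe) / (2 * h)
    }
  }
  max(abs(num - f$forces))
}

make_topo <- function(...) {
  t <- topology()
  el <- list(...)
  for (n in names(el)) t[[n]] <- el[[n]]
  t
}

# minimal md_run-shaped object for profile analyses on constructed frames
fake_run <- function(frames, box, species) {
  structure(list(frames = frames, box = box, species = species,
                 samples = data.frame(step = vapply(frames, `[[`, numeric(1), "step")),
                 system = NULL),
            class = "md_run")
}
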