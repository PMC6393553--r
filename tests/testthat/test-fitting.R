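test_that("the post-step extremum is located per deformation direction", {
  p <- nanosphere_exp_params()
  proto <- default_protocol()
  tr <- generate_trace(trace_spec(p, noise_sd = 0), proto)
  i0 <- locate_step_extremum(tr)
  expect_identical(tr$t[i0], proto$equilibration_s + proto$step_duration_s)

  # seeded noisy trace, peak SNR >> 10: argmax over the window is the oracle
  trn <- generate_trace(trace_spec(p, noise_sd = 0.05, seed = 7), proto)
  win <- which(trn$t >= trn$step_time & trn$t <= trn$step_time + 3 * trn$step_duration)
  expect_identical(locate_step_extremum(trn), win[which.max(trn$gamma[win])])

  # mirrored compression trace has the symmetric minimum
  pc <- kww_params(a = -5, tau1 = 19.5, beta = 0.55, b = 1, tau2 = 2000, c = 50)
  trc <- generate_trace(trace_spec(pc, noise_sd = 0),
                        deformation_protocol(step_fraction = -0.10))
  ic <- locate_step_extremum(trc)
  expect_identical(trc$t[ic], proto$equilibration_s + proto$step_duration_s)

  # no samples after the step is an error
  short <- tr
  short$t <- tr$t[tr$t < 500]; short$gamma <- tr$gamma[tr$t < 500]
  expect_error(locate_step_extremum(short), "empty window")
})

test_that("noise-free traces are recovered to high relative accuracy", {
  p <- nanosphere_exp_params()
  tr <- generate_trace(trace_spec(p, noise_sd = 0), default_protocol())
  fit <- kwwfit(tr)
  expect_true(fit$converged)
  cf <- coef(fit)
  expect_equal(cf[["beta"]], 0.55, tolerance = 1e-3)
  expect_equal(cf[["tau1"]], 19.5, tolerance = 1e-3)
  expect_lt(fit$residual_rms, 1e-6)
  expect_equal(unname(cf[c("a", "b", "tau2", "c")]), c(5, 1, 2000, 50),
               tolerance = 1e-3)

  # degenerate single-exponential limit: beta pinned at its upper bound
  p1 <- kww_params(a = 5, tau1 = 20, beta = 1, b = 0, tau2 = 2000, c = 50)
  f1 <- kwwfit(generate_trace(trace_spec(p1, noise_sd = 0), default_protocol()))
  expect_equal(coef(f1)[["beta"]], 1, tolerance = 1e-6)
  expect_equal(coef(f1)[["tau1"]], 20, tolerance = 1e-3)
})

test_that("parameter recovery holds across the beta x tau1 grid", {
  for (beta in c(0.4, 0.55, 0.7, 0.85, 1.0)) {
    for (tau1 in c(10, 20, 30)) {
      p <- fixture_params(beta, tau1)
      tr <- generate_trace(trace_spec(p, noise_sd = 0), default_protocol())
      cf <- coef(kwwfit(tr, restarts = 8L))
      expect_equal(cf[["beta"]], beta, tolerance = 1e-3,
                   label = sprintf("beta (truth %.2f/%g)", beta, tau1))
      expect_equal(cf[["tau1"]], tau1, tolerance = 1e-3,
                   label = sprintf("tau1 (truth %.2f/%g)", beta, tau1))
    }
  }
})

test_that("fits are invariant under stress offset and time shift", {
  p <- nanosphere_exp_params()
  tr <- generate_trace(trace_spec(p, noise_sd = 0), default_protocol())
  base <- coef(kwwfit(tr))
  up <- tr; up$gamma <- tr$gamma + 7.3
  cfu <- coef(kwwfit(up))
  expect_equal(cfu[["beta"]], base[["beta"]], tolerance = 1e-6)
  expect_equal(cfu[["tau1"]], base[["tau1"]], tolerance = 1e-5)
  expect_equal(cfu[["c"]], base[["c"]] + 7.3, tolerance = 1e-5)

  sh <- relaxation_trace(tr$t + 500, tr$gamma, tr$step_time + 500,
                         tr$step_fraction, tr$step_duration, tr$phase_label)
  cfs <- coef(kwwfit(sh))
  expect_equal(cfs[["beta"]], base[["beta"]], tolerance = 1e-6)
  expect_equal(cfs[["tau1"]], base[["tau1"]], tolerance = 1e-5)
})

test_that("noisy fits report a residual RMS near the injected noise", {
  p <- nanosphere_exp_params()
  tr <- generate_trace(trace_spec(p, noise_sd = 0.05, seed = 3),
                       default_protocol())
  fit <- kwwfit(tr)
  expect_true(fit$converged)
  expect_equal(fit$residual_rms, 0.05, tolerance = 0.2)
  # uncertainties are finite and positive for all six parameters
  expect_true(all(is.finite(fit$se) & fit$se > 0))
})

test_that("fit window bookkeeping: truncation is flagged, short windows refuse", {
  p <- nanosphere_exp_params()
  proto <- deformation_protocol(hold_s = 400)
  tr <- generate_trace(trace_spec(p, noise_sd = 0), proto)
  expect_warning(fit <- kwwfit(tr, window = 1000), "truncat")
  expect_true(fit$truncated)
  expect_lte(diff(fit$window), 1000)
  short <- generate_trace(trace_spec(p, noise_sd = 0),
                          deformation_protocol(hold_s = 25))
  expect_warning(expect_error(kwwfit(short), "30 samples"))
})

test_that("asymmetry report quantifies compression/expansion differences", {
  # native pea-protein-like asymmetry: beta 0.42 in extension, 0.73 in compression
  pe <- fixture_params(0.42, 17.9)
  pc <- kww_params(a = -5, tau1 = 18.0, beta = 0.73, b = -1, tau2 = 2000, c = 50)
  fe <- kwwfit(generate_trace(trace_spec(pe, noise_sd = 0), default_protocol()))
  fc <- kwwfit(generate_trace(trace_spec(pc, noise_sd = 0),
                              deformation_protocol(step_fraction = -0.2)))
  rep1 <- asymmetry_report(fe, fc)
  expect_equal(rep1$delta_beta, 0.31, tolerance = 1e-3)
  expect_true(rep1$heterogeneous_expansion)
  expect_true(rep1$heterogeneous_compression)

  # identical fits: no asymmetry
  rep0 <- asymmetry_report(fe, fe)
  expect_identical(rep0$delta_beta, 0)
  expect_equal(rep0$tau1_ratio, 1)

  # nanoparticle pattern: stretched behavior disappears in compression
  pc1 <- kww_params(a = -5, tau1 = 62.9, beta = 1, b = -1, tau2 = 2000, c = 50)
  fc1 <- kwwfit(generate_trace(trace_spec(pc1, noise_sd = 0),
                               deformation_protocol(step_fraction = -0.1)))
  pe1 <- fixture_params(0.55, 19.5)
  fe1 <- kwwfit(generate_trace(trace_spec(pe1, noise_sd = 0), default_protocol()))
  rep2 <- asymmetry_report(fe1, fc1)
  expect_false(rep2$heterogeneous_compression)
  expect_true(rep2$heterogeneous_expansion)

  # unconverged input refuses, naming the failed side
  bad <- fe; bad$converged <- FALSE
  expect_error(asymmetry_report(bad, fc), "expansion")
  expect_error(asymmetry_report(fe, bad), "compression")
})

test_that("kwwfit model methods are coherent", {
  p <- nanosphere_exp_params()
  tr <- generate_trace(trace_spec(p, noise_sd = 0.03, seed = 9),
                       default_protocol())
  fit <- kwwfit(tr)
  expect_s3_class(fit, "kwwfit")
  expect_length(coef(fit), 6)
  expect_equal(fitted(fit) + residuals(fit), fit$gamma)
  expect_equal(predict(fit, 0), sum(coef(fit)[c("a", "b", "c")]),
               tolerance = 1e-10)
  s <- summary(fit)
  expect_true(s$heterogeneous)
  expect_equal(s$mean_relaxation_time,
               kww_mean_relaxation_time(coef(fit)[["tau1"]], coef(fit)[["beta"]]))
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "relaxation_trace")
  expect_identical(simulate(fit, seed = 4)[[1]]$gamma, sims[[1]]$gamma)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
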