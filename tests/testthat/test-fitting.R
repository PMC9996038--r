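# Nonlinear least-squares fitters: exactness on noiseless data, ordering
# invariances, misfit detection and model-order selection.

test_that("all fitters recover generating parameters exactly from noiseless data", {
  ctx <- thermo_context()
  none <- noise_spec(sd = 0)
  # Hill
  hp <- hill_params(2.5, 1, 15, 1.3)
  fh <- fit_hill(gen_dose_response(hp, noise = none, n = 2))
  expect_rel_equal(unlist(coef(fh)), unlist(unclass(hp)), 1e-6)
  # Boltzmann
  bp <- boltzmann_params(-15.4, 7.9)
  db <- gen_gv(bp, seq(-60, 40, 10), noise = none, n = 1)
  fb <- fit_boltzmann(db)
  expect_rel_equal(unlist(coef(fb)), c(-15.4, 7.9), 1e-6)
  # double Boltzmann (D540K control shape)
  dp <- calibrate_double_boltzmann(-118, 10.6, -24.7, 7.2, trough = 0.02)
  dd <- gen_gv(dp, seq(-140, 40, 10), noise = none, n = 1)
  fd <- fit_double_boltzmann(dd)
  expect_rel_equal(unlist(coef(fd))[c("v05_hyp_mV", "k_hyp_mV",
                                      "v05_dep_mV", "k_dep_mV")],
                   c(-118, 10.6, -24.7, 7.2), 1e-6)
  expect_equal(fd$extra$curve_min, 0.02, tolerance = 1e-4)
  # 6-state gating model
  gp <- split_control()
  dg <- gen_gv(gp, seq(-60, 60, 10), noise = none, n = 1, ctx = ctx)
  fg <- fit_gating_gv(dg, ctx)
  expect_rel_equal(unlist(coef(fg)), c(0.155, 1.71, 0.32, 0.73), 1e-6)
  # exponential decays, order 1-3
  mixes <- list(exp_mixture(67, 1),
                exp_mixture(c(44, 1451), c(0.6, 0.4)),
                exp_mixture(c(35, 442, 1970), c(0.4, 0.3, 0.3)))
  durs <- c(500, 8000, 12000)
  for (i in seq_along(mixes)) {
    seg <- gen_tail_trace(mixes[[i]], dt_ms = durs[i] / 2000,
                          duration_ms = durs[i], noise = none)
    fe <- fit_exp_decay(seg, order = mixes[[i]]$order)
    expect_rel_equal(coef(fe)$taus_ms, mixes[[i]]$taus_ms, 1e-6)
    expect_rel_equal(coef(fe)$amps, mixes[[i]]$amps, 1e-6)
  }
})

test_that("hill fit flags degenerate inputs instead of returning silent defaults", {
  flat <- data.frame(conc_uM = rep(c(1, 3, 10, 30), 3), response = 2)
  ff <- fit_hill(flat)
  expect_false(ff$converged)
  expect_true("unidentifiable_flat" %in% ff$flags)
  expect_error(fit_hill(data.frame(conc_uM = c(1, 3), response = c(1, 2))),
               "4 distinct")
})

test_that("hill fit recovers EC50 from noisy tau-deactivation dose-response data", {
  hp <- hill_params(Amax = 4, Amin = 1, ec50_uM = 7.9, nH = 1.9)
  d <- gen_dose_response(hp, noise = noise_spec(frac_span = 0.03, seed = 202),
                         n = 5)
  f <- fit_hill(d)
  expect_true(f$converged)
  expect_lt(abs(coef(f)$ec50_uM / 7.9 - 1), 0.1)
})

test_that("boltzmann fit errors on under-determined data and shows lack of fit to 6-state curves", {
  ctx <- thermo_context()
  expect_error(fit_boltzmann(data.frame(V_mV = c(-20, 0), g_norm = c(0.2, 0.8))),
               "under-determined")
  # a 6-state G-V is not exactly a Boltzmann: nested-model rss ordering
  dg <- gen_gv(split_control(), seq(-60, 60, 10), noise = noise_spec(sd = 0),
               n = 1, ctx = ctx)
  rss_b <- fit_boltzmann(dg)$rss
  rss_g <- fit_gating_gv(dg, ctx)$rss
  expect_gt(rss_b, rss_g)
  expect_gt(rss_b, 1e-6)  # systematic misfit, not numerical noise
  # and the flexible 6-state fit tracks plain Boltzmann data about as well
  dbz <- gen_gv(boltzmann_params(-10, 9), seq(-60, 60, 10),
                noise = noise_spec(sd = 0), n = 1)
  fgb <- fit_gating_gv(dbz, ctx)
  expect_true(fgb$converged)
  expect_lt(sqrt(fgb$rss / 13), 0.02)   # tracks a plain Boltzmann closely
})

test_that("fit results are invariant to row order of the dataset", {
  ctx <- thermo_context()
  d <- gen_gv(split_control(), seq(-60, 60, 10),
              noise = noise_spec(frac_span = 0.02, seed = 5), n = 3, ctx = ctx)
  shuf <- d[sample.int(nrow(d)), ]
  f1 <- fit_gating_gv(d, ctx)
  f2 <- fit_gating_gv(shuf, ctx)
  expect_equal(unlist(coef(f1)), unlist(coef(f2)), tolerance = 1e-6)
  b1 <- fit_boltzmann(d)
  b2 <- fit_boltzmann(shuf)
  expect_equal(unlist(coef(b1)), unlist(coef(b2)), tolerance = 1e-6)
})

test_that("double boltzmann degrades gracefully to a single branch", {
  p <- double_boltzmann_params(-200, 10, 0, -24.7, 7.2, 1, 0)
  d <- gen_gv(p, seq(-140, 40, 10), noise = noise_spec(sd = 0), n = 1)
  f <- fit_double_boltzmann(d)
  expect_equal(coef(f)$v05_dep_mV, -24.7, tolerance = 0.1)
  expect_lt(coef(f)$A_hyp, 0.05)
  expect_error(
    fit_double_boltzmann(data.frame(V_mV = seq(-40, 0, 10),
                                    g_norm = runif(5))),
    "6 distinct")
})

test_that("recovered relative slow amplitude matches the generating fraction", {
  m <- exp_mixture(c(44, 1451), c(0.6, 0.4))
  seg <- suppressWarnings(
    gen_tail_trace(m, dt_ms = 2, duration_ms = 6000,
                   noise = noise_spec(frac_span = 0.02, seed = 303)))
  f <- fit_exp_decay(seg, order = 2)
  rel_slow <- coef(f)$amps[2] / sum(abs(coef(f)$amps))
  expect_equal(rel_slow, 0.4, tolerance = 0.05)
})

test_that("overfitting mono data with order 2 is flagged as degenerate", {
  seg <- gen_tail_trace(exp_mixture(67, 1), dt_ms = 1, duration_ms = 500,
                        noise = noise_spec(frac_span = 0.02, seed = 11))
  f2 <- fit_exp_decay(seg, order = 2)
  expect_true("tau_collapse" %in% f2$flags ||
                f2$rss >= 0.99 * fit_exp_decay(seg, order = 1)$rss)
  expect_error(fit_exp_decay(seg$time_ms[1:15], seg$current_uA[1:15],
                             order = 2), "10 samples")
})

test_that("recovery error shrinks with noise level and replicate count", {
  ctx <- thermo_context()
  hp <- hill_params(2.5, 1, 10, 1.5)
  err_of <- function(frac, n, nseeds = 8) {
    mean(vapply(seq_len(nseeds), function(s) {
      d <- gen_dose_response(hp, concs_uM = c(0.5, 1, 3, 5, 10, 20, 40, 80),
                             noise = noise_spec(frac_span = frac, seed = 1000 + s),
                             n = n)
      abs(coef(fit_hill(d))$ec50_uM / 10 - 1)
    }, numeric(1)))
  }
  expect_lt(err_of(0.01, 5), err_of(0.08, 5))
  expect_lt(err_of(0.05, 12), err_of(0.05, 1))
})

test_that("F-test order selection finds the generating order and rejects overfits", {
  # canonical single cases (the >= 90% rate over 100 seeds is an
  # acceptance-level property tested separately)
  mono <- gen_tail_trace(exp_mixture(67, 1), dt_ms = 1, duration_ms = 500,
                         noise = noise_spec(sd = 0.05, seed = 1))
  expect_identical(select_exp_order(mono)$order, 1L)
  bi <- suppressWarnings(
    gen_tail_trace(exp_mixture(c(44, 1451), c(0.6, 0.4)), dt_ms = 2,
                   duration_ms = 6000, noise = noise_spec(sd = 0.05, seed = 2)))
  expect_identical(select_exp_order(bi)$order, 2L)
  tri <- gen_tail_trace(exp_mixture(c(35, 442, 1970), c(0.4, 0.3, 0.3)),
                        dt_ms = 4, duration_ms = 10000,
                        noise = noise_spec(sd = 0.02, seed = 3))
  sel <- select_exp_order(tri)
  expect_identical(sel$order, 3L)
  expect_true(all(diff(vapply(sel$fits, function(f) f$rss, numeric(1))) <= 0))
})

test_that("fit results serialize to JSON with parameters and diagnostics", {
  f <- fit_hill(gen_dose_response(hill_params(2, 1, 8, 1.2),
                                  noise = noise_spec(sd = 0), n = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(obj$model_tag, "hill")
  expect_equal(obj$params$ec50_uM, 8, tolerance = 1e-6)
  expect_true(obj$converged)
  expect_identical(obj$n_points, f$n_points)
})
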