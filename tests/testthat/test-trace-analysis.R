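# Trace measurement operators: peaks, tails, ratio statistic, G-V assembly
# and deactivation curves.

make_step_trace <- function(values, dt = 1, volts = c(40, -60)) {
  # two-epoch trace with given current samples split evenly across epochs
  n <- length(values)
  n1 <- n %/% 2
  prot <- voltage_protocol(list(c(n1 * dt, volts[1]), c((n - n1) * dt, volts[2])),
                           sample_interval_ms = dt, holding_mV = -70,
                           holding_ms = 0)
  current_trace(seq(0, by = dt, length.out = n),
                rep(volts, c(n1, n - n1)), values,
                metadata = list(protocol = prot))
}

test_that("peak extraction respects epoch windows, blanking and sign convention", {
  tr <- make_step_trace(c(seq(0, 1, length.out = 10), seq(1, 0, length.out = 10)))
  expect_equal(measure_peak_current(tr, 1), 1)          # monotone rise: last sample
  expect_equal(measure_peak_current(tr, 2), 1)
  expect_equal(measure_peak_current(tr, 2, blank_ms = 5), 4 / 9, tolerance = 1e-9)
  expect_error(measure_peak_current(tr, 2, blank_ms = 50), "whole epoch")
  expect_error(measure_peak_current(tr, 7), "not present")
  # inward peaks
  tr2 <- make_step_trace(-c(seq(0, 1, length.out = 10), seq(1, 0, length.out = 10)))
  expect_equal(measure_peak_current(tr2, 1, direction = "inward"), -1)
  expect_equal(measure_peak_current(tr2, 1, direction = "absolute"), -1)
})

test_that("tail peak location anchors the decay and flat traces yield zero", {
  t <- seq(0, 199, by = 1)
  tail_part <- exp(-(0:99) / 30)
  tr <- make_step_trace(c(rep(1, 100), tail_part), dt = 1)
  pk <- measure_tail_peak(tr, 2, blank_ms = 0)
  expect_equal(pk$I_tail_peak_uA, 1)
  expect_equal(pk$t_peak_ms, 100)
  flat <- make_step_trace(rep(0, 200))
  expect_equal(measure_tail_peak(flat, 2, blank_ms = 0)$I_tail_peak_uA, 0)
})

test_that("tail ratio is analytic for mono-exponential tails", {
  tau <- 30
  tr <- make_step_trace(c(rep(1, 100), exp(-(0:99) / tau)), dt = 1)
  expect_equal(tail_ratio(tr, 2, t_end_ms = tau, blank_ms = 0), exp(-1),
               tolerance = 1e-9)
  expect_equal(tail_ratio(tr, 2, t_end_ms = 0, blank_ms = 0), 1)
  expect_error(tail_ratio(tr, 2, t_end_ms = 500, blank_ms = 0), "beyond")
  flat <- make_step_trace(rep(0, 200))
  expect_warning(rat <- tail_ratio(flat, 2, t_end_ms = 10, blank_ms = 0), "undefined")
  expect_true(is.na(rat))
  # ratios of noiseless monotone tails stay in [0, 1]
  fam <- gen_tail_family(data.frame(V_mV = c(-140, -40), tau_ms = c(3.4, 67)),
                         seq(-140, -40, 20), return_ms = 300)
  rc <- ratio_curve(fam, t_end_ms = 25)
  expect_true(all(rc$ratio >= 0 & rc$ratio <= 1))
})

test_that("ratio-curve midpoints recover construction and shift differences", {
  # ratios generated directly from a Boltzmann in V_ret
  bp <- boltzmann_params(-90, 12)
  v <- seq(-140, -40, 10)
  rc1 <- data.frame(V_ret_mV = v, ratio = boltzmann_gv(v, bp))
  expect_equal(ratio_curve_midpoint(rc1)$midpoint_mV, -90, tolerance = 1e-6)
  # a curve shifted by -60 mV reports a -60 mV midpoint difference
  rc2 <- data.frame(V_ret_mV = v,
                    ratio = boltzmann_gv(v, boltzmann_params(-30, 12)))
  d <- ratio_curve_midpoint(rc1)$midpoint_mV - ratio_curve_midpoint(rc2)$midpoint_mV
  expect_equal(d, -60, tolerance = 1e-6)
  flat <- data.frame(V_ret_mV = v, ratio = rep(0.5, length(v)))
  expect_error(ratio_curve_midpoint(flat), "flat")
})

test_that("G-V assembly from tails honors both normalization modes", {
  ctx <- thermo_context()
  r <- rate_params(split_control())
  tmpl <- voltage_protocol(list(c(1500, 0), c(300, -50)),
                           sample_interval_ms = 1, holding_mV = -90,
                           holding_ms = 20)
  fam <- gen_protocol_family(r, tmpl, 1, seq(-60, 60, 10), sim_config(), ctx,
                             "control")
  gv <- build_gv_from_tails(fam, blank_ms = 0)
  expect_equal(max(gv$g_norm), 1)
  # control-max mode with a scaled (potentiated) condition exceeds 1
  fam_rpr <- fam
  for (i in seq_along(fam_rpr$traces))
    fam_rpr$traces[[i]]$current_uA <- 2.5 * fam_rpr$traces[[i]]$current_uA
  gv_rpr <- build_gv_from_tails(fam_rpr, normalization = "control_max",
                                reference_max_uA = attr(gv, "tail_max_uA"),
                                blank_ms = 0)
  expect_gt(max(gv_rpr$g_norm), 1.5)
  zero_fam <- fam
  for (i in seq_along(zero_fam$traces))
    zero_fam$traces[[i]]$current_uA <- 0 * zero_fam$traces[[i]]$current_uA
  expect_error(build_gv_from_tails(zero_fam, blank_ms = 0), "zero")
})

test_that("simulate -> G-V -> 6-state fit round trip recovers the simulator parameters", {
  ctx <- thermo_context()
  p <- split_control()
  r <- rate_params(p)
  tmpl <- voltage_protocol(list(c(1500, 0), c(300, -50)),
                           sample_interval_ms = 1, holding_mV = -90,
                           holding_ms = 20)
  fam <- gen_protocol_family(r, tmpl, 1, seq(-60, 60, 10), sim_config(), ctx,
                             "control")
  gv <- build_gv_from_tails(fam, blank_ms = 0)
  fg <- fit_gating_gv(gv, ctx)
  expect_rel_equal(unlist(coef(fg)), c(0.155, 1.71, 0.32, 0.73), 1e-3)
})

test_that("deactivation tau curves recover the generating voltage dependence", {
  anchors <- data.frame(V_mV = c(-140, -40), tau_ms = c(3.4, 67))
  fam <- gen_tail_family(anchors, seq(-140, -40, 10), dt_ms = 0.5,
                         return_ms = 350,
                         noise = noise_spec(frac_span = 0.01, seed = 9))
  tab <- deactivation_tau_curve(fam, order = 1)
  expect_equal(tab$tau_ms[tab$V_ret_mV == -40], 67, tolerance = 0.05 * 67)
  expect_equal(tab$tau_ms[tab$V_ret_mV == -140], 3.4, tolerance = 0.05 * 3.4)
  # log-linear interpolation holds in between
  mid <- tab$tau_ms[tab$V_ret_mV == -90]
  expect_equal(log(mid), mean(log(c(3.4, 67))), tolerance = 0.05)
  # forcing order 1 on biexponential data degrades the fit badly
  m_bi <- exp_mixture(c(44, 1451), c(0.6, 0.4))
  fam_bi <- gen_tail_family(list(`-60` = m_bi), -60, dt_ms = 2,
                            return_ms = 6000,
                            noise = noise_spec(frac_span = 0.005, seed = 4))
  t1 <- deactivation_tau_curve(fam_bi, order = 1)
  t2 <- deactivation_tau_curve(fam_bi, order = 2)
  expect_gt(t1$rss[1], 10 * t2$rss[1])
  # automatic selection picks the biexponential
  ta <- deactivation_tau_curve(fam_bi, order = "auto")
  expect_equal(unique(ta$order), 2)
})
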