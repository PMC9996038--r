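# Closed-form model functions: reduced potential, 6-state equilibrium,
# Boltzmann / double-Boltzmann / Hill curves, exponential mixtures.

test_that("reduced potential has the right scale, sign and error behavior", {
  ctx <- thermo_context(295.15)
  expect_identical(reduced_potential(0, ctx), 0)
  # 96485 * 0.02542 / (8.314 * 295.15) = 0.99950 (hand check)
  expect_equal(reduced_potential(25.42, ctx), 0.99950, tolerance = 1e-4)
  expect_equal(reduced_potential(-25.42, ctx), -reduced_potential(25.42, ctx))
  expect_error(reduced_potential(NA_real_, ctx), "finite")
  expect_error(thermo_context(-1), "> 0")
})

test_that("equilibrium constants follow K0 exp(-z FV/RT)", {
  ctx <- thermo_context(295.15)
  p <- split_control()
  at0 <- equilibrium_constants(p, 0, ctx)
  expect_equal(at0$K, 0.155)
  expect_equal(at0$Ko, 0.32)
  # independent evaluation at -100 mV, T = 295.15 K
  u <- -0.1 * 96485 / (8.314 * 295.15)
  at100 <- equilibrium_constants(p, -100, ctx)
  expect_equal(at100$K, 0.155 * exp(-1.71 * u), tolerance = 1e-12)
  expect_equal(at100$Ko, 0.32 * exp(-0.73 * u), tolerance = 1e-12)
  # both decrease with depolarization for positive charges
  Ks <- equilibrium_constants(p, seq(-100, 100, 20), ctx)
  expect_true(all(diff(Ks$K) < 0) && all(diff(Ks$Ko) < 0))
})

test_that("state occupancies are a normalized binomial ladder", {
  ctx <- thermo_context()
  p <- split_control()
  for (V in seq(-200, 200, 25)) {
    occ <- state_occupancies(p, V, ctx)
    expect_true(all(occ >= 0 & occ <= 1))
    expect_lt(abs(sum(occ) - 1), 1e-9)
  }
  # binomial structure at 0 mV: C_j / O = Ko * choose(4, 4-j) * K^(4-j)
  occ0 <- state_occupancies(p, 0, ctx)
  w <- 0.32 * choose(4, 4:0) * 0.155^(4:0)
  expect_equal(as.numeric(occ0[1:5] / occ0["O"]), w, tolerance = 1e-10)
  # saturation limits
  expect_equal(as.numeric(state_occupancies(p, 2000, ctx)["O"]), 1,
               tolerance = 1e-10)
  expect_equal(as.numeric(state_occupancies(p, -2000, ctx)["C0"]), 1,
               tolerance = 1e-10)
})

test_that("open probability matches the independent closed-form oracle", {
  ctx <- thermo_context()
  p <- split_control()
  # hand-derived: 1 / (1 + 0.32 * 1.155^4) = 0.6372 at 0 mV
  expect_equal(po_equilibrium(p, 0, ctx), 0.6372, tolerance = 1e-3)
  V <- seq(-140, 60, 10)
  expect_equal(po_equilibrium(p, V, ctx),
               po_oracle(0.155, 1.71, 0.32, 0.73, V), tolerance = 1e-12)
  pr <- split_rpr()
  expect_equal(po_equilibrium(pr, V, ctx),
               po_oracle(0.023, 2.98, 0.513, 0.81, V), tolerance = 1e-12)
})

test_that("po_equilibrium equals the O occupancy and is monotone with limits", {
  ctx <- thermo_context()
  for (p in list(split_control(), split_rpr(),
                 gating_params(1, 0.5, 2, 2))) {
    V <- seq(-140, 60, 5)
    po <- po_equilibrium(p, V, ctx)
    occO <- vapply(V, function(v) state_occupancies(p, v, ctx)[["O"]],
                   numeric(1))
    expect_lt(max(abs(po - occO)), 1e-12)
    expect_true(all(diff(po) >= 0))
  }
  expect_equal(po_equilibrium(split_control(), 1000), 1, tolerance = 1e-9)
  expect_equal(po_equilibrium(split_control(), -1000), 0, tolerance = 1e-9)
})

test_that("Boltzmann curve midpoint, slope convention and saturation", {
  p <- boltzmann_params(-20, 7.4)
  expect_identical(boltzmann_gv(-20, p), 0.5)
  expect_equal(boltzmann_gv(-20 + 7.4, p), 1 / (1 + exp(-1)))
  expect_equal(boltzmann_gv(1e4, p), 1)
  expect_error(boltzmann_params(-20, 0), "> 0")
})

test_that("double Boltzmann reduces to single branches and is biphasic", {
  # depolarized branch only
  p1 <- double_boltzmann_params(-200, 10, 0, -24.7, 7.2, 1, 0)
  bp <- boltzmann_params(-24.7, 7.2)
  V <- seq(-60, 40, 5)
  expect_equal(double_boltzmann_gv(V, p1), boltzmann_gv(V, bp),
               tolerance = 1e-9)
  # symmetric overlap: both midpoints at -70, amplitudes 0.5 -> 0.5 at -70
  p2 <- double_boltzmann_params(-70, 10, 0.5, -70, 10, 0.5, 0)
  expect_equal(double_boltzmann_gv(-70, p2), 0.5)
  # D540K control shape: larger at -140 than at the -70 trough
  cal <- calibrate_double_boltzmann(-118, 10.6, -24.7, 7.2, trough = 0.02)
  expect_gt(double_boltzmann_gv(-140, cal), double_boltzmann_gv(-70, cal))
  curve <- double_boltzmann_gv(seq(-140, 40, 1), cal)
  expect_equal(min(curve), 0.02, tolerance = 1e-9)
  expect_equal(max(curve), 1, tolerance = 1e-9)
})

test_that("Hill curve runs from Amin at zero dose to Amax at saturation", {
  p <- hill_params(Amax = 2.5, Amin = 1, ec50_uM = 15, nH = 1.3)
  expect_identical(hill_response(0, p), 1)
  expect_equal(hill_response(15, p), (2.5 + 1) / 2)
  expect_equal(hill_response(1e9, p), 2.5, tolerance = 1e-6)
  expect_error(hill_response(-1, p), ">= 0")
  # inhibition direction also works (Amax < Amin)
  pi <- hill_params(Amax = 0.2, Amin = 1, ec50_uM = 5, nH = 1)
  expect_true(all(diff(hill_response(c(0, 1, 5, 20, 100), pi)) < 0))
})

test_that("exponential mixtures evaluate correctly and canonicalize", {
  m <- exp_mixture(67, 1)
  expect_equal(exp_mixture_value(0, m), 1)
  expect_equal(exp_mixture_value(67, m), exp(-1))
  expect_equal(exp_mixture_value(1e6, m), 0)
  # permutation invariance via canonical ascending-tau form
  m1 <- exp_mixture(c(44, 1451), c(0.6, 0.4), offset = 0.1)
  m2 <- exp_mixture(c(1451, 44), c(0.4, 0.6), offset = 0.1)
  t <- c(0, 10, 100, 1000)
  expect_identical(exp_mixture_value(t, m1), exp_mixture_value(t, m2))
  expect_equal(m2$taus_ms, c(44, 1451))
  expect_equal(exp_mixture_value(0, m1), 1.1)
  expect_error(exp_mixture(c(10, 10), c(1, 1)), "distinct")
  expect_error(exp_mixture(c(-5), 1), "> 0")
})
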