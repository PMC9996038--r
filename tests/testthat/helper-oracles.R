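# Shared fixtures and independent oracles for the test suite.

# split hERG1a gating parameter sets (control / 30 µM RPR)
split_control <- function() gating_params(K0 = 0.155, z1 = 1.71,
                                          Ko0 = 0.32, z2 = 0.73)
split_rpr <- function() gating_params(K0 = 0.023, z1 = 2.98,
                                      Ko0 = 0.513, z2 = 0.81)

# independent closed-form oracle: plain-arithmetic evaluation of the printed
# denominator 1 + Ko + 4KoK + 6KoK^2 + 4KoK^3 + KoK^4 (no reuse of package
# internals beyond the physical constants)
po_oracle <- function(K0, z1, Ko0, z2, V_mV, T_K = 295.15) {
  u <- (V_mV / 1000) * 96485 / (8.314 * T_K)
  K <- K0 * exp(-z1 * u)
  Ko <- Ko0 * exp(-z2 * u)
  1 / (1 + Ko + 4 * Ko * K + 6 * Ko * K^2 + 4 * Ko * K^3 + Ko * K^4)
}

# fine-step integration oracle for the master equation ds/dt = s Q
ode_propagate_oracle <- function(Q, s0, dt_ms) {
  f <- function(t, y, parms) list(as.numeric(y %*% Q))
  out <- deSolve::ode(s0, c(0, dt_ms), f, NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-12)
  as.numeric(out[2, -1])
}

# slowest relaxation time constant of a generator (eigenvalue oracle)
slowest_tau_oracle <- function(Q) {
  ev <- Re(eigen(Q, only.values = TRUE)$values)
  -1 / sort(ev[ev < -1e-12], decreasing = TRUE)[1]
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual / expected - 1)), rel_tol)
}
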