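# Six-state sequential gating model:
#
#   C0 <-> C1 <-> C2 <-> C3 <-> C4 <-> O
#
# Four identical, independent voltage-sensor transitions (per-subunit
# equilibrium constant K, expressed in the closing direction) followed by a
# concerted closed-open transition (constant Ko, also closing direction).
# Because the four sensors are independent and identical, the closed-state
# occupancies relative to the open state are binomially weighted:
#
#   (O, C4, C3, C2, C1, C0) propto (1, Ko, 4*Ko*K, 6*Ko*K^2, 4*Ko*K^3, Ko*K^4)
#
# i.e. the state with m resting sensors carries weight Ko * choose(4, m) * K^m.
# Summing the closed weights gives Ko*(1+K)^4, so the open probability is
#
#   Po(V) = [1 + Ko + 4*Ko*K + 6*Ko*K^2 + 4*Ko*K^3 + Ko*K^4]^(-1)
#         = [1 + Ko*(1+K)^4]^(-1)
#
# with K = K(0) exp(-z1*F*V/RT) and Ko = Ko(0) exp(-z2*F*V/RT). Positive
# effective charges z1, z2 with the minus sign make both constants fall with
# depolarization, so channels open at positive voltages. The successive
# pairwise equilibrium constants implied by the binomial weights are K/4,
# 2K/3, 3K/2 and 4K going from C1/C0 down the chain, the unique assignment
# consistent with the closed-form denominator above.

STATE_NAMES <- c("C0", "C1", "C2", "C3", "C4", "O")

#' Gating-model parameters
#'
#' Zero-voltage equilibrium constants and effective charges of the 6-state
#' sequential gating model. `K0` and `Ko0` are the per-subunit and concerted
#' equilibrium constants at 0 mV, expressed in the closing direction
#' (resting/activated sensor and closed/open pore respectively); `z1` and
#' `z2` are the corresponding effective gating charges in elementary charges.
#'
#' @param K0,Ko0 Dimensionless zero-voltage equilibrium constants (>= 0).
#' @param z1,z2 Effective charges (>= 0).
#' @return An object of class `gating_params`.
#' @examples
#' # split hERG1a channel, control conditions
#' gating_params(K0 = 0.155, z1 = 1.71, Ko0 = 0.32, z2 = 0.73)
#' @export
gating_params <- function(K0, z1, Ko0, z2) {
  for (nm in c("K0", "z1", "Ko0", "z2")) check_number(get(nm), nm)
  stop_if(K0 < 0 || z1 < 0 || Ko0 < 0 || z2 < 0,
          "gating parameters must be non-negative")
  structure(list(K0 = K0, z1 = z1, Ko0 = Ko0, z2 = z2),
            class = "gating_params")
}

#' @export
print.gating_params <- function(x, ...) {
  cat(sprintf("<gating_params> K(0) = %.4g (z1 = %.3g), Ko(0) = %.4g (z2 = %.3g)\n",
              x$K0, x$z1, x$Ko0, x$z2))
  invisible(x)
}

#' Voltage-dependent equilibrium constants
#'
#' Evaluates \eqn{K(V) = K(0) e^{-z_1 FV/RT}} and
#' \eqn{K_o(V) = K_o(0) e^{-z_2 FV/RT}} of the 6-state model.
#'
#' @param p A [gating_params()].
#' @param V_mV Voltage(s) in millivolts.
#' @param ctx A [thermo_context()].
#' @return A list with numeric vectors `K` and `Ko`.
#' @export
equilibrium_constants <- function(p, V_mV, ctx = thermo_context()) {
  stopifnot(inherits(p, "gating_params"))
  u <- reduced_potential(V_mV, ctx)
  list(K = p$K0 * exp(-p$z1 * u), Ko = p$Ko0 * exp(-p$z2 * u))
}

# log K and log Ko, safe for K0 = 0 (returns -Inf)
log_equilibrium_constants <- function(p, V_mV, ctx) {
  u <- reduced_potential(V_mV, ctx)
  list(logK = log(p$K0) - p$z1 * u, logKo = log(p$Ko0) - p$z2 * u)
}

#' Equilibrium state occupancies of the 6-state model
#'
#' Occupancies of (C0, C1, C2, C3, C4, O) at equilibrium for one voltage.
#' Computed on the log scale (log-sum-exp normalization) so that extreme
#' voltages saturate to the limiting distribution instead of overflowing.
#'
#' @inheritParams equilibrium_constants
#' @param V_mV A single voltage in millivolts.
#' @return Named numeric vector of six probabilities summing to 1.
#' @examples
#' p <- gating_params(0.155, 1.71, 0.32, 0.73)
#' state_occupancies(p, 0)["O"] # ~ 0.637
#' @export
state_occupancies <- function(p, V_mV, ctx = thermo_context()) {
  stopifnot(inherits(p, "gating_params"))
  check_number(V_mV, "V_mV")
  lk <- log_equilibrium_constants(p, V_mV, ctx)
  # state C_j has m = 4 - j resting sensors; O has weight 1 (log 0)
  m <- 4:0
  logw_closed <- lk$logKo + lchoose(4, m) + ifelse(m == 0, 0, m * lk$logK)
  logw <- c(logw_closed, 0)
  occ <- exp(logw - logsumexp(logw))
  occ <- occ / sum(occ)
  names(occ) <- STATE_NAMES
  occ
}

#' Equilibrium open probability of the 6-state model
#'
#' Closed-form normalized conductance
#' \eqn{g/g_{max} = [1 + K_o + 4K_oK + 6K_oK^2 + 4K_oK^3 + K_oK^4]^{-1}},
#' evaluated via the equivalent factorized form \eqn{[1 + K_o(1+K)^4]^{-1}}
#' on the log scale. This is an independent code path from
#' [state_occupancies()]; the two agree to machine precision.
#'
#' @inheritParams equilibrium_constants
#' @return Open probability, same length as `V_mV`, in (0, 1).
#' @examples
#' p <- gating_params(0.155, 1.71, 0.32, 0.73)
#' po_equilibrium(p, seq(-60, 60, 10))
#' @export
po_equilibrium <- function(p, V_mV, ctx = thermo_context()) {
  stopifnot(inherits(p, "gating_params"))
  lk <- log_equilibrium_constants(p, V_mV, ctx)
  # log closed weight = log Ko + 4*log(1+K), via log1p(exp(logK))
  log_closed <- lk$logKo + 4 * vapply(lk$logK, function(x) {
    if (x == -Inf) 0 else if (x > 30) x else log1p(exp(x))
  }, numeric(1))
  ifelse(log_closed == -Inf, 1,
         1 / (1 + exp(pmin(log_closed, 700))))
}
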