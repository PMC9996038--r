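# Kinetic (Q-matrix) lift of the equilibrium 6-state model.
#
# The equilibrium model constrains only the ratios beta/alpha = K(V) (per
# subunit) and closing/opening = Ko(V) (concerted step). Any rate
# assignment respecting those ratios reproduces the same steady-state G-V;
# here the voltage dependence of each equilibrium charge is split between
# the forward and backward rate by `charge_split` (s):
#
#   alpha(V) = a_c * exp(+s*z1*FV/RT)         sensor activation
#   beta(V)  = alpha(V) * K(V) = a_c*K0 * exp(-(1-s)*z1*FV/RT)
#   gamma(V) = a_o * exp(+s*z2*FV/RT)         concerted opening
#   delta(V) = gamma(V) * Ko(V)
#
# Between C_j and C_{j+1} (j activated sensors) the rates carry the usual
# combinatorial multiplicities (4-j)*alpha forward and (j+1)*beta backward,
# so the chain is a birth-death process whose stationary distribution is
# exactly the binomial equilibrium of the closed-form model.

#' Kinetic rate parameters
#'
#' Lifts a [gating_params()] equilibrium description to transition rates.
#' `base_rate_closed` and `base_rate_open` set the per-subunit activation
#' and concerted opening rates at 0 mV; `charge_split` apportions each
#' effective charge between the forward and backward rate. Changing the base
#' rates or the split changes kinetics but never the steady-state G-V.
#'
#' @param gating A [gating_params()].
#' @param base_rate_closed Per-subunit activation rate at 0 mV, 1/ms (> 0).
#' @param base_rate_open Concerted opening rate at 0 mV, 1/ms (> 0).
#' @param charge_split Fraction of each charge on the forward rate, in
#'   \[0, 1\].
#' @return Object of class `rate_params`.
#' @export
rate_params <- function(gating, base_rate_closed = 1, base_rate_open = 0.5,
                        charge_split = 0.5) {
  stopifnot(inherits(gating, "gating_params"))
  check_number(base_rate_closed, "base_rate_closed")
  check_number(base_rate_open, "base_rate_open")
  check_number(charge_split, "charge_split")
  stop_if(base_rate_closed <= 0 || base_rate_open <= 0, "base rates must be > 0")
  stop_if(charge_split < 0 || charge_split > 1, "charge_split must be in [0, 1]")
  structure(list(gating = gating, base_rate_closed = base_rate_closed,
                 base_rate_open = base_rate_open, charge_split = charge_split),
            class = "rate_params")
}

#' Transition-rate generator of the 6-state chain
#'
#' Builds the 6x6 generator (Q-matrix) over states (C0..C4, O) at one
#' voltage. Rows sum to zero; off-diagonal entries are non-negative; the
#' stationary distribution equals [state_occupancies()] of the underlying
#' equilibrium model.
#'
#' @param r A [rate_params()].
#' @param V_mV Voltage, mV.
#' @param ctx A [thermo_context()].
#' @return 6x6 numeric matrix with dimnames (C0..C4, O).
#' @export
build_rate_matrix <- function(r, V_mV, ctx = thermo_context()) {
  stopifnot(inherits(r, "rate_params"))
  check_number(V_mV, "V_mV")
  g <- r$gating
  u <- reduced_potential(V_mV, ctx)
  s <- r$charge_split
  alpha <- r$base_rate_closed * exp(s * g$z1 * u)
  beta  <- r$base_rate_closed * g$K0 * exp(-(1 - s) * g$z1 * u)
  gamma <- r$base_rate_open * exp(s * g$z2 * u)
  delta <- r$base_rate_open * g$Ko0 * exp(-(1 - s) * g$z2 * u)
  rates <- c(alpha, beta, gamma, delta)
  stop_if(any(!is.finite(rates)) || max(rates) > 1e12,
          paste("transition rates overflow at V = %g mV;",
                "clip the protocol voltage range"), V_mV)
  Q <- matrix(0, 6, 6, dimnames = list(STATE_NAMES, STATE_NAMES))
  for (j in 0:3) {                      # C_j -> C_{j+1}, j activated sensors
    Q[j + 1, j + 2] <- (4 - j) * alpha
    Q[j + 2, j + 1] <- (j + 1) * beta
  }
  Q[5, 6] <- gamma                      # C4 -> O
  Q[6, 5] <- delta                      # O  -> C4
  diag(Q) <- -rowSums(Q)
  Q
}

# stationary distribution of a birth-death generator via the detailed-balance
# product form (independent of matrix algebra; used as the simulator's
# initial condition)
stationary_distribution <- function(Q) {
  n <- nrow(Q)
  logw <- numeric(n)
  for (i in 2:n) logw[i] <- logw[i - 1] + log(Q[i - 1, i]) - log(Q[i, i - 1])
  w <- exp(logw - logsumexp(logw))
  w / sum(w)
}

#' Propagate state occupancies over a constant-voltage interval
#'
#' Advances an occupancy vector by `dt_ms` under a fixed generator using the
#' matrix exponential, which is exact for a time-homogeneous chain.
#'
#' @param Q 6x6 generator from [build_rate_matrix()].
#' @param s Occupancy vector (probabilities summing to 1).
#' @param dt_ms Time step, ms (> 0).
#' @return Propagated occupancy vector.
#' @export
propagate <- function(Q, s, dt_ms) {
  check_number(dt_ms, "dt_ms")
  stop_if(dt_ms <= 0, "dt_ms must be > 0")
  stop_if(length(s) != nrow(Q), "state vector does not match generator")
  P <- as.matrix(Matrix::expm(Q * dt_ms))
  as.numeric(s %*% P)
}

#' Simulate a voltage-clamp protocol
#'
#' Mean-field simulation of the 6-state chain under a step protocol. The
#' initial state is the stationary distribution at the holding potential;
#' within each constant-voltage epoch the occupancies are advanced by one
#' matrix-exponential transition step per sample. The macroscopic current is
#' `n_channels * unitary_conductance * P_O(t) * (V(t) - E_rev)` (in µA)
#' plus additive Gaussian noise (seeded, reproducible).
#'
#' @param r A [rate_params()].
#' @param prot A [voltage_protocol()].
#' @param cfg A [sim_config()].
#' @param ctx A [thermo_context()].
#' @param condition Condition label stored in the trace metadata.
#' @return A [current_trace()]; the full state trajectory is attached as
#'   `metadata$states` (samples x 6 matrix).
#' @examples
#' r <- rate_params(gating_params(0.155, 1.71, 0.32, 0.73))
#' prot <- voltage_protocol(list(c(500, 50), c(200, -100)),
#'                          sample_interval_ms = 2, holding_mV = -70,
#'                          holding_ms = 10)
#' tr <- simulate_protocol(r, prot, sim_config())
#' @export
simulate_protocol <- function(r, prot, cfg = sim_config(),
                              ctx = thermo_context(), condition = "sim") {
  stopifnot(inherits(r, "rate_params"), inherits(prot, "voltage_protocol"),
            inherits(cfg, "sim_config"))
  dt <- prot$sample_interval_ms
  ep <- protocol_epoch_table(prot)
  stop_if(nrow(ep) == 0L, "empty protocol")

  s <- state_occupancies(r$gating, prot$holding_mV, ctx)
  times <- list(); volts <- list(); states <- list()
  t0 <- 0
  for (i in seq_len(nrow(ep))) {
    nsteps <- max(1L, round((ep$end_ms[i] - ep$start_ms[i]) / dt))
    Q <- build_rate_matrix(r, ep$voltage_mV[i], ctx)
    P <- as.matrix(Matrix::expm(Q * dt))
    S <- matrix(NA_real_, nsteps, 6)
    for (k in seq_len(nsteps)) {
      S[k, ] <- s        # sample at start of each step within the epoch
      s <- as.numeric(s %*% P)
    }
    states[[i]] <- S
    times[[i]] <- t0 + (seq_len(nsteps) - 1L) * dt
    volts[[i]] <- rep(ep$voltage_mV[i], nsteps)
    t0 <- t0 + nsteps * dt
  }
  time_ms <- unlist(times)
  voltage_mV <- unlist(volts)
  S <- do.call(rbind, states)
  colnames(S) <- STATE_NAMES
  po <- S[, "O"]
  current <- cfg$n_channels * cfg$unitary_conductance_nS * po *
    (voltage_mV - cfg$reversal_mV) * 1e-6   # nS * mV = pA; 1e-6 pA/µA
  if (cfg$noise_sd_uA > 0) {
    current <- current + with_preserved_seed(
      cfg$seed, rnorm(length(current), 0, cfg$noise_sd_uA))
  }
  current_trace(time_ms, voltage_mV, current,
                metadata = list(protocol = prot, condition = condition,
                                seed = cfg$seed, states = S,
                                epoch_table = ep))
}
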