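# Empirical curve families used throughout voltage-clamp analysis:
# single and double Boltzmann G-V curves, the logistic (Hill)
# concentration-response, and sums of exponential decays for tail currents.

#' Boltzmann G-V parameters
#'
#' @param v05_mV Half-activation voltage in mV.
#' @param k_mV Slope factor in mV (> 0).
#' @return Object of class `boltzmann_params`.
#' @export
boltzmann_params <- function(v05_mV, k_mV) {
  check_number(v05_mV, "v05_mV"); check_number(k_mV, "k_mV")
  stop_if(k_mV <= 0, "slope factor k_mV must be > 0")
  structure(list(v05_mV = v05_mV, k_mV = k_mV), class = "boltzmann_params")
}

#' Boltzmann conductance-voltage curve
#'
#' \eqn{g/g_{max} = 1 / (1 + e^{(V_{0.5} - V)/k})}: rises from 0 to 1 with
#' depolarization, equals 0.5 at `v05_mV`.
#'
#' @param V_mV Voltage(s), mV.
#' @param p A [boltzmann_params()].
#' @return Fractional conductance in (0, 1).
#' @export
boltzmann_gv <- function(V_mV, p) {
  stopifnot(inherits(p, "boltzmann_params"))
  plogis((V_mV - p$v05_mV) / p$k_mV)
}

#' Double-Boltzmann G-V parameters
#'
#' Sum of a hyperpolarization-activated and a depolarization-activated
#' Boltzmann branch plus a constant offset, describing biphasic G-V curves
#' such as those of D540K hERG1a channels. Only the two (V0.5, k) pairs are
#' mechanistically interpreted; amplitudes and offset are free shape
#' parameters of the fit.
#'
#' @param v05_hyp_mV,k_hyp_mV Midpoint and slope (mV, k > 0) of the
#'   hyperpolarization-activated branch.
#' @param A_hyp Amplitude of that branch (>= 0).
#' @param v05_dep_mV,k_dep_mV Midpoint and slope (mV, k > 0) of the
#'   depolarization-activated branch.
#' @param A_dep Amplitude of that branch (>= 0).
#' @param offset Voltage-independent floor (>= 0).
#' @return Object of class `double_boltzmann_params`.
#' @export
double_boltzmann_params <- function(v05_hyp_mV, k_hyp_mV, A_hyp,
                                    v05_dep_mV, k_dep_mV, A_dep, offset = 0) {
  for (nm in c("v05_hyp_mV", "k_hyp_mV", "A_hyp", "v05_dep_mV", "k_dep_mV",
               "A_dep", "offset")) check_number(get(nm), nm)
  stop_if(k_hyp_mV <= 0 || k_dep_mV <= 0, "slope factors must be > 0")
  stop_if(A_hyp < 0 || A_dep < 0 || offset < 0,
          "amplitudes and offset must be >= 0")
  stop_if(A_hyp + A_dep + offset <= 0, "curve must have positive amplitude")
  structure(list(v05_hyp_mV = v05_hyp_mV, k_hyp_mV = k_hyp_mV, A_hyp = A_hyp,
                 v05_dep_mV = v05_dep_mV, k_dep_mV = k_dep_mV, A_dep = A_dep,
                 offset = offset),
            class = "double_boltzmann_params")
}

#' Double-Boltzmann conductance-voltage curve
#'
#' \eqn{offset + A_{hyp}\,\sigma((V_{0.5,hyp} - V)/k_{hyp}) +
#'      A_{dep}\,\sigma((V - V_{0.5,dep})/k_{dep})} with
#' \eqn{\sigma(x) = 1/(1+e^{-x})}: the first branch grows toward
#' hyperpolarization, the second toward depolarization.
#'
#' @param V_mV Voltage(s), mV.
#' @param p A [double_boltzmann_params()].
#' @return Fractional conductance values.
#' @export
double_boltzmann_gv <- function(V_mV, p) {
  stopifnot(inherits(p, "double_boltzmann_params"))
  p$offset +
    p$A_hyp * plogis((p$v05_hyp_mV - V_mV) / p$k_hyp_mV) +
    p$A_dep * plogis((V_mV - p$v05_dep_mV) / p$k_dep_mV)
}

#' Calibrate double-Boltzmann amplitudes to a target trough
#'
#' Given the two (V0.5, k) pairs, chooses equal branch amplitudes and an
#' offset such that over `V_grid` the curve maximum equals 1 and the curve
#' minimum (the trough between the branches) equals `trough`. Because the
#' curve is affine in (A, offset) for fixed shape, the solution is exact.
#'
#' @param v05_hyp_mV,k_hyp_mV,v05_dep_mV,k_dep_mV Branch shape parameters.
#' @param trough Target minimum of the curve over `V_grid`, in (0, 1).
#' @param V_grid Voltages (mV) over which max/min are taken.
#' @return A [double_boltzmann_params()].
#' @export
calibrate_double_boltzmann <- function(v05_hyp_mV, k_hyp_mV,
                                       v05_dep_mV, k_dep_mV,
                                       trough, V_grid = seq(-140, 40, 1)) {
  stop_if(trough < 0 || trough >= 1, "trough must be in [0, 1)")
  shape <- plogis((v05_hyp_mV - V_grid) / k_hyp_mV) +
    plogis((V_grid - v05_dep_mV) / k_dep_mV)
  M <- max(shape); m <- min(shape)
  stop_if(M - m < 1e-6, "branches too close: curve has no trough on this grid")
  A <- (1 - trough) / (M - m)
  offset <- trough - A * m
  stop_if(offset < -1e-12, "requested trough not attainable with offset >= 0")
  double_boltzmann_params(v05_hyp_mV, k_hyp_mV, A,
                          v05_dep_mV, k_dep_mV, A, max(offset, 0))
}

#' Hill (logistic) concentration-response parameters
#'
#' Parameters of the logistic equation
#' \eqn{y(c) = A_{max} + (A_{min} - A_{max}) / (1 + (c/EC_{50})^{n_H})},
#' which runs from `Amin` at zero concentration to `Amax` at saturating
#' concentration; for a potentiating drug `Amax > Amin`.
#'
#' @param Amax,Amin Maximum and minimum values of the measured parameter
#'   (response units).
#' @param ec50_uM Half-maximally effective concentration, µM (> 0).
#' @param nH Hill coefficient (> 0).
#' @return Object of class `hill_params`.
#' @export
hill_params <- function(Amax, Amin, ec50_uM, nH) {
  for (nm in c("Amax", "Amin", "ec50_uM", "nH")) check_number(get(nm), nm)
  stop_if(ec50_uM <= 0, "ec50_uM must be > 0")
  stop_if(nH <= 0, "nH must be > 0")
  structure(list(Amax = Amax, Amin = Amin, ec50_uM = ec50_uM, nH = nH),
            class = "hill_params")
}

#' Logistic (Hill) concentration-response
#'
#' @param conc_uM Concentration(s), µM (>= 0).
#' @param p A [hill_params()].
#' @return Response value(s); `Amin` at `conc_uM = 0`, `(Amax + Amin)/2` at
#'   `ec50_uM`, `Amax` at saturation.
#' @export
hill_response <- function(conc_uM, p) {
  stopifnot(inherits(p, "hill_params"))
  stop_if(any(!is.finite(conc_uM)) || any(conc_uM < 0),
          "concentrations must be finite and >= 0")
  p$Amax + (p$Amin - p$Amax) / (1 + (conc_uM / p$ec50_uM)^p$nH)
}

#' Exponential-mixture (multi-exponential decay) parameters
#'
#' Describes tail-current decay as a sum of 1-3 exponential components plus
#' a constant: \eqn{I(t) = \sum_i A_i e^{-t/\tau_i} + C}. Components are
#' stored in canonical form with time constants sorted ascending (fast
#' first); amplitudes may be signed.
#'
#' @param taus_ms Time constants, ms (> 0), length 1-3.
#' @param amps Amplitudes, one per component (current units).
#' @param offset Constant offset `C` (current units).
#' @return Object of class `exp_mixture` with fields `order`, `taus_ms`,
#'   `amps`, `offset`.
#' @examples
#' exp_mixture(67, 1)                       # mono-exponential, tau = 67 ms
#' exp_mixture(c(1451, 44), c(0.4, 0.6))    # canonicalized to fast-first
#' @export
exp_mixture <- function(taus_ms, amps, offset = 0) {
  stop_if(!is.numeric(taus_ms) || length(taus_ms) < 1L || length(taus_ms) > 3L,
          "taus_ms must have length 1-3")
  stop_if(any(!is.finite(taus_ms)) || any(taus_ms <= 0), "taus_ms must be > 0")
  stop_if(length(amps) != length(taus_ms), "amps must match taus_ms in length")
  stop_if(any(!is.finite(amps)), "amps must be finite")
  check_number(offset, "offset")
  ord <- order(taus_ms)
  stop_if(anyDuplicated(taus_ms) > 0L, "time constants must be distinct")
  structure(list(order = length(taus_ms), taus_ms = taus_ms[ord],
                 amps = amps[ord], offset = offset),
            class = "exp_mixture")
}

#' @export
print.exp_mixture <- function(x, ...) {
  cat(sprintf("<exp_mixture> order %d: tau = [%s] ms, A = [%s], C = %.4g\n",
              x$order, paste(signif(x$taus_ms, 4), collapse = ", "),
              paste(signif(x$amps, 4), collapse = ", "), x$offset))
  invisible(x)
}

#' Evaluate an exponential mixture
#'
#' @param t_ms Time(s) since decay onset, ms (>= 0).
#' @param m An [exp_mixture()].
#' @return Current value(s) \eqn{\sum_i A_i e^{-t/\tau_i} + C}.
#' @export
exp_mixture_value <- function(t_ms, m) {
  stopifnot(inherits(m, "exp_mixture"))
  stop_if(any(t_ms < 0), "t_ms must be >= 0")
  out <- rep(m$offset, length(t_ms))
  for (i in seq_len(m$order)) out <- out + m$amps[i] * exp(-t_ms / m$taus_ms[i])
  out
}
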