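# Nonlinear least-squares estimation for every model family, plus
# exponential model-order selection. All fitters use bounded
# Levenberg-Marquardt (minpack.lm) on unweighted residuals by default,
# searching scale parameters (EC50, slope factors, time constants,
# equilibrium constants) on the log scale.

# ---- dataset coercion ------------------------------------------------------

# standardize a G-V dataset to columns V_mV, g_norm (+ optional weight)
as_gv_dataset <- function(d) {
  stop_if(!is.data.frame(d), "G-V dataset must be a data.frame")
  vcol <- intersect(c("V_mV", "V", "voltage_mV"), names(d))[1]
  gcol <- intersect(c("g_norm", "g", "gv", "ratio"), names(d))[1]
  stop_if(is.na(vcol) || is.na(gcol),
          "G-V dataset needs voltage (V_mV) and conductance (g_norm) columns")
  out <- data.frame(V_mV = d[[vcol]], g_norm = d[[gcol]])
  if ("weight" %in% names(d)) out$weight <- d$weight
  stop_if(any(!is.finite(out$V_mV)) || any(!is.finite(out$g_norm)),
          "G-V dataset contains non-finite values")
  out
}

# standardize a concentration-response dataset to conc_uM, response
as_dose_response <- function(d) {
  stop_if(!is.data.frame(d), "dose-response dataset must be a data.frame")
  ccol <- intersect(c("conc_uM", "conc", "concentration"), names(d))[1]
  rcol <- intersect(c("response", "y"), names(d))[1]
  stop_if(is.na(ccol) || is.na(rcol),
          "dataset needs concentration (conc_uM) and response columns")
  out <- data.frame(conc_uM = d[[ccol]], response = d[[rcol]])
  stop_if(any(out$conc_uM < 0), "concentrations must be >= 0")
  out
}

weighted_resid <- function(resid, weight) {
  if (is.null(weight)) resid else resid * sqrt(weight)
}

# ---- Hill ------------------------------------------------------------------

#' Fit the logistic (Hill) concentration-response equation
#'
#' Least-squares fit of [hill_response()] to (concentration, response)
#' data. EC50 is searched on the log scale; the Hill coefficient is bounded
#' to (0, 10]. Endpoints `Amax`/`Amin` are free, so both potentiation and
#' inhibition data fit naturally.
#'
#' @param d A data.frame with columns `conc_uM` and `response` (replicates
#'   as repeated rows), e.g. from [gen_dose_response()].
#' @param init Optional [hill_params()] starting values.
#' @return A `herg_fit` whose `coef()` is a [hill_params()].
#' @export
fit_hill <- function(d, init = NULL) {
  d <- as_dose_response(d)
  stop_if(length(unique(d$conc_uM)) < 4L,
          "need >= 4 distinct concentrations to fit the Hill equation")
  if (stats::sd(d$response) == 0) {
    return(new_fit_result("hill", NULL, rss = 0, n_points = nrow(d),
                          converged = FALSE, flags = "unidentifiable_flat"))
  }
  means <- tapply(d$response, d$conc_uM, mean)
  concs <- as.numeric(names(means))
  if (is.null(init)) {
    Amin0 <- means[[which.min(concs)]]
    Amax0 <- means[[which.max(concs)]]
    mid <- (Amin0 + Amax0) / 2
    pos <- concs[concs > 0]
    cross <- tryCatch(
      stats::approx(means, concs, xout = mid, ties = mean)$y,
      error = function(e) NA_real_)
    ec50_0 <- if (is.finite(cross) && cross > 0) cross else exp(mean(log(pos)))
    init <- hill_params(Amax = Amax0, Amin = Amin0, ec50_uM = ec50_0, nH = 1)
  }
  stopifnot(inherits(init, "hill_params"))
  cmax <- max(d$conc_uM)
  lo_log <- log(min(d$conc_uM[d$conc_uM > 0])) - log(100)
  hi_log <- log(cmax) + log(100)
  resid_fn <- function(par) {
    p <- hill_params(par[1], par[2], exp(par[3]), par[4])
    hill_response(d$conc_uM, p) - d$response
  }
  fit <- lm_least_squares(
    par = c(init$Amax, init$Amin, log(init$ec50_uM), init$nH),
    resid_fn = resid_fn,
    lower = c(-Inf, -Inf, lo_log, 1e-3),
    upper = c(Inf, Inf, hi_log, 10))
  ec50 <- exp(fit$par[3])
  flags <- character()
  if (abs(fit$par[3] - hi_log) < 1e-6 || abs(fit$par[3] - lo_log) < 1e-6)
    flags <- c(flags, "ec50_at_bound")
  se <- c(Amax = fit$se[1], Amin = fit$se[2],
          ec50_uM = fit$se[3] * ec50,      # delta method from log scale
          nH = fit$se[4])
  new_fit_result("hill",
                 hill_params(fit$par[1], fit$par[2], ec50, fit$par[4]),
                 rss = fit$rss, n_points = nrow(d),
                 converged = fit$converged && !length(flags),
                 se = se, flags = flags)
}

# ---- Boltzmann -------------------------------------------------------------

#' Fit a Boltzmann G-V curve
#'
#' Least-squares fit of [boltzmann_gv()] to (voltage, normalized
#' conductance) data. With `free_amplitude = TRUE` the model becomes
#' `A * sigma((V - V0.5)/k) + C`, which is how ratio-voltage curves are
#' fitted (see [ratio_curve_midpoint()]).
#'
#' @param d A data.frame with columns `V_mV` and `g_norm`.
#' @param init Optional [boltzmann_params()] starting values.
#' @param free_amplitude Fit amplitude and offset as free parameters.
#' @return A `herg_fit`; `coef()` is a [boltzmann_params()], with fitted
#'   amplitude/offset in `$extra` when free.
#' @export
fit_boltzmann <- function(d, init = NULL, free_amplitude = FALSE) {
  d <- as_gv_dataset(d)
  stop_if(length(unique(d$V_mV)) < 4L,
          "need >= 4 distinct voltages to fit a Boltzmann (under-determined)")
  means <- tapply(d$g_norm, d$V_mV, mean)
  volts <- as.numeric(names(means))
  if (is.null(init)) {
    lo <- min(means); hi <- max(means)
    mid <- (lo + hi) / 2
    v05_0 <- tryCatch(stats::approx(means, volts, xout = mid, ties = mean)$y,
                      error = function(e) NA_real_)
    if (!is.finite(v05_0)) v05_0 <- stats::median(volts)
    v10 <- tryCatch(stats::approx(means, volts, xout = lo + 0.1 * (hi - lo),
                                  ties = mean)$y, error = function(e) NA_real_)
    v90 <- tryCatch(stats::approx(means, volts, xout = lo + 0.9 * (hi - lo),
                                  ties = mean)$y, error = function(e) NA_real_)
    k0 <- if (is.finite(v10) && is.finite(v90) && abs(v90 - v10) > 0.1)
      abs(v90 - v10) / 4.39 else diff(range(volts)) / 6
    init <- boltzmann_params(v05_0, max(k0, 0.5))
  }
  stopifnot(inherits(init, "boltzmann_params"))
  w <- d$weight
  if (free_amplitude) {
    span <- max(means) - min(means)
    resid_fn <- function(par) {
      pred <- par[3] * plogis((d$V_mV - par[1]) / exp(par[2])) + par[4]
      weighted_resid(pred - d$g_norm, w)
    }
    fit <- lm_least_squares(c(init$v05_mV, log(init$k_mV), span, min(means)),
                            resid_fn)
    k <- exp(fit$par[2])
    se <- c(v05_mV = fit$se[1], k_mV = fit$se[2] * k,
            amplitude = fit$se[3], offset = fit$se[4])
    extra <- list(amplitude = fit$par[3], offset = fit$par[4])
  } else {
    resid_fn <- function(par) {
      pred <- plogis((d$V_mV - par[1]) / exp(par[2]))
      weighted_resid(pred - d$g_norm, w)
    }
    fit <- lm_least_squares(c(init$v05_mV, log(init$k_mV)), resid_fn)
    k <- exp(fit$par[2])
    se <- c(v05_mV = fit$se[1], k_mV = fit$se[2] * k)
    extra <- list()
  }
  new_fit_result("boltzmann", boltzmann_params(fit$par[1], k),
                 rss = fit$rss, n_points = nrow(d), converged = fit$converged,
                 se = se, extra = extra)
}

# ---- double Boltzmann ------------------------------------------------------

#' Fit a sum of two Boltzmann functions to a biphasic G-V curve
#'
#' For channels that open both on hyperpolarization and depolarization
#' (e.g. D540K hERG1a), fits [double_boltzmann_gv()] with positivity bounds
#' on slopes, amplitudes and offset, using several jittered starts. Reports
#' the fitted-curve minimum and maximum over a dense voltage grid spanning
#' the data (the curve minimum is the conventional "minimum g/gmax").
#'
#' @param d A data.frame with columns `V_mV` and `g_norm`; the data should
#'   span both branches (roughly min V <= -100 mV and max V >= 0 mV).
#' @param init Optional [double_boltzmann_params()] starting values.
#' @param n_starts Number of jittered optimizer starts (best RSS wins).
#' @param start_seed Fixed seed for start-point jitter.
#' @return A `herg_fit`; `coef()` is a [double_boltzmann_params()];
#'   `$extra$curve_min` / `$extra$curve_max` hold the curve extrema.
#'   Branch collapse (both midpoints within 5 mV) is flagged.
#' @export
fit_double_boltzmann <- function(d, init = NULL, n_starts = 5,
                                 start_seed = 1234) {
  d <- as_gv_dataset(d)
  stop_if(length(unique(d$V_mV)) < 6L,
          "need >= 6 distinct voltages to fit a double Boltzmann")
  means <- tapply(d$g_norm, d$V_mV, mean)
  volts <- as.numeric(names(means))
  if (is.null(init)) {
    i_tr <- which.min(means)
    v_tr <- volts[i_tr]
    off0 <- max(min(means), 1e-3)
    Ah0 <- max(means[volts <= v_tr][1] - off0, 0.05)   # most negative V
    Ad0 <- max(means[volts >= v_tr][sum(volts >= v_tr)] - off0, 0.05)
    v05h0 <- if (i_tr > 1) mean(c(min(volts), v_tr)) else min(volts) + 10
    v05d0 <- if (i_tr < length(volts)) mean(c(max(volts), v_tr)) else max(volts) - 10
    init <- double_boltzmann_params(v05h0, 10, Ah0, v05d0, 10, Ad0, off0)
  }
  stopifnot(inherits(init, "double_boltzmann_params"))
  w <- d$weight
  resid_fn <- function(par) {
    pred <- par[7] +
      par[3] * plogis((par[1] - d$V_mV) / exp(par[2])) +
      par[6] * plogis((d$V_mV - par[4]) / exp(par[5]))
    weighted_resid(pred - d$g_norm, w)
  }
  base <- c(init$v05_hyp_mV, log(init$k_hyp_mV), init$A_hyp,
            init$v05_dep_mV, log(init$k_dep_mV), init$A_dep, init$offset)
  lower <- c(-Inf, log(0.1), 0, -Inf, log(0.1), 0, 0)
  upper <- c(Inf, log(100), Inf, Inf, log(100), Inf, Inf)
  starts <- with_preserved_seed(start_seed, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1) return(base)
      jit <- base
      jit[c(1, 4)] <- jit[c(1, 4)] + stats::runif(2, -15, 15)
      jit[c(2, 5)] <- jit[c(2, 5)] + stats::runif(2, -0.5, 0.5)
      jit[c(3, 6)] <- pmax(jit[c(3, 6)] * exp(stats::runif(2, -0.5, 0.5)), 1e-3)
      jit
    })
  })
  best <- NULL
  for (st in starts) {
    fit <- lm_least_squares(st, resid_fn, lower, upper)
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  fit <- best
  p <- double_boltzmann_params(fit$par[1], exp(fit$par[2]), fit$par[3],
                               fit$par[4], exp(fit$par[5]), fit$par[6],
                               fit$par[7])
  grid <- seq(min(d$V_mV), max(d$V_mV), length.out = 2001)
  curve <- double_boltzmann_gv(grid, p)
  flags <- character()
  if (abs(p$v05_hyp_mV - p$v05_dep_mV) < 5) flags <- c(flags, "branch_collapse")
  se <- c(v05_hyp_mV = fit$se[1], k_hyp_mV = fit$se[2] * exp(fit$par[2]),
          A_hyp = fit$se[3],
          v05_dep_mV = fit$se[4], k_dep_mV = fit$se[5] * exp(fit$par[5]),
          A_dep = fit$se[6], offset = fit$se[7])
  new_fit_result("double_boltzmann", p, rss = fit$rss, n_points = nrow(d),
                 converged = fit$converged, se = se, flags = flags,
                 extra = list(curve_min = min(curve), curve_max = max(curve),
                              curve_min_V = grid[which.min(curve)]))
}

# ---- 6-state gating model --------------------------------------------------

#' Fit the 6-state gating model to a G-V dataset
#'
#' Least-squares estimation of (`K0`, `z1`, `Ko0`, `z2`) from a normalized
#' G-V relationship. Equilibrium constants are searched on the log scale
#' with positivity bounds on the charges, using multiple jittered starts
#' (best RSS wins). Because experimental G-V data are normalized to their
#' maximum over the tested voltages, the model prediction is renormalized
#' the same way before computing residuals (`normalize = TRUE`).
#'
#' @param d A data.frame with columns `V_mV` and `g_norm`, spanning the
#'   activation range at >= 6 distinct voltages.
#' @param ctx A [thermo_context()].
#' @param init Optional [gating_params()] starting values.
#' @param n_starts Number of optimizer starts (>= 1; 5 by default).
#' @param start_seed Fixed seed for start-point jitter.
#' @param normalize Renormalize the model curve to its maximum over the
#'   data voltages (matching how the data were normalized).
#' @return A `herg_fit`; `coef()` is a [gating_params()].
#' @export
fit_gating_gv <- function(d, ctx = thermo_context(), init = NULL,
                          n_starts = 5, start_seed = 1234, normalize = TRUE) {
  d <- as_gv_dataset(d)
  stop_if(length(unique(d$V_mV)) < 6L,
          "need >= 6 distinct voltages to fit the 6-state model")
  if (is.null(init)) init <- gating_params(0.2, 1.5, 0.3, 0.7)
  stopifnot(inherits(init, "gating_params"))
  w <- d$weight
  vs <- sort(unique(d$V_mV))
  predict_g <- function(par) {
    p <- gating_params(exp(par[1]), par[2], exp(par[3]), par[4])
    po <- po_equilibrium(p, d$V_mV, ctx)
    if (normalize) po / max(po_equilibrium(p, vs, ctx)) else po
  }
  resid_fn <- function(par) weighted_resid(predict_g(par) - d$g_norm, w)
  base <- c(log(max(init$K0, 1e-8)), init$z1, log(max(init$Ko0, 1e-8)), init$z2)
  lower <- c(-25, 0, -25, 0)
  upper <- c(15, 15, 15, 15)
  starts <- with_preserved_seed(start_seed, {
    lapply(seq_len(max(1L, n_starts)), function(i) {
      if (i == 1) return(base)
      jit <- base
      jit[c(1, 3)] <- jit[c(1, 3)] + stats::runif(2, -2, 2)
      jit[c(2, 4)] <- pmax(jit[c(2, 4)] + stats::runif(2, -0.8, 0.8), 0.05)
      jit
    })
  })
  best <- NULL
  for (st in starts) {
    fit <- lm_least_squares(st, resid_fn, lower, upper)
    if (fit$converged && (is.null(best) || fit$rss < best$rss)) best <- fit
  }
  if (is.null(best)) {
    return(new_fit_result("gating6", NULL, rss = Inf, n_points = nrow(d),
                          converged = FALSE, flags = "all_starts_failed"))
  }
  fit <- best
  p <- gating_params(exp(fit$par[1]), fit$par[2], exp(fit$par[3]), fit$par[4])
  se <- c(K0 = fit$se[1] * p$K0, z1 = fit$se[2],
          Ko0 = fit$se[3] * p$Ko0, z2 = fit$se[4])
  new_fit_result("gating6", p, rss = fit$rss, n_points = nrow(d),
                 converged = TRUE, se = se)
}

# ---- exponential decay -----------------------------------------------------

# peeling initializer: estimate components slow-to-fast by repeated
# log-linear fits of the late phase
peel_exp_init <- function(t, y, order) {
  C0 <- mean(y[t >= stats::quantile(t, 0.95)])
  r <- y - C0
  sgn <- if (sum(r[seq_len(max(3, length(r) %/% 10))]) < 0) -1 else 1
  r <- r * sgn
  taus <- amps <- numeric(0)
  t_hi <- max(t)
  for (i in seq_len(order)) {
    ok <- which(r > max(r, 0) * 1e-4 & t <= t_hi)
    if (length(ok) < 5) break
    late <- ok[t[ok] >= stats::quantile(t[ok], 1 - 1 / (order - i + 2))]
    if (length(late) < 3) late <- utils::tail(ok, 5)
    co <- stats::coef(stats::lm(log(r[late]) ~ t[late]))
    if (!is.finite(co[2]) || co[2] >= 0) break
    tau <- -1 / co[2]
    amp <- exp(co[1])
    taus <- c(taus, tau); amps <- c(amps, amp)
    r <- r - amp * exp(-t / tau)
    t_hi <- stats::quantile(t[ok], 0.5)
  }
  while (length(taus) < order) {          # pad with a faster component
    taus <- c(taus, (if (length(taus)) min(taus) else max(t) / 3) / 5)
    amps <- c(amps, max(amps, 0.1))
  }
  list(taus = taus, amps = amps * sgn, offset = C0)
}

# given taus, amplitudes and offset are linear: solve by ordinary LS
solve_linear_amps <- function(t, y, taus) {
  X <- cbind(vapply(taus, function(tau) exp(-t / tau), numeric(length(t))), 1)
  co <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(NA_real_, ncol(X)))
  co[!is.finite(co)] <- 0
  list(amps = co[seq_along(taus)], offset = co[length(co)])
}

#' Fit a multi-exponential decay to a tail-current segment
#'
#' Fits \eqn{I(t) = \sum_i A_i e^{-t/\tau_i} + C} of the given order to a
#' decay segment re-zeroed at the tail peak. Time constants are searched on
#' the log scale; initialization is by peeling (log-linear fit of the late
#' phase, subtract, repeat) with a geometric-ladder fallback, amplitudes
#' solved linearly given the taus. Returned taus are sorted ascending.
#' Fits whose adjacent tau ratio falls below 1.5 are flagged
#' `"tau_collapse"` (over-parameterized).
#'
#' @param t_ms Time since tail peak, ms (or a data.frame with columns
#'   `time_ms` and `current_uA`, in which case `current` is ignored).
#' @param current Current samples, µA.
#' @param order Number of exponential components (1, 2 or 3).
#' @param init Optional [exp_mixture()] starting values.
#' @return A `herg_fit`; `coef()` is an [exp_mixture()]; `$extra$aicc`
#'   holds the corrected Akaike criterion.
#' @export
fit_exp_decay <- function(t_ms, current = NULL, order = 1, init = NULL) {
  if (is.data.frame(t_ms)) {
    current <- t_ms$current_uA %||% t_ms$current
    t_ms <- t_ms$time_ms %||% t_ms$t_ms
  }
  stop_if(!order %in% 1:3, "order must be 1, 2 or 3")
  stop_if(length(t_ms) != length(current), "time and current lengths differ")
  stop_if(length(t_ms) < 10 * order,
          "need at least 10 samples per exponential component")
  t <- t_ms - t_ms[1]
  y <- current

  cand <- list()
  if (!is.null(init)) {
    stopifnot(inherits(init, "exp_mixture"))
    stop_if(init$order != order, "init order does not match requested order")
    cand[[length(cand) + 1]] <- list(taus = init$taus_ms, amps = init$amps,
                                     offset = init$offset)
  }
  peel <- tryCatch(peel_exp_init(t, y, order), error = function(e) NULL)
  if (!is.null(peel)) cand[[length(cand) + 1]] <- peel
  # geometric ladder spanning the record
  Tspan <- max(t)
  ladder_taus <- Tspan / (3 * 5^(seq(order - 1, 0)))
  lad <- solve_linear_amps(t, y, ladder_taus)
  cand[[length(cand) + 1]] <- list(taus = ladder_taus, amps = lad$amps,
                                   offset = lad$offset)

  resid_fn <- function(par) {
    taus <- exp(par[seq_len(order)])
    amps <- par[order + seq_len(order)]
    off <- par[2 * order + 1]
    pred <- rep(off, length(t))
    for (i in seq_len(order)) pred <- pred + amps[i] * exp(-t / taus[i])
    pred - y
  }
  dt <- t[2] - t[1]
  lo <- c(rep(log(dt / 10), order), rep(-Inf, order + 1))
  hi <- c(rep(log(Tspan * 100), order), rep(Inf, order + 1))
  best <- NULL
  for (cd in cand) {
    ln <- solve_linear_amps(t, y, cd$taus)   # refine amplitudes linearly
    par0 <- c(log(cd$taus), ln$amps, ln$offset)
    fit <- lm_least_squares(par0, resid_fn, lo, hi)
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  fit <- best
  taus <- exp(fit$par[seq_len(order)])
  amps <- fit$par[order + seq_len(order)]
  off <- fit$par[2 * order + 1]
  flags <- character()
  if (order > 1) {
    st <- sort(taus)
    if (any(st[-1] / st[-order] < 1.5)) flags <- c(flags, "tau_collapse")
  }
  if (anyDuplicated(signif(taus, 12)) > 0L)
    taus <- taus * (1 + 1e-9 * seq_along(taus))   # keep mixture constructible
  m <- exp_mixture(taus, amps, off)
  ord_idx <- order(exp(fit$par[seq_len(order)]))
  se_tau <- (fit$se[seq_len(order)] * taus)[ord_idx]
  se_amp <- fit$se[order + seq_len(order)][ord_idx]
  se <- c(stats::setNames(se_tau, paste0("tau", seq_len(order))),
          stats::setNames(se_amp, paste0("A", seq_len(order))),
          offset = fit$se[2 * order + 1])
  new_fit_result(paste0("exp", order), m, rss = fit$rss,
                 n_points = length(t), converged = fit$converged,
                 se = se, flags = flags,
                 extra = list(aicc = aicc_from_rss(fit$rss, length(t),
                                                   2 * order + 1)))
}

#' Select the exponential order of a tail-current decay
#'
#' Fits orders 1..`max_order` and increases the order while the
#' extra-sum-of-squares F-test rejects the simpler model at `alpha` and the
#' richer fit is neither degenerate (`tau_collapse`) nor non-converged.
#' AICc values are reported for reference but do not decide.
#'
#' @inheritParams fit_exp_decay
#' @param max_order Largest order to consider (<= 3).
#' @param alpha Significance level of the F-test.
#' @return A list with `order` (chosen), `fits` (per-order `herg_fit`s) and
#'   `comparison` (data.frame of F statistics and p-values).
#' @export
select_exp_order <- function(t_ms, current = NULL, max_order = 3,
                             alpha = 0.05) {
  if (is.data.frame(t_ms)) {
    current <- t_ms$current_uA %||% t_ms$current
    t_ms <- t_ms$time_ms %||% t_ms$t_ms
  }
  stop_if(!max_order %in% 1:3, "max_order must be 1, 2 or 3")
  n <- length(t_ms)
  fits <- list(fit_exp_decay(t_ms, current, order = 1))
  chosen <- 1L
  comp <- data.frame(order_simple = integer(), order_rich = integer(),
                     F = numeric(), p = numeric(), accepted = logical())
  for (k in seq_len(max_order - 1)) {
    rich <- fit_exp_decay(t_ms, current, order = k + 1)
    fits[[k + 1]] <- rich
    p1 <- 2 * k + 1; p2 <- 2 * (k + 1) + 1
    Fstat <- ((fits[[k]]$rss - rich$rss) / (p2 - p1)) / (rich$rss / (n - p2))
    pval <- stats::pf(Fstat, p2 - p1, n - p2, lower.tail = FALSE)
    ok <- is.finite(Fstat) && pval < alpha && rich$converged &&
      !"tau_collapse" %in% rich$flags
    comp <- rbind(comp, data.frame(order_simple = k, order_rich = k + 1,
                                   F = Fstat, p = pval, accepted = ok))
    if (!ok) break
    chosen <- k + 1L
  }
  list(order = chosen, fits = fits, comparison = comp)
}
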