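# Measurement operators on current traces: peak and tail extraction,
# normalization conventions, the tail-ratio statistic and per-sweep
# deactivation fits.

# sample indices belonging to a protocol epoch (0 = holding). Traces read
# from CSV carry no protocol metadata; their epochs are inferred from runs
# of constant command voltage (numbered 1..k in order).
trace_epoch_idx <- function(tr, epoch_index) {
  stopifnot(inherits(tr, "current_trace"))
  prot <- tr$metadata$protocol
  ep <- if (is.null(prot)) {
    runs <- rle(tr$voltage_mV)
    ends_i <- cumsum(runs$lengths)
    dt <- tr$time_ms[2] - tr$time_ms[1]
    data.frame(epoch = seq_along(runs$values),
               start_ms = tr$time_ms[c(1, utils::head(ends_i, -1) + 1)],
               end_ms = tr$time_ms[ends_i] + dt,
               voltage_mV = runs$values)
  } else {
    tr$metadata$epoch_table %||% protocol_epoch_table(prot)
  }
  row <- which(ep$epoch == epoch_index)
  stop_if(length(row) != 1L, "epoch %s not present in protocol", epoch_index)
  idx <- which(tr$time_ms >= ep$start_ms[row] - 1e-9 &
                 tr$time_ms < ep$end_ms[row] - 1e-9)
  stop_if(length(idx) == 0L, "epoch %s contains no samples", epoch_index)
  idx
}

#' Peak current within a protocol epoch
#'
#' Extremum of the current inside the given epoch after skipping an initial
#' blanking window (used to ignore capacitance-transient artifacts in real
#' recordings). Outward-positive convention: `direction = "outward"` takes
#' the maximum, `"inward"` the minimum, `"absolute"` the largest magnitude.
#'
#' @param tr A [current_trace()] with protocol metadata.
#' @param epoch_index Epoch number (0 = holding, 1.. = protocol epochs).
#' @param blank_ms Initial time to skip within the epoch, ms.
#' @param direction One of `"outward"`, `"inward"`, `"absolute"`.
#' @return Peak current, µA.
#' @export
measure_peak_current <- function(tr, epoch_index, blank_ms = 0,
                                 direction = c("outward", "inward", "absolute")) {
  direction <- match.arg(direction)
  idx <- trace_epoch_idx(tr, epoch_index)
  t0 <- tr$time_ms[idx[1]]
  keep <- idx[tr$time_ms[idx] >= t0 + blank_ms]
  stop_if(length(keep) == 0L,
          "blanking window (%g ms) covers the whole epoch", blank_ms)
  cur <- tr$current_uA[keep]
  switch(direction,
         outward = max(cur),
         inward = min(cur),
         absolute = cur[which.max(abs(cur))])
}

#' Peak tail current and its time
#'
#' Finds the tail-current peak in a return epoch (after blanking) and the
#' sample time at which it occurs, used to re-zero tail decays before
#' exponential fitting.
#'
#' @inheritParams measure_peak_current
#' @param return_epoch Epoch index of the return (repolarization) step.
#' @param blank_ms Initial blanking, ms (default 2).
#' @return A list with `I_tail_peak_uA` and `t_peak_ms` (absolute trace time).
#' @export
measure_tail_peak <- function(tr, return_epoch, blank_ms = 2,
                              direction = c("absolute", "outward", "inward")) {
  direction <- match.arg(direction)
  idx <- trace_epoch_idx(tr, return_epoch)
  t0 <- tr$time_ms[idx[1]]
  keep <- idx[tr$time_ms[idx] >= t0 + blank_ms]
  stop_if(length(keep) == 0L,
          "blanking window (%g ms) covers the whole epoch", blank_ms)
  cur <- tr$current_uA[keep]
  ipk <- switch(direction,
                outward = which.max(cur),
                inward = which.min(cur),
                absolute = which.max(abs(cur)))
  list(I_tail_peak_uA = cur[ipk], t_peak_ms = tr$time_ms[keep[ipk]])
}

#' Tail-current ratio statistic
#'
#' `I_tail_end / I_tail_peak`: the fraction of tail current remaining
#' `t_end_ms` after the tail peak. Summarizes deactivation without
#' committing to an exponential order; its voltage dependence (ratio vs
#' return potential) shifts when deactivation is slowed.
#'
#' @inheritParams measure_tail_peak
#' @param t_end_ms Time after the tail peak at which the end current is
#'   read, ms (e.g. 2500 for slowly deactivating WT channels, 25 for fast
#'   split channels).
#' @return Ratio (dimensionless); `NA` with a warning when the tail peak is
#'   indistinguishable from zero.
#' @export
tail_ratio <- function(tr, return_epoch, t_end_ms, blank_ms = 2,
                       direction = c("absolute", "outward", "inward")) {
  direction <- match.arg(direction)
  pk <- measure_tail_peak(tr, return_epoch, blank_ms, direction)
  idx <- trace_epoch_idx(tr, return_epoch)
  t_target <- pk$t_peak_ms + t_end_ms
  stop_if(t_target > tr$time_ms[idx[length(idx)]] + 1e-9,
          "t_end_ms = %g extends beyond the return epoch", t_end_ms)
  i_end <- idx[which.min(abs(tr$time_ms[idx] - t_target))]
  scale <- max(abs(tr$current_uA[idx]))
  if (abs(pk$I_tail_peak_uA) < max(scale * 1e-6, .Machine$double.eps)) {
    warning("tail peak is ~0; ratio undefined")
    return(NA_real_)
  }
  tr$current_uA[i_end] / pk$I_tail_peak_uA
}

#' Tail-ratio versus return-potential curve
#'
#' Applies [tail_ratio()] across a family of sweeps in which the return
#' potential was varied.
#'
#' @param fam A [sweep_family()] varying the return epoch voltage.
#' @param t_end_ms See [tail_ratio()].
#' @param blank_ms,direction Passed to [tail_ratio()].
#' @return A data.frame with columns `V_ret_mV` and `ratio`, with the
#'   condition label and `t_end_ms` as attributes.
#' @export
ratio_curve <- function(fam, t_end_ms, blank_ms = 2,
                        direction = c("absolute", "outward", "inward")) {
  stopifnot(inherits(fam, "sweep_family"))
  direction <- match.arg(direction)
  ratios <- vapply(fam$traces, tail_ratio, numeric(1),
                   return_epoch = fam$varied_epoch, t_end_ms = t_end_ms,
                   blank_ms = blank_ms, direction = direction)
  out <- data.frame(V_ret_mV = fam$varied_voltage_mV, ratio = ratios)
  attr(out, "condition") <- fam$condition
  attr(out, "t_end_ms") <- t_end_ms
  out
}

#' Midpoint of a tail-ratio curve
#'
#' Fits a Boltzmann with free amplitude and offset to ratio vs return
#' potential and returns the half-point voltage. More robust to noise than
#' linear interpolation of the half-crossing.
#'
#' @param rc A data.frame with columns `V_ret_mV` (or `V_mV`) and `ratio`,
#'   e.g. from [ratio_curve()].
#' @return A list with `midpoint_mV` and the underlying `fit`.
#' @export
ratio_curve_midpoint <- function(rc) {
  stop_if(!is.data.frame(rc), "ratio curve must be a data.frame")
  v <- rc$V_ret_mV %||% rc$V_mV
  stop_if(is.null(v) || is.null(rc$ratio), "need V_ret_mV and ratio columns")
  ok <- is.finite(rc$ratio)
  stop_if(sum(ok) < 4L, "need >= 4 finite ratio points")
  rng <- diff(range(rc$ratio[ok]))
  stop_if(rng < 0.2,
          "ratio curve is too flat to locate a midpoint (span %.3g)", rng)
  fit <- fit_boltzmann(data.frame(V_mV = v[ok], g_norm = rc$ratio[ok]),
                       free_amplitude = TRUE)
  list(midpoint_mV = coef(fit)$v05_mV, fit = fit)
}

#' Build a G-V dataset from tail-current peaks
#'
#' Measures the peak tail current of every sweep of a test-potential family
#' (fixed return potential) and normalizes: `per_condition_max` divides by
#' the family's own maximum (the resulting maximum is exactly 1);
#' `control_max` divides by a supplied reference (e.g. the control family's
#' maximum), so a potentiated condition may exceed 1.
#'
#' @param fam A [sweep_family()] varying the test-pulse epoch, with the
#'   tail measured in the following epoch.
#' @param normalization `"per_condition_max"` or `"control_max"`.
#' @param reference_max_uA Reference tail maximum for `control_max` mode.
#' @param return_epoch Epoch of the tail; defaults to the epoch after the
#'   varied one.
#' @param blank_ms,direction Passed to [measure_tail_peak()].
#' @return A data.frame with columns `V_mV`, `g_norm` and `condition`, with
#'   the raw tail maximum as attribute `tail_max_uA`.
#' @export
build_gv_from_tails <- function(fam,
                                normalization = c("per_condition_max",
                                                  "control_max"),
                                reference_max_uA = NULL, return_epoch = NULL,
                                blank_ms = 2,
                                direction = c("absolute", "outward", "inward")) {
  stopifnot(inherits(fam, "sweep_family"))
  normalization <- match.arg(normalization)
  direction <- match.arg(direction)
  return_epoch <- return_epoch %||% (fam$varied_epoch + 1L)
  peaks <- vapply(fam$traces, function(tr)
    measure_tail_peak(tr, return_epoch, blank_ms, direction)$I_tail_peak_uA,
    numeric(1))
  fam_max <- max(abs(peaks))
  stop_if(fam_max == 0, "all tail peaks are zero; cannot normalize")
  denom <- if (normalization == "per_condition_max") fam_max else {
    stop_if(is.null(reference_max_uA) || reference_max_uA == 0,
            "control_max normalization needs a nonzero reference_max_uA")
    abs(reference_max_uA)
  }
  out <- data.frame(V_mV = fam$varied_voltage_mV,
                    g_norm = abs(peaks) / denom,
                    condition = fam$condition)
  attr(out, "tail_max_uA") <- fam_max
  out
}

#' Deactivation time constants across return potentials
#'
#' Fits the tail decay of every sweep of a return-potential family with a
#' multi-exponential, re-zeroed at the tail peak. The order is chosen per
#' sweep by [select_exp_order()] (`order = "auto"`) or forced.
#'
#' @param fam A [sweep_family()] varying the return epoch after a fixed
#'   activating step.
#' @param order `"auto"` or a fixed order 1-3.
#' @param alpha F-test level for automatic order selection.
#' @param blank_ms,direction Passed to [measure_tail_peak()].
#' @return A tidy data.frame with one row per fitted component: `V_ret_mV`,
#'   `order`, `component`, `tau_ms`, `amplitude`, `rel_amplitude`, `offset`,
#'   `rss`, `converged`, `flags`. The per-sweep `herg_fit`s are attached as
#'   attribute `fits`.
#' @export
deactivation_tau_curve <- function(fam, order = "auto", alpha = 0.05,
                                   blank_ms = 2,
                                   direction = c("absolute", "outward",
                                                 "inward")) {
  stopifnot(inherits(fam, "sweep_family"))
  direction <- match.arg(direction)
  rows <- list(); fits <- list()
  for (i in seq_along(fam$traces)) {
    tr <- fam$traces[[i]]
    pk <- measure_tail_peak(tr, fam$varied_epoch, blank_ms, direction)
    idx <- trace_epoch_idx(tr, fam$varied_epoch)
    seg <- idx[tr$time_ms[idx] >= pk$t_peak_ms]
    t <- tr$time_ms[seg] - pk$t_peak_ms
    y <- tr$current_uA[seg]
    if (identical(order, "auto")) {
      sel <- select_exp_order(t, y, max_order = 3, alpha = alpha)
      fit <- sel$fits[[sel$order]]
    } else {
      fit <- fit_exp_decay(t, y, order = as.integer(order))
    }
    fits[[i]] <- fit
    m <- coef(fit)
    rows[[i]] <- data.frame(
      V_ret_mV = fam$varied_voltage_mV[i], order = m$order,
      component = seq_len(m$order), tau_ms = m$taus_ms,
      amplitude = m$amps,
      rel_amplitude = m$amps / sum(abs(m$amps)),
      offset = m$offset, rss = fit$rss, converged = fit$converged,
      flags = paste(fit$flags, collapse = ";"))
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "condition") <- fam$condition
  out
}
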