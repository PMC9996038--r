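# Voltage-clamp protocol and trace containers.

#' Step voltage-clamp protocol
#'
#' An ordered sequence of constant-voltage epochs preceded by an implicit
#' holding epoch. Times in ms, voltages in mV.
#'
#' @param epochs A list of `c(duration_ms, voltage_mV)` pairs, or a 2-column
#'   matrix/data.frame with columns duration and voltage.
#' @param sample_interval_ms Sampling interval, ms (> 0).
#' @param holding_mV Holding potential (implicit epoch 0).
#' @param holding_ms Duration of the recorded holding segment, ms (>= 0).
#' @return Object of class `voltage_protocol` whose `$epochs` is a
#'   data.frame with columns `duration_ms`, `voltage_mV` (holding epoch
#'   included as row 1 when `holding_ms > 0`, tagged in `$holding_rows`).
#' @examples
#' voltage_protocol(list(c(4000, 60), c(2000, -40)),
#'                  sample_interval_ms = 1, holding_mV = -70)
#' @export
voltage_protocol <- function(epochs, sample_interval_ms = 1,
                             holding_mV = -70, holding_ms = 100) {
  if (is.matrix(epochs) || is.data.frame(epochs)) {
    epochs <- lapply(seq_len(nrow(epochs)), function(i) as.numeric(epochs[i, 1:2]))
  }
  stop_if(length(epochs) == 0L, "protocol must contain at least one epoch")
  ep <- do.call(rbind, lapply(epochs, function(e) {
    stop_if(length(e) != 2L || any(!is.finite(e)), "each epoch is c(duration_ms, voltage_mV)")
    stop_if(e[1] <= 0, "epoch durations must be > 0")
    data.frame(duration_ms = e[1], voltage_mV = e[2])
  }))
  check_number(sample_interval_ms, "sample_interval_ms")
  stop_if(sample_interval_ms <= 0, "sample_interval_ms must be > 0")
  check_number(holding_mV, "holding_mV")
  check_number(holding_ms, "holding_ms")
  stop_if(holding_ms < 0, "holding_ms must be >= 0")
  structure(list(epochs = ep, sample_interval_ms = sample_interval_ms,
                 holding_mV = holding_mV, holding_ms = holding_ms),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> hold %g mV (%g ms), %d epoch(s), dt = %g ms\n",
              x$holding_mV, x$holding_ms, nrow(x$epochs), x$sample_interval_ms))
  for (i in seq_len(nrow(x$epochs)))
    cat(sprintf("  epoch %d: %g ms at %g mV\n", i,
                x$epochs$duration_ms[i], x$epochs$voltage_mV[i]))
  invisible(x)
}

# epoch table including the implicit holding epoch as row 0 metadata:
# returns data.frame(epoch, start_ms, end_ms, voltage_mV); epoch 0 = holding
protocol_epoch_table <- function(prot) {
  dur <- c(prot$holding_ms, prot$epochs$duration_ms)
  volt <- c(prot$holding_mV, prot$epochs$voltage_mV)
  keep <- dur > 0
  ends <- cumsum(dur)
  data.frame(epoch = c(0L, seq_len(nrow(prot$epochs))),
             start_ms = c(0, ends[-length(ends)]),
             end_ms = ends,
             voltage_mV = volt)[keep, , drop = FALSE]
}

#' Simulation configuration
#'
#' Current-scaling and noise settings for the mean-field simulator. The
#' macroscopic current is `n_channels * unitary_conductance_nS * Po *
#' (V - reversal_mV)`, converted to µA, plus optional additive Gaussian
#' noise. Defaults give oocyte-scale (µA) currents.
#'
#' @param n_channels Number of channels (>= 1).
#' @param unitary_conductance_nS Single-channel conductance, nS (> 0).
#' @param reversal_mV Reversal potential, mV (near 0 in high-K bath, about
#'   -100 mV in low-K bath).
#' @param noise_sd_uA SD of additive Gaussian recording noise, µA (>= 0).
#' @param seed Integer RNG seed for the noise.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 1e6, unitary_conductance_nS = 0.012,
                       reversal_mV = 0, noise_sd_uA = 0, seed = 1L) {
  check_number(n_channels, "n_channels")
  stop_if(n_channels < 1, "n_channels must be >= 1")
  check_number(unitary_conductance_nS, "unitary_conductance_nS")
  stop_if(unitary_conductance_nS <= 0, "unitary_conductance_nS must be > 0")
  check_number(reversal_mV, "reversal_mV")
  check_number(noise_sd_uA, "noise_sd_uA")
  stop_if(noise_sd_uA < 0, "noise_sd_uA must be >= 0")
  structure(list(n_channels = n_channels,
                 unitary_conductance_nS = unitary_conductance_nS,
                 reversal_mV = reversal_mV, noise_sd_uA = noise_sd_uA,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Current trace
#'
#' A sampled voltage-clamp sweep: uniformly sampled time, the command
#' voltage and the recorded (or simulated) current.
#'
#' @param time_ms,voltage_mV,current_uA Equal-length numeric vectors;
#'   `time_ms` strictly increasing and uniformly spaced.
#' @param metadata Named list (protocol, condition label, seed, ...).
#' @return Object of class `current_trace`.
#' @export
current_trace <- function(time_ms, voltage_mV, current_uA, metadata = list()) {
  n <- length(time_ms)
  stop_if(length(voltage_mV) != n || length(current_uA) != n,
          "time, voltage and current must have equal length")
  stop_if(n < 2L, "trace needs at least 2 samples")
  dt <- diff(time_ms)
  stop_if(any(dt <= 0), "time_ms must be strictly increasing")
  stop_if(max(abs(dt - dt[1])) > 1e-6 * dt[1] + 1e-9,
          "time_ms must be uniformly sampled")
  structure(list(time_ms = time_ms, voltage_mV = voltage_mV,
                 current_uA = current_uA, metadata = metadata),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples, %g-%g ms, V in [%g, %g] mV%s\n",
              length(x$time_ms), min(x$time_ms), max(x$time_ms),
              min(x$voltage_mV), max(x$voltage_mV),
              if (!is.null(x$metadata$condition))
                paste0(" [", x$metadata$condition, "]") else ""))
  invisible(x)
}

#' Family of sweeps sharing a protocol template
#'
#' Collects traces from a protocol in which exactly one epoch's voltage was
#' varied across sweeps (a test-potential or return-potential family).
#'
#' @param traces List of [current_trace()] objects.
#' @param varied_voltage_mV Numeric vector, one voltage per trace.
#' @param varied_epoch Index (1-based) of the varied epoch.
#' @param condition Condition label.
#' @return Object of class `sweep_family`.
#' @export
sweep_family <- function(traces, varied_voltage_mV, varied_epoch,
                         condition = "unlabeled") {
  stop_if(length(traces) != length(varied_voltage_mV),
          "one varied voltage per trace required")
  stop_if(length(traces) == 0L, "family must contain at least one sweep")
  stop_if(!all(vapply(traces, inherits, logical(1), "current_trace")),
          "traces must be current_trace objects")
  ns <- vapply(traces, function(tr) length(tr$time_ms), integer(1))
  stop_if(length(unique(ns)) != 1L, "all sweeps must share sampling structure")
  structure(list(traces = traces, varied_voltage_mV = varied_voltage_mV,
                 varied_epoch = as.integer(varied_epoch), condition = condition),
            class = "sweep_family")
}

#' @export
print.sweep_family <- function(x, ...) {
  cat(sprintf("<sweep_family> %d sweeps [%s], varied epoch %d: %s mV\n",
              length(x$traces), x$condition, x$varied_epoch,
              paste(x$varied_voltage_mV, collapse = ", ")))
  invisible(x)
}
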