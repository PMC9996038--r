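# Seeded synthetic-data generators. Every generator's noiseless output is
# exactly its closed-form model; noise is additive Gaussian with an SD given
# either absolutely or as a fraction of the signal span (scale-free, 3% by
# default), and identical seeds give byte-identical output.

#' Noise specification for synthetic data
#'
#' Additive Gaussian noise, with the SD given either in the units of the
#' generated quantity (`sd`) or as a fraction of the noiseless signal span
#' (`frac_span`; used when `sd` is `NULL`).
#'
#' @param sd Absolute noise SD (>= 0), or `NULL` to use `frac_span`.
#' @param frac_span Noise SD as a fraction of the signal span.
#' @param seed Integer RNG seed.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(sd = NULL, frac_span = 0.03, seed = 1L) {
  if (!is.null(sd)) {
    check_number(sd, "sd")
    stop_if(sd < 0, "sd must be >= 0")
  }
  check_number(frac_span, "frac_span")
  stop_if(frac_span < 0, "frac_span must be >= 0")
  structure(list(sd = sd, frac_span = frac_span, seed = as.integer(seed)),
            class = "noise_spec")
}

resolve_sd <- function(noise, signal) {
  if (!is.null(noise$sd)) return(noise$sd)
  span <- diff(range(signal))
  noise$frac_span * span
}

add_noise <- function(signal, noise, n_draws = length(signal)) {
  sdv <- resolve_sd(noise, signal)
  if (sdv == 0) return(signal)
  signal + with_preserved_seed(noise$seed, stats::rnorm(n_draws, 0, sdv))
}

#' Generate a synthetic concentration-response dataset
#'
#' Draws `n` replicate response curves from [hill_response()] plus additive
#' Gaussian noise, emulating cumulative drug-application experiments.
#'
#' @param p A [hill_params()] (the generator truth).
#' @param concs_uM Concentrations, µM (>= 4 distinct values).
#' @param noise A [noise_spec()].
#' @param n Number of replicates.
#' @return A data.frame with columns `conc_uM`, `response`, `replicate`.
#' @export
gen_dose_response <- function(p, concs_uM = c(1, 3, 5, 10, 20, 30),
                              noise = noise_spec(), n = 5) {
  stopifnot(inherits(p, "hill_params"), inherits(noise, "noise_spec"))
  stop_if(any(concs_uM < 0), "concentrations must be >= 0")
  stop_if(length(unique(concs_uM)) < 4L, "need >= 4 distinct concentrations")
  stop_if(n < 1, "n must be >= 1")
  truth <- hill_response(concs_uM, p)
  out <- data.frame(conc_uM = rep(concs_uM, n),
                    response = rep(truth, n),
                    replicate = rep(seq_len(n), each = length(concs_uM)))
  out$response <- add_noise(out$response, noise_rescale(noise, truth))
  out
}

# use the span of the noiseless curve (not of the replicated vector, which
# has the same span) to resolve fractional SD, then fix it as absolute
noise_rescale <- function(noise, truth) {
  noise_spec(sd = resolve_sd(noise, truth), seed = noise$seed)
}

#' Generate a synthetic G-V dataset
#'
#' Draws `n` replicate normalized conductance-voltage relationships from a
#' Boltzmann, double-Boltzmann or 6-state gating model, plus additive
#' Gaussian noise. For `gating6` the noiseless values are
#' [po_equilibrium()] renormalized to its maximum over the grid, matching
#' how tail-current G-V data are normalized.
#'
#' @param params A [boltzmann_params()], [double_boltzmann_params()] or
#'   [gating_params()] object (the model kind is inferred from the class).
#' @param V_grid_mV Voltage grid, mV (non-empty).
#' @param noise A [noise_spec()].
#' @param n Number of replicates.
#' @param ctx A [thermo_context()] (gating model only).
#' @return A data.frame with columns `V_mV`, `g_norm`, `replicate`.
#' @export
gen_gv <- function(params, V_grid_mV = seq(-60, 60, 10),
                   noise = noise_spec(), n = 5, ctx = thermo_context()) {
  stopifnot(inherits(noise, "noise_spec"))
  stop_if(length(V_grid_mV) == 0L, "voltage grid must be non-empty")
  stop_if(n < 1, "n must be >= 1")
  truth <- if (inherits(params, "boltzmann_params")) {
    boltzmann_gv(V_grid_mV, params)
  } else if (inherits(params, "double_boltzmann_params")) {
    double_boltzmann_gv(V_grid_mV, params)
  } else if (inherits(params, "gating_params")) {
    po <- po_equilibrium(params, V_grid_mV, ctx)
    po / max(po)
  } else stop("params must be boltzmann_params, double_boltzmann_params or gating_params",
              call. = FALSE)
  out <- data.frame(V_mV = rep(V_grid_mV, n),
                    g_norm = rep(truth, n),
                    replicate = rep(seq_len(n), each = length(V_grid_mV)))
  out$g_norm <- add_noise(out$g_norm, noise_rescale(noise, truth))
  out
}

#' Generate a synthetic tail-current decay segment
#'
#' Samples an [exp_mixture()] decay on a uniform grid with additive
#' Gaussian noise, emulating a tail current re-zeroed at its peak.
#'
#' @param m An [exp_mixture()] (the generator truth).
#' @param dt_ms Sampling interval, ms.
#' @param duration_ms Segment duration, ms. A warning is issued when the
#'   record is shorter than 5 times the slowest time constant (the slow
#'   component is then poorly constrained).
#' @param noise A [noise_spec()]; for traces, fractional SD is relative to
#'   the initial (peak) amplitude span.
#' @return A data.frame with columns `time_ms`, `current_uA`.
#' @export
gen_tail_trace <- function(m, dt_ms = 1, duration_ms = 500,
                           noise = noise_spec()) {
  stopifnot(inherits(m, "exp_mixture"), inherits(noise, "noise_spec"))
  stop_if(dt_ms <= 0 || duration_ms <= 0, "dt_ms and duration_ms must be > 0")
  if (duration_ms < 5 * max(m$taus_ms))
    warning(sprintf("duration %g ms < 5 * slowest tau (%g ms); slow component poorly constrained",
                    duration_ms, max(m$taus_ms)))
  t <- seq(0, duration_ms, by = dt_ms)
  truth <- exp_mixture_value(t, m)
  data.frame(time_ms = t,
             current_uA = add_noise(truth, noise_rescale(noise, truth)))
}

#' Generate a simulated sweep family from a protocol template
#'
#' Runs the kinetic simulator once per voltage, substituting each value
#' into the varied epoch of the template. Per-sweep noise seeds are derived
#' deterministically from the configured seed (`seed + sweep index`).
#'
#' @param r A [rate_params()].
#' @param template A [voltage_protocol()].
#' @param varied_epoch Index of the epoch whose voltage is varied.
#' @param voltages_mV One voltage per sweep, mV.
#' @param cfg A [sim_config()].
#' @param ctx A [thermo_context()].
#' @param condition Condition label.
#' @return A [sweep_family()].
#' @export
gen_protocol_family <- function(r, template, varied_epoch, voltages_mV,
                                cfg = sim_config(), ctx = thermo_context(),
                                condition = "sim") {
  stopifnot(inherits(template, "voltage_protocol"))
  stop_if(varied_epoch < 1 || varied_epoch > nrow(template$epochs),
          "varied_epoch out of range")
  stop_if(length(voltages_mV) == 0L, "need at least one voltage")
  traces <- lapply(seq_along(voltages_mV), function(i) {
    prot <- template
    prot$epochs$voltage_mV[varied_epoch] <- voltages_mV[i]
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    simulate_protocol(r, prot, cfg_i, ctx, condition = condition)
  })
  sweep_family(traces, voltages_mV, varied_epoch, condition)
}

#' Generate an exponential-decay tail family
#'
#' Builds a return-potential sweep family whose tail decays are exponential
#' mixtures with voltage-dependent time constants (log-linearly
#' interpolated between anchor values), embedded in a minimal two-epoch
#' protocol (activating step, then the return step). This emulates
#' deactivation experiments whose time constants are known, independently
#' of the kinetic simulator.
#'
#' @param tau_anchors A data.frame with columns `V_mV` and `tau_ms` (>= 2
#'   rows) through which `log(tau)` is interpolated linearly in V, or a
#'   named list of [exp_mixture()] objects keyed by voltage (used as-is).
#' @param V_ret_mV Return potentials, one per sweep.
#' @param amp_uA Tail-peak amplitude, µA.
#' @param dt_ms,return_ms Sampling interval and return-epoch duration, ms.
#' @param noise A [noise_spec()]; per-sweep seeds are `seed + sweep index`.
#' @param condition Condition label.
#' @return A [sweep_family()] with the tail in epoch 2.
#' @export
gen_tail_family <- function(tau_anchors, V_ret_mV = seq(-140, -40, 10),
                            amp_uA = 1, dt_ms = 0.5, return_ms = 400,
                            noise = noise_spec(sd = 0), condition = "tails") {
  mix_for <- if (is.data.frame(tau_anchors)) {
    stop_if(nrow(tau_anchors) < 2L, "need >= 2 tau anchors")
    function(v) {
      lt <- stats::approx(tau_anchors$V_mV, log(tau_anchors$tau_ms),
                          xout = v, rule = 2)$y
      exp_mixture(exp(lt), amp_uA)
    }
  } else {
    function(v) {
      m <- tau_anchors[[as.character(v)]]
      stop_if(is.null(m), "no exp_mixture supplied for V = %g", v)
      m
    }
  }
  act_ms <- 50
  traces <- lapply(seq_along(V_ret_mV), function(i) {
    v <- V_ret_mV[i]
    m <- mix_for(v)
    prot <- voltage_protocol(list(c(act_ms, 40), c(return_ms, v)),
                             sample_interval_ms = dt_ms,
                             holding_mV = -70, holding_ms = 0)
    t <- seq(0, act_ms + return_ms - dt_ms, by = dt_ms)
    in_tail <- t >= act_ms
    cur <- numeric(length(t))
    cur[!in_tail] <- exp_mixture_value(0, m)      # activated plateau
    cur[in_tail] <- exp_mixture_value(t[in_tail] - act_ms, m)
    ns <- noise_spec(sd = resolve_sd(noise, cur), seed = noise$seed + i)
    cur <- add_noise(cur, ns)
    current_trace(t, ifelse(in_tail, v, 40), cur,
                  metadata = list(protocol = prot, condition = condition,
                                  seed = ns$seed, truth = m))
  })
  sweep_family(traces, V_ret_mV, varied_epoch = 2L, condition = condition)
}

#' Generate a complete synthetic study bundle
#'
#' One-command synthetic stand-in for the whole voltage-clamp study: writes
#' concentration-response, G-V and tail-current CSV fixtures for the
#' channel archetypes in [herg_conditions()] (split control/RPR, N-del,
#' C-del, D540K), plus a JSON manifest listing every file with the seed
#' that produced it. Per-file seeds are derived deterministically from the
#' master seed as `master_seed + file index`.
#'
#' @param out_dir Output directory (created if needed).
#' @param master_seed Integer master seed.
#' @param noise_frac Noise SD as a fraction of each dataset's signal span.
#' @param ctx A [thermo_context()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
gen_study_bundle <- function(out_dir, master_seed = 1L, noise_frac = 0.03,
                             ctx = thermo_context()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cond <- herg_conditions()
  files <- list()
  idx <- 0L
  next_seed <- function() {
    idx <<- idx + 1L
    master_seed + idx
  }
  put <- function(df, name, seed, kind, truth) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files[[length(files) + 1L]] <<- list(file = name, kind = kind,
                                         seed = seed, truth = truth)
    path
  }

  for (nm in names(cond$hill)) {
    sd_seed <- next_seed()
    h <- cond$hill[[nm]]
    df <- gen_dose_response(h$params,
                            noise = noise_spec(frac_span = noise_frac,
                                               seed = sd_seed),
                            n = h$replicates)
    put(df, paste0("dose_", nm, ".csv"), sd_seed, "dose_response",
        unclass(h$params))
  }
  for (nm in names(cond$gating)) {
    sd_seed <- next_seed()
    g <- cond$gating[[nm]]
    df <- gen_gv(g$params, seq(-60, 60, 10),
                 noise = noise_spec(frac_span = noise_frac, seed = sd_seed),
                 n = g$replicates, ctx = ctx)
    put(df, paste0("gv_", nm, ".csv"), sd_seed, "gv_gating6",
        unclass(g$params))
  }
  for (nm in names(cond$d540k_gv)) {
    sd_seed <- next_seed()
    dk <- cond$d540k_gv[[nm]]
    p <- calibrate_double_boltzmann(dk$v05_hyp_mV, dk$k_hyp_mV,
                                    dk$v05_dep_mV, dk$k_dep_mV, dk$trough)
    df <- gen_gv(p, seq(-140, 40, 10),
                 noise = noise_spec(sd = 0.02, seed = sd_seed),
                 n = dk$replicates, ctx = ctx)
    put(df, paste0("gv_d540k_", nm, ".csv"), sd_seed, "gv_double_boltzmann",
        unclass(p))
  }
  for (arch in names(cond$deactivation)) {
    sets <- cond$deactivation[[arch]]
    for (cn in setdiff(names(sets), "replicates")) {
      for (vn in names(sets[[cn]])) {
        sd_seed <- next_seed()
        m <- sets[[cn]][[vn]]
        dur <- max(200, 5 * max(m$taus_ms))
        df <- gen_tail_trace(m, dt_ms = max(0.5, dur / 2000),
                             duration_ms = dur,
                             noise = noise_spec(frac_span = noise_frac,
                                                seed = sd_seed))
        put(df, sprintf("tail_%s_%s_%smV.csv", arch, cn, vn), sd_seed,
            "tail_trace",
            list(taus_ms = m$taus_ms, amps = m$amps, offset = m$offset))
      }
    }
  }
  manifest <- list(master_seed = master_seed, noise_frac = noise_frac,
                   temperature_K = ctx$temperature_K,
                   package_version = as.character(utils::packageVersion("hergate")),
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
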