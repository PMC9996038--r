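# File formats: long-format trace CSV, parameter / protocol JSON.
# Trace CSV dialect: columns sweep_id, time_ms, voltage_mV, current_uA;
# header required; UTF-8; "." decimal separator; within a sweep time_ms is
# strictly increasing and uniformly spaced.

TRACE_COLUMNS <- c("sweep_id", "time_ms", "voltage_mV", "current_uA")

#' Read current traces from CSV
#'
#' Reads the package's long-format trace dialect and validates it: all four
#' columns present, and within every sweep a strictly increasing, uniformly
#' spaced time axis. Violations produce errors naming the offending sweep.
#'
#' @param path CSV file path.
#' @return A named list of [current_trace()] objects, one per `sweep_id`.
#' @export
read_trace_csv <- function(path) {
  stop_if(!file.exists(path), "file not found: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  stop_if(nrow(df) == 0L, "empty trace file: %s", path)
  missing_cols <- setdiff(TRACE_COLUMNS, names(df))
  stop_if(length(missing_cols) > 0L, "missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  out <- list()
  for (sid in unique(df$sweep_id)) {
    sub <- df[df$sweep_id == sid, , drop = FALSE]
    dt <- diff(sub$time_ms)
    stop_if(any(dt <= 0),
            "sweep '%s': time_ms not strictly increasing", sid)
    stop_if(length(dt) > 0 && max(abs(dt - dt[1])) > 1e-6 * dt[1] + 1e-9,
            "sweep '%s': mixed sampling intervals", sid)
    out[[as.character(sid)]] <- current_trace(
      sub$time_ms, sub$voltage_mV, sub$current_uA,
      metadata = list(sweep_id = as.character(sid), source = path))
  }
  out
}

#' Write current traces to CSV
#'
#' Inverse of [read_trace_csv()]: numbers are written with 9 significant
#' digits, so a write/read round trip reproduces a trace to within 1e-9
#' relative.
#'
#' @param traces A [current_trace()], a list of them (names become sweep
#'   ids), or a [sweep_family()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "current_trace")) traces <- list(sweep1 = traces)
  if (inherits(traces, "sweep_family")) {
    nm <- paste0("V", traces$varied_voltage_mV)
    traces <- stats::setNames(traces$traces, nm)
  }
  stop_if(length(traces) == 0L, "no traces to write")
  ids <- names(traces) %||% paste0("sweep", seq_along(traces))
  ids[ids == ""] <- paste0("sweep", which(ids == ""))
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    stopifnot(inherits(tr, "current_trace"))
    data.frame(sweep_id = ids[i],
               time_ms = signif(tr$time_ms, 9),
               voltage_mV = signif(tr$voltage_mV, 9),
               current_uA = signif(tr$current_uA, 9))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- parameter JSON --------------------------------------------------------

PARAM_CLASSES <- c(gating = "gating_params", boltzmann = "boltzmann_params",
                   double_boltzmann = "double_boltzmann_params",
                   hill = "hill_params", exp_mixture = "exp_mixture")

#' Write model parameters to JSON
#'
#' Flat JSON object with keys matching the parameter field names, plus a
#' `model` tag for round-tripping.
#'
#' @param p A parameter object ([gating_params()], [boltzmann_params()],
#'   [double_boltzmann_params()], [hill_params()] or [exp_mixture()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(p, path) {
  model <- names(PARAM_CLASSES)[vapply(PARAM_CLASSES, inherits,
                                       logical(1), x = p)]
  stop_if(length(model) != 1L, "unknown parameter object")
  obj <- c(list(model = model), unclass(p))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path JSON file written by [write_params_json()], or a flat object
#'   whose keys identify the model (e.g. `{"K0":...,"z1":...}`).
#' @return The corresponding parameter object.
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- obj$model %||% {
    if (all(c("K0", "z1", "Ko0", "z2") %in% names(obj))) "gating"
    else if (all(c("Amax", "Amin") %in% names(obj))) "hill"
    else if ("v05_hyp_mV" %in% names(obj)) "double_boltzmann"
    else if ("v05_mV" %in% names(obj)) "boltzmann"
    else if ("taus_ms" %in% names(obj)) "exp_mixture"
    else stop("cannot identify parameter model in ", path, call. = FALSE)
  }
  switch(model,
         gating = gating_params(obj$K0, obj$z1, obj$Ko0, obj$z2),
         boltzmann = boltzmann_params(obj$v05_mV, obj$k_mV),
         double_boltzmann = double_boltzmann_params(
           obj$v05_hyp_mV, obj$k_hyp_mV, obj$A_hyp,
           obj$v05_dep_mV, obj$k_dep_mV, obj$A_dep, obj$offset),
         hill = hill_params(obj$Amax, obj$Amin, obj$ec50_uM, obj$nH),
         exp_mixture = exp_mixture(obj$taus_ms, obj$amps, obj$offset),
         stop("unknown model tag: ", model, call. = FALSE))
}

#' Read a voltage protocol from JSON
#'
#' Schema: `{"holding_mV": -70, "holding_ms": 500,
#' "epochs": [[4000, 60], [2000, -40]], "sample_interval_ms": 1}`.
#'
#' @param path JSON file path.
#' @return A [voltage_protocol()].
#' @export
read_protocol_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("holding_mV", "epochs", "sample_interval_ms"))
    stop_if(is.null(obj[[k]]), "protocol JSON missing '%s'", k)
  ep <- obj$epochs
  if (is.matrix(ep)) ep <- lapply(seq_len(nrow(ep)), function(i) ep[i, ])
  voltage_protocol(ep, sample_interval_ms = obj$sample_interval_ms,
                   holding_mV = obj$holding_mV,
                   holding_ms = obj$holding_ms %||% 100)
}

#' Write a voltage protocol to JSON
#'
#' @param prot A [voltage_protocol()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protocol_json <- function(prot, path) {
  stopifnot(inherits(prot, "voltage_protocol"))
  obj <- list(holding_mV = prot$holding_mV, holding_ms = prot$holding_ms,
              epochs = lapply(seq_len(nrow(prot$epochs)), function(i)
                c(prot$epochs$duration_ms[i], prot$epochs$voltage_mV[i])),
              sample_interval_ms = prot$sample_interval_ms)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
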