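# Fit-result container shared by all fitters.

new_fit_result <- function(model_tag, params, rss, n_points, converged,
                           se = NULL, flags = character(), extra = list()) {
  structure(list(model_tag = model_tag, params = params, rss = rss,
                 n_points = n_points, converged = isTRUE(converged),
                 se = se, flags = flags, extra = extra),
            class = "herg_fit")
}

#' @export
print.herg_fit <- function(x, ...) {
  cat(sprintf("<herg_fit:%s> %s (rss = %.4g, n = %d%s)\n",
              x$model_tag,
              if (x$converged) "converged" else "NOT converged",
              x$rss, x$n_points,
              if (length(x$flags)) paste0("; flags: ",
                                          paste(x$flags, collapse = ", "))
              else ""))
  pl <- unclass(x$params)
  pl <- pl[vapply(pl, is.numeric, logical(1))]
  for (nm in names(pl)) {
    se_txt <- if (!is.null(x$se) && nm %in% names(x$se) && is.finite(x$se[[nm]]))
      sprintf(" +/- %.3g", x$se[[nm]]) else ""
    cat(sprintf("  %-10s %s%s\n", nm,
                paste(signif(pl[[nm]], 5), collapse = ", "), se_txt))
  }
  invisible(x)
}

#' Extract fitted parameters
#'
#' @param object A `herg_fit`.
#' @param ... Unused.
#' @return The model-specific parameter object (e.g. [hill_params()],
#'   [exp_mixture()]).
#' @export
coef.herg_fit <- function(object, ...) object$params

#' Serialize a fit result to JSON
#'
#' Writes model tag, parameter record, residual sum of squares, number of
#' points, convergence flag and per-parameter standard errors.
#'
#' @param fit A `herg_fit`.
#' @param path Output file path; `NULL` returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
write_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "herg_fit"))
  obj <- list(model_tag = fit$model_tag,
              params = unclass(fit$params),
              rss = fit$rss, n_points = fit$n_points,
              converged = fit$converged,
              se = as.list(fit$se),
              flags = as.list(fit$flags),
              extra = fit$extra[!vapply(fit$extra, is.function, logical(1))])
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(as.character(json), path)
  invisible(path)
}

# bounded Levenberg-Marquardt with SE extraction; resid_fn(par) -> residuals
lm_least_squares <- function(par, resid_fn, lower = NULL, upper = NULL) {
  n <- length(par)
  lower <- lower %||% rep(-Inf, n)
  upper <- upper %||% rep(Inf, n)
  fit <- try(minpack.lm::nls.lm(
    par = par, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14, gtol = 1e-14)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(par = par, rss = Inf, converged = FALSE, se = rep(NA_real_, n)))
  }
  se <- rep(NA_real_, n)
  sm <- try(summary(fit), silent = TRUE)
  if (!inherits(sm, "try-error"))
    se <- tryCatch(sm$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, n))
  list(par = coef(fit), rss = fit$deviance,
       converged = fit$info %in% 1:4, se = se, info = fit$info)
}

# corrected Akaike criterion for a Gaussian least-squares fit with k free
# parameters (+1 for the noise variance)
aicc_from_rss <- function(rss, n, k) {
  k <- k + 1
  n * log(rss / n) + 2 * k + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
}
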