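# Internal helpers shared across modules.

#' @noRd
stop_if <- function(cond, ..., call. = FALSE) {
  if (isTRUE(cond)) stop(sprintf(...), call. = call.)
  invisible(NULL)
}

#' @noRd
check_number <- function(x, name, finite = TRUE) {
  stop_if(!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)),
          "`%s` must be a single finite number", name)
  invisible(x)
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded generators do not perturb the session
#' random stream.
#' @noRd
with_preserved_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' log-sum-exp, robust to -Inf entries
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
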