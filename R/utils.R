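# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "desynctrl_error")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded package internals do not
#' perturb the caller's random stream. A `NULL` seed leaves the stream alone.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a finite numeric scalar", name), "invalid_parameter")
  if (x < lower || x > upper)
    abort(sprintf("`%s` = %g out of range [%g, %g]", name, x, lower, upper),
          "invalid_parameter")
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    abort(sprintf("`%s` must be an integer", name), "invalid_parameter")
  if (x < lower)
    abort(sprintf("`%s` = %d below minimum %d", name, as.integer(x), lower),
          "invalid_parameter")
  as.integer(x)
}

# wrap angles into [0, 2*pi)
wrap_phase <- function(phi) phi %% (2 * pi)

# circular distance on the torus, result in [0, pi]
circ_dist <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}
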