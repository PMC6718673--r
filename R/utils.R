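# Shared internal helpers: classed errors and local RNG scoping.

stop_twindff <- function(message, type) {
  abort(message, class = c(paste0("twindff_error_", type), "twindff_error"))
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards. All generators in the package take
#' explicit seeds and route through this helper, so no function mutates
#' global random state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_twindff("`seed` must be a single finite integer.", "config")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# scalar checks used by the config constructors
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_twindff(sprintf("`%s` must be a single finite number.", name),
                 "config")
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    stop_twindff(sprintf("`%s` must be in [%s, %s]%s (got %g).",
                         name, format(lower), format(upper),
                         if (allow_zero) "" else ", nonzero", x),
                 "config")
  }
  x
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) {
    stop_twindff(sprintf("`%s` must be a whole number (got %g).", name, x),
                 "config")
  }
  as.integer(x)
}
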