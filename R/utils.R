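# Shared condition classes and small helpers.

abort_config <- function(message, ...) {
  rlang::abort(message, class = c("flowramp_config_error", "flowramp_error"), ...)
}

abort_data <- function(message, ...) {
  rlang::abort(message, class = c("flowramp_data_error", "flowramp_error"), ...)
}

abort_schedule <- function(message, ...) {
  rlang::abort(message,
    class = c("flowramp_schedule_error", "flowramp_data_error", "flowramp_error"), ...)
}

abort_parameter <- function(message, ...) {
  rlang::abort(message,
    class = c("flowramp_parameter_error", "flowramp_config_error", "flowramp_error"), ...)
}

abort_convergence <- function(message, ...) {
  rlang::abort(message, class = c("flowramp_convergence_error", "flowramp_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    abort_config(sprintf("`%s` = %g is outside the allowed range [%g, %g].",
      name, x, lower, upper))
  }
  invisible(x)
}

#' @importFrom rlang hash
config_hash <- function(x) substr(rlang::hash(x), 1, 12)

# Gas constant, J mol^-1 K^-1
GAS_CONSTANT <- 8.314

celsius_to_kelvin <- function(temp_c) temp_c + 273.15

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
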