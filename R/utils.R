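# internal helpers shared across modules

# run code with a private RNG stream; the caller's .Random.seed is untouched
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stop_format <- function(msg, ...) abort(sprintf(msg, ...), class = "ebpr_format_error")
stop_validation <- function(msg, ...) abort(sprintf(msg, ...), class = "ebpr_validation_error")
stop_config <- function(msg, ...) abort(sprintf(msg, ...), class = "ebpr_config_error")

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_validation("`%s` must be a single finite number in [%s, %s]", name, lower, upper)
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stop_validation("`%s` must be an integer", name)
  invisible(as.integer(x))
}

#' @keywords internal
#' @noRd
`%||%` <- rlang::`%||%`
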