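# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

#' Evaluate code under a fixed RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so that simulation helpers never disturb
#' an analysis script's own random stream.  A `NULL` seed leaves the stream
#' untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
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

#' Derive a per-stage seed from a master seed
#'
#' The pipeline takes a single master seed and derives a distinct,
#' reproducible seed for each stochastic stage.  Results stay below
#' 2^31 - 1 so they are always valid R integer seeds.
#'
#' @param seed Master seed (single number).
#' @param stage Integer stage index.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, 1)
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(stage) * 1299721) %%
               2147483647)
}

# single finite number in an open/closed range
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_(name, " must be a single finite number")
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_(name, " must be in ", if (open_lower) "(" else "[", lower, ", ",
          upper, if (open_upper) ")" else "]")
  }
  invisible(x)
}
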