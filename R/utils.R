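#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  force(expr)
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                      strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  }
  lo_ok <- if (strict_min) x > min else x >= min
  if (!lo_ok || x > max) {
    stop(sprintf("`%s` = %g is out of range [%s, %g]", name, x,
                 if (strict_min) paste0(">", min) else min, max),
         call. = FALSE)
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 1L) {
  stop_if_not_scalar_number(x, name, min = min)
  if (x != round(x)) {
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
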