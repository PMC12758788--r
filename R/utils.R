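# shared helpers

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so no package function perturbs the global stream.
with_seed <- function(seed, expr) {
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
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) stop(..., call. = FALSE)

check_finite <- function(x, what) {
  if (any(!is.finite(x))) stop_data(what, " contains NaN or infinite entries")
  invisible(x)
}
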