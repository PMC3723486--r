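#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a given seed without disturbing the caller's RNG
# stream. seed = NULL means "use the current stream" (no restore).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

stop_if_not_scalar_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) {
    bounds <- if (open) "(0, 1)" else "[0, 1]"
    stop(sprintf("`%s` must be a single value in %s", name, bounds),
         call. = FALSE)
  }
  invisible(x)
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
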