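# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards so seeded calls do not perturb callers.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic 31-bit seed derived from a master seed and a label, so every
# cell of a sweep gets its own reproducible stream.  Doubles are exact far
# beyond 2^31, so the modular arithmetic below is exact.
derive_seed <- function(master, ...) {
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "|")
  h <- as.double(master %% 2147483647)
  for (cp in utf8ToInt(label)) h <- (h * 131 + cp) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

check_series <- function(x, min_length = 2L, what = "time series") {
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  if (length(x) < min_length)
    stop(what, " must have length >= ", min_length, call. = FALSE)
  invisible(x)
}

check_not_constant <- function(x, what = "time series") {
  if (stats::sd(x) == 0)
    stop("degenerate input: ", what, " is constant (zero variance)",
         call. = FALSE)
  invisible(x)
}

# Trapezoidal integral of y over abscissa x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
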