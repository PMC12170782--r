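# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs user RNG.
with_local_seed <- function(seed, expr) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a per-item 31-bit seed from a base seed; keeps values < 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 7919) %% 2147483629 + 1)
}

# Trapezoid quadrature weights for a (possibly non-uniform) time axis, so that
# sum(w * y) == pracma::trapz(t, y). Used to integrate many curves at once.
trapz_weights <- function(t) {
  n <- length(t)
  stopifnot(n >= 2)
  dt <- diff(t)
  w <- numeric(n)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-(n - 1)] + dt[-1]) / 2
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vlog <- function(...) {
  if (isTRUE(getOption("gbmphen.verbose", FALSE))) message(...)
}
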