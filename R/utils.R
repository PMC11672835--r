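# Internal helpers shared across modules.

#' Derive a reproducible sub-seed for a named random stream
#'
#' All randomness in the simulator flows from one user-supplied seed; each
#' channel/stream gets its own deterministic sub-seed so that adding or
#' reordering streams never perturbs the others.
#'
#' @param seed integer master seed.
#' @param stream character stream label, e.g. `"ecg/human"`.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @keywords internal
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.double(seed %% m)
  for (k in utf8ToInt(stream)) {
    h <- (h * 31 + k) %% m
  }
  # one multiplicative scramble to decorrelate consecutive seeds
  as.integer((h * 48271) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#' @keywords internal
#' @noRd
ds_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "dyadsync_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

assert_scalar_in <- function(x, name, lo, hi, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    ds_stop("dyadsync_parameter_error", "'%s' must be a single number", name)
  }
  ok <- if (open) x > lo && x < hi else x >= lo && x <= hi
  if (!ok) {
    ds_stop("dyadsync_parameter_error",
            "'%s' = %g outside %s%g, %g%s", name, x,
            if (open) "(" else "[", lo, hi, if (open) ")" else "]")
  }
  invisible(x)
}

# Linear interpolation with NA masking outside a maximum gap.  Samples of `y`
# at times `t` are interpolated onto `t_out`; output points whose bracketing
# input samples are more than `max_gap` seconds apart become NA.
interp_with_gaps <- function(t, y, t_out, max_gap = 2) {
  if (length(t) < 2L) return(rep(NA_real_, length(t_out)))
  out <- approx(t, y, xout = t_out, rule = 1)$y
  gaps <- diff(t)
  if (any(gaps > max_gap)) {
    idx <- findInterval(t_out, t)
    inside <- idx >= 1L & idx < length(t)
    bad <- inside & gaps[pmax(idx, 1L)] > max_gap
    out[bad] <- NA_real_
  }
  out
}
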