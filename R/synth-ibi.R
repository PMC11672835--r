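# Interbeat-interval and ECG simulation.

#' Simulate an interbeat-interval series with target SDNN and RMSSD
#'
#' Generates a stationary AR(1) process in IBI space around the mean interval
#' `60000 / mean_hr` ms.  The lag-1 autocorrelation is chosen from the AR(1)
#' identity `RMSSD^2 = 2 * Var * (1 - phi)`, so one (SDNN, RMSSD) pair is
#' targeted exactly in expectation.
#'
#' @param mean_hr mean heart rate, beats/min.
#' @param sdnn target standard deviation of the IBIs, ms.
#' @param rmssd target root-mean-square of successive IBI differences, ms.
#' @param duration minimum cumulative duration to cover, s.
#' @param seed integer seed.
#' @return Numeric vector of IBI values (ms) whose cumulative sum reaches at
#'   least `duration` seconds.
#' @examples
#' ibi <- simulate_ibi_series(75, sdnn = 50, rmssd = 40, duration = 300, seed = 1)
#' sd(ibi)   # close to 50
#' @export
simulate_ibi_series <- function(mean_hr, sdnn, rmssd, duration, seed = 1L) {
  assert_scalar_in(mean_hr, "mean_hr", 20, 300, open = TRUE)
  assert_scalar_in(sdnn, "sdnn", 0, Inf)
  assert_scalar_in(rmssd, "rmssd", 0, Inf)
  assert_scalar_in(duration, "duration", 0, Inf, open = TRUE)
  base <- 60000 / mean_hr
  n <- ceiling(duration * 1000 / base) + 10L
  if (sdnn == 0) {
    if (rmssd != 0) {
      ds_stop("dyadsync_parameter_error",
              "rmssd must be 0 when sdnn is 0 (zero-variance process)")
    }
    return(rep(base, n))
  }
  phi <- ibi_phi(sdnn, rmssd)
  withr_seed(seed, {
    innov_sd <- sdnn * sqrt(1 - phi^2)
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sdnn)
    eps <- rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) x[i] <- phi * x[i - 1] + eps[i - 1]
    base + x
  })
}

# AR(1) coefficient implied by (sdnn, rmssd); errors when outside (-1, 1).
ibi_phi <- function(sdnn, rmssd) {
  phi <- 1 - rmssd^2 / (2 * sdnn^2)
  if (phi <= -1 || phi >= 1) {
    ds_stop("dyadsync_parameter_error",
            paste0("infeasible (sdnn = %g, rmssd = %g): implied AR(1) ",
                   "coefficient phi = %g outside (-1, 1); requires ",
                   "0 < rmssd < 2 * sdnn"), sdnn, rmssd, phi)
  }
  phi
}

# Evaluate a block with a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Render a raw ECG waveform from an IBI sequence
#'
#' Each beat is drawn as three Gaussian bumps (P, R, T) with a narrow
#' dominant R wave of 1 mV, plus additive Gaussian noise.  The true R-wave
#' sample times are returned alongside the trace so that detector recovery
#' can be scored exactly.
#'
#' @param ibi IBI sequence, ms.
#' @param fs sampling rate, Hz (>= 100 so the QRS is resolvable).
#' @param seed integer seed for the additive noise.
#' @param noise_sd noise standard deviation, mV.
#' @param t0 time of the first R peak, s.
#' @return List with `t` (s), `ecg` (mV), `r_peak_times` (s), `fs`.
#' @export
render_ecg <- function(ibi, fs, seed = 1L, noise_sd = 0.02, t0 = 0.5) {
  if (fs < 100) {
    ds_stop("dyadsync_parameter_error",
            "fs = %g Hz too low to resolve the QRS complex (need >= 100 Hz)", fs)
  }
  if (any(ibi <= 0)) ds_stop("dyadsync_parameter_error", "non-positive IBI")
  r_times <- t0 + c(0, cumsum(ibi[-length(ibi)])) / 1000
  dur <- r_times[length(r_times)] + 0.6
  t <- seq(0, dur, by = 1 / fs)
  ecg <- numeric(length(t))
  # P, R, T bumps: (offset before R in fraction of local IBI or fixed s,
  # amplitude mV, width s)
  add_bump <- function(centers, amp, width) {
    for (ci in centers) {
      lo <- max(1L, floor((ci - 4 * width) * fs) + 1L)
      hi <- min(length(t), ceiling((ci + 4 * width) * fs) + 1L)
      if (lo > hi) next
      seg <- lo:hi
      ecg[seg] <<- ecg[seg] + amp * exp(-((t[seg] - ci)^2) / (2 * width^2))
    }
  }
  add_bump(r_times, 1.0, 0.010)          # R: 1 mV, 10 ms
  add_bump(r_times - 0.16, 0.12, 0.025)  # P
  add_bump(r_times + 0.22, 0.25, 0.045)  # T
  if (noise_sd > 0) {
    ecg <- ecg + withr_seed(seed, rnorm(length(t), 0, noise_sd))
  }
  list(t = t, ecg = ecg, r_peak_times = r_times, fs = fs)
}
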