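# EDA, skin-temperature and accelerometer channel simulation.

#' Simulate an electrodermal activity channel
#'
#' Tonic ramp plus a sum of bi-exponential (Bateman-style) skin conductance
#' response kernels at the requested event times, plus Gaussian noise.
#'
#' @param duration length, s.
#' @param fs sampling rate, Hz.
#' @param scr_times SCR event (onset) times, s.
#' @param scr_amplitudes peak amplitude of each SCR, µS (non-negative).
#' @param tonic_level baseline skin conductance level, µS.
#' @param drift tonic drift, µS/min.
#' @param seed integer seed.
#' @param noise_sd noise SD, µS.
#' @return List with `t` (s), `eda` (µS), `fs`.
#' @export
simulate_eda <- function(duration, fs = 4, scr_times = numeric(),
                         scr_amplitudes = numeric(), tonic_level = 2,
                         drift = 0, seed = 1L, noise_sd = 0.005) {
  if (length(scr_amplitudes) == 1L && length(scr_times) > 1L) {
    scr_amplitudes <- rep(scr_amplitudes, length(scr_times))
  }
  if (length(scr_times) != length(scr_amplitudes)) {
    ds_stop("dyadsync_parameter_error", "scr_times/scr_amplitudes length mismatch")
  }
  if (any(scr_amplitudes < 0)) {
    ds_stop("dyadsync_parameter_error", "negative SCR amplitude")
  }
  t <- seq(0, duration, by = 1 / fs)
  eda <- tonic_level + drift / 60 * t
  eda <- eda + eda_phasic(t, scr_times, scr_amplitudes)
  if (noise_sd > 0) eda <- eda + withr_seed(seed, rnorm(length(t), 0, noise_sd))
  list(t = t, eda = eda, fs = fs)
}

# Bateman kernel phasic component, scaled so each event's peak equals its
# stated amplitude.  tau_rise = 0.75 s, tau_decay = 2 s (fast SCR shape).
eda_phasic <- function(t, scr_times, scr_amplitudes,
                       tau_rise = 0.75, tau_decay = 2) {
  ph <- numeric(length(t))
  if (!length(scr_times)) return(ph)
  # normalizing peak of exp(-x/td) - exp(-x/tr)
  tpk <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  pk <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  for (k in seq_along(scr_times)) {
    dt <- t - scr_times[k]
    on <- dt >= 0
    ph[on] <- ph[on] + scr_amplitudes[k] / pk *
      (exp(-dt[on] / tau_decay) - exp(-dt[on] / tau_rise))
  }
  ph
}

#' Simulate a skin temperature channel
#'
#' Slow linear drift from a baseline plus low-amplitude noise.
#'
#' @param duration s; @param fs Hz; @param baseline °C; @param drift °C/min.
#' @param seed integer seed; @param noise_sd °C.
#' @return List with `t`, `st`, `fs`.
#' @export
simulate_st <- function(duration, fs = 4, baseline = 31, drift = 0.05,
                        seed = 1L, noise_sd = 0.01) {
  t <- seq(0, duration, by = 1 / fs)
  st <- baseline + drift / 60 * t
  if (noise_sd > 0) st <- st + withr_seed(seed, rnorm(length(t), 0, noise_sd))
  list(t = t, st = st, fs = fs)
}

#' Simulate a tri-axial accelerometer channel
#'
#' Gravity (9.81 m/s² on the z axis) plus band-limited dynamic noise whose
#' amplitude rises during scheduled activity bouts.  Outside bouts only a
#' small sensor noise floor remains, so gravity-removed activity metrics are
#' near zero at rest.
#'
#' @param duration s.
#' @param fs sampling rate, Hz.
#' @param schedule data.frame with columns `start`, `end` (s) and `amplitude`
#'   (m/s², dynamic-noise SD during the bout). Intervals must not overlap.
#' @param seed integer seed.
#' @param rest_sd sensor noise floor, m/s².
#' @param envelope optional function of time (s) returning a multiplicative
#'   modulation (>= 0) of the bout amplitude; used by the session generator
#'   to couple dyad activity.
#' @return List with `t`, `acc` (n x 3 matrix, m/s²), `fs`.
#' @export
simulate_accelerometer <- function(duration, fs = 32, schedule = NULL,
                                   seed = 1L, rest_sd = 0.03,
                                   envelope = NULL) {
  t <- seq(0, duration, by = 1 / fs)
  n <- length(t)
  if (!is.null(schedule) && nrow(schedule) > 0) {
    sch <- schedule[order(schedule$start), , drop = FALSE]
    if (any(sch$start < 0 | sch$end > duration | sch$end <= sch$start)) {
      ds_stop("dyadsync_parameter_error", "bout interval outside [0, duration]")
    }
    if (nrow(sch) > 1 && any(sch$start[-1] < sch$end[-nrow(sch)])) {
      ds_stop("dyadsync_parameter_error", "overlapping bout intervals")
    }
  } else {
    sch <- data.frame(start = numeric(), end = numeric(), amplitude = numeric())
  }
  amp <- rep(0, n)
  for (k in seq_len(nrow(sch))) {
    amp[t >= sch$start[k] & t < sch$end[k]] <- sch$amplitude[k]
  }
  if (!is.null(envelope)) amp <- amp * pmax(0, envelope(t))
  withr_seed(seed, {
    dyn <- matrix(rnorm(3 * n), n, 3)
    # band-limit the dynamic component (~0.5-8 Hz movement band) with a
    # short smoothing kernel so bursts look like movement, not white noise
    k <- max(1L, round(fs / 16))
    if (k > 1) {
      ker <- rep(1 / k, k)
      dyn <- apply(dyn, 2, function(col)
        as.numeric(stats::filter(col, ker, sides = 2)))
      dyn[is.na(dyn)] <- 0
      dyn <- dyn * sqrt(k)  # restore unit variance after smoothing
    }
    acc <- dyn * (amp + rest_sd)
    acc[, 3] <- acc[, 3] + 9.81
    list(t = t, acc = acc, fs = fs)
  })
}
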