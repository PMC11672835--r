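# RE extraction: centered 60 s rolling window evaluated at 10 Hz.

#' Rolling-window metric series (RE) from a beat series
#'
#' At each 0.1 s tick the metric is evaluated over the beats whose closing R
#' peak lies in the centered half-open window `[t - w/2, t + w/2)`.  Ticks
#' whose window is truncated by the record bounds are computed but flagged
#' as `edge`; ticks with fewer than 2 valid IBIs are missing.
#'
#' @param beats a `beat_series`.
#' @param metric one of `"HR"`, `"IBI"`, `"SDNN"`, `"RMSSD"`.
#' @param t_start,t_end output range, s.
#' @param out_fs output rate, Hz (default 10).
#' @param window window length, s (default 60, centered).
#' @return data.frame `t`, `value`, `edge` of class `re_series` with
#'   attribute `metric`.
#' @export
rolling_re_beats <- function(beats, metric = c("HR", "IBI", "SDNN", "RMSSD"),
                             t_start, t_end, out_fs = 10, window = 60) {
  metric <- match.arg(metric)
  stopifnot(inherits(beats, "beat_series"))
  ticks <- seq(t_start, t_end, by = 1 / out_fs)
  lo <- ticks - window / 2
  hi <- ticks + window / 2
  close_t <- beats$r_peak_times[-1]
  v <- beats$valid
  ibi <- beats$ibi
  # cumulative sums over valid IBIs ordered by closing-peak time
  x <- ifelse(v, ibi, 0)
  x2 <- ifelse(v, ibi^2, 0)
  cnt <- as.numeric(v)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x2)); cn <- c(0, cumsum(cnt))
  i0 <- findInterval(lo - 1e-12, close_t)
  i1 <- findInterval(hi - 1e-12, close_t)
  n <- cn[i1 + 1L] - cn[i0 + 1L]
  s <- cs[i1 + 1L] - cs[i0 + 1L]
  s2 <- cs2[i1 + 1L] - cs2[i0 + 1L]
  mean_ibi <- ifelse(n >= 1, s / n, NA_real_)
  value <- switch(metric,
    HR = ifelse(n >= 2, 60000 / (s / n), NA_real_),
    IBI = ifelse(n >= 2, mean_ibi, NA_real_),
    SDNN = ifelse(n >= 2, sqrt(pmax(0, (s2 - s^2 / n) / (n - 1))), NA_real_),
    RMSSD = {
      # successive differences: pair j = (ibi[j], ibi[j+1]) valid if both
      # valid and adjacent; timestamped at the later closing peak
      pj <- which(head(v, -1) & tail(v, -1))
      d2 <- (ibi[pj + 1L] - ibi[pj])^2
      pt <- close_t[pj + 1L]
      cd <- c(0, cumsum(d2)); cp <- c(0, cumsum(rep(1, length(pj))))
      j0 <- findInterval(lo - 1e-12, pt)
      j1 <- findInterval(hi - 1e-12, pt)
      m <- cp[j1 + 1L] - cp[j0 + 1L]
      sd2 <- cd[j1 + 1L] - cd[j0 + 1L]
      ifelse(m >= 1 & n >= 2, sqrt(sd2 / m), NA_real_)
    })
  edge <- lo < beats$r_peak_times[1] | hi > beats$r_peak_times[length(beats$r_peak_times)]
  out <- data.frame(t = ticks, value = value, edge = edge)
  attr(out, "metric") <- metric
  class(out) <- c("re_series", "data.frame")
  out
}

#' Rolling-window IMA series (RE) from an accelerometer channel
#'
#' Time-normalized integral of the L1 modulus of the dynamic component over
#' the centered window; ticks with under half the expected samples are
#' missing.
#'
#' @param channel preprocessed `ACC3` channel (with `$dyn`).
#' @param t_start,t_end,out_fs,window as in [rolling_re_beats()].
#' @return An `re_series` data.frame (`t`, `value`, `edge`).
#' @export
rolling_re_ima <- function(channel, t_start, t_end, out_fs = 10, window = 60) {
  stopifnot(inherits(channel, "cai_channel"), channel$kind == "ACC3",
            !is.null(channel$dyn))
  ticks <- seq(t_start, t_end, by = 1 / out_fs)
  lo <- ticks - window / 2
  hi <- ticks + window / 2
  l1 <- rowSums(abs(channel$dyn))
  usable <- !channel$mask & is.finite(l1)
  x <- ifelse(usable, l1, 0)
  cs <- c(0, cumsum(x)); cn <- c(0, cumsum(as.numeric(usable)))
  tt <- channel$t
  i0 <- findInterval(lo - 1e-12, tt)
  i1 <- findInterval(hi - 1e-12, tt)
  n <- cn[i1 + 1L] - cn[i0 + 1L]
  s <- cs[i1 + 1L] - cs[i0 + 1L]
  n_exp <- window * channel$fs
  value <- ifelse(n >= 0.5 * n_exp, s / n, NA_real_)
  edge <- lo < tt[1] | hi > tt[length(tt)]
  out <- data.frame(t = ticks, value = value, edge = edge)
  attr(out, "metric") <- "IMA"
  class(out) <- c("re_series", "data.frame")
  out
}
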