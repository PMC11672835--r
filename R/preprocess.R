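# Preprocessing chain: data check / outlier masking, band-pass filtering,
# normalization.

# Physiological plausibility bounds used for the data check (per kind).
PLAUSIBILITY_BOUNDS <- list(
  EDA = c(0.01, 60),    # uS
  ST  = c(20, 42),      # degC
  ACC3 = c(-8 * 9.81, 8 * 9.81),  # m/s^2 (+-8 g per axis)
  ECG = c(-10, 10))     # mV

#' Mask implausible and spiky samples in a channel
#'
#' Samples outside per-kind physiological plausibility bounds, or failing a
#' Hampel test (1 s window, 5 MAD) for the slow channels (EDA, ST), are
#' masked — never interpolated.  ECG and accelerometer channels are checked
#' against bounds only, since R waves and movement bursts are legitimate
#' spikes.  Masking is idempotent.
#'
#' @param channel a `cai_channel` (synchronized).
#' @param hampel_k Hampel threshold in MAD units.
#' @return The channel with its mask extended; attribute `mask_fraction`
#'   reports the masked share.  Raises a quality error when more than 50% of
#'   a channel's samples are masked.
#' @export
remove_outliers <- function(channel, hampel_k = 5) {
  stopifnot(inherits(channel, "cai_channel"))
  b <- PLAUSIBILITY_BOUNDS[[channel$kind]]
  v <- channel$values
  bad <- rep(FALSE, nrow(v))
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    bad <- bad | (!is.na(x) & (x < b[1] | x > b[2]))
  }
  if (channel$kind %in% c("EDA", "ST")) {
    x <- v[, 1]
    k <- max(3L, 2L * floor(channel$fs / 2) + 1L)  # ~1 s, odd
    med <- runmed_na(x, k)
    dev <- abs(x - med)
    s <- 1.4826 * runmed_na(dev, k)
    bad <- bad | (!is.na(x) & dev > hampel_k * pmax(s, 1e-6))
  }
  mask <- channel$mask | bad
  # quality check on the artifact fraction among samples that were usable
  # coming in (pre-existing gaps, e.g. the dog's absence, are not artifacts)
  frac <- if (any(!channel$mask)) mean(bad[!channel$mask]) else 0
  if (frac > 0.5) {
    ds_stop("dyadsync_quality_error",
            "channel %s %s@%s: %.0f%% of samples masked (>50%%)",
            channel$subject_id, channel$kind, channel$placement, 100 * frac)
  }
  out <- channel
  out$mask <- mask
  attr(out, "mask_fraction") <- frac
  out
}

# runmed tolerant of NA (NAs carried through unchanged).
runmed_na <- function(x, k) {
  if (!anyNA(x)) return(as.numeric(stats::runmed(x, k, endrule = "median")))
  y <- x
  ok <- !is.na(x)
  if (sum(ok) >= k) {
    y[ok] <- as.numeric(stats::runmed(x[ok], k, endrule = "median"))
  }
  y
}

#' Butterworth filter specification
#'
#' @param low,high band edges, Hz (`0 <= low < high < fs/2`); `low = 0`
#'   yields a pure low-pass section (DC preserved, as needed for EDA and
#'   skin temperature whose epoch means are reported in physical units).
#' @param order filter order.
#' @param zero_phase forward-backward application (no phase shift).
#' @return List of class `filter_spec`.
#' @export
filter_spec <- function(low, high, order = 4, zero_phase = TRUE) {
  structure(list(low = low, high = high, order = order,
                 zero_phase = zero_phase), class = "filter_spec")
}

# Default bands per channel kind (configurable; standard physiological
# choices — the method itself fixes none).
default_filter_spec <- function(kind, fs) {
  switch(kind,
    ECG  = filter_spec(0.5, min(40, 0.45 * fs), order = 4),
    ACC3 = filter_spec(0.1, 0.4 * fs, order = 4),
    EDA  = filter_spec(0, min(1, 0.45 * fs), order = 2),
    ST   = filter_spec(0, min(0.01, 0.4 * fs), order = 2),
    ds_stop("dyadsync_parameter_error", "no default band for kind %s", kind))
}

#' Band-pass filter a channel (zero-phase Butterworth)
#'
#' Masked/NA samples are bridged by linear interpolation before filtering so
#' the IIR filter sees a finite signal; the mask is preserved so bridged
#' regions stay excluded downstream.
#'
#' @param channel a `cai_channel`.
#' @param spec a [filter_spec()]; `NULL` uses the per-kind default band.
#' @return The filtered channel.
#' @export
bandpass <- function(channel, spec = NULL) {
  stopifnot(inherits(channel, "cai_channel"))
  if (is.null(spec)) spec <- default_filter_spec(channel$kind, channel$fs)
  fs <- channel$fs
  if (!(spec$low >= 0 && spec$low < spec$high && spec$high < fs / 2)) {
    ds_stop("dyadsync_parameter_error",
            "invalid band [%g, %g] Hz for fs = %g Hz", spec$low, spec$high, fs)
  }
  bf <- if (spec$low == 0) {
    signal::butter(spec$order, spec$high / (fs / 2), type = "low")
  } else {
    signal::butter(spec$order, c(spec$low, spec$high) / (fs / 2), type = "pass")
  }
  out <- channel
  for (j in seq_len(ncol(out$values))) {
    x <- out$values[, j]
    x <- fill_na_linear(x)
    y <- if (spec$zero_phase) {
      signal::filtfilt(bf, x)
    } else {
      as.numeric(signal::filter(bf, x))
    }
    out$values[, j] <- y
  }
  out
}

fill_na_linear <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) < 2) {
    x[is.na(x)] <- if (length(ok)) x[ok[1]] else 0
    return(x)
  }
  filled <- approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
  filled
}

#' Z-score normalization within subject/session
#'
#' Used for visualization and the optional normalized DTW mode; metric
#' extraction always runs on physical units.
#'
#' @param series numeric vector (>= 2 finite values, non-constant).
#' @return The standardized series (mean 0, SD 1 over finite entries).
#' @export
normalize_z <- function(series) {
  ok <- is.finite(series)
  if (sum(ok) < 2) {
    ds_stop("dyadsync_parameter_error", "need >= 2 finite values to normalize")
  }
  s <- sd(series[ok])
  if (s == 0) {
    ds_stop("dyadsync_parameter_error",
            "constant series (sd = 0) cannot be z-scored")
  }
  (series - mean(series[ok])) / s
}

#' Closed-form Butterworth band-pass magnitude response
#'
#' `|H(f)|` for an analog-prototype Butterworth band-pass: the product of a
#' high-pass and a low-pass section of the given order.  Used to predict
#' attenuation at a frequency (an independent check on the digital filter).
#'
#' @param f frequency, Hz; @param low,high band edges, Hz; @param order order.
#' @return Gain magnitude in `[0, 1]`.
#' @export
butterworth_gain <- function(f, low, high, order) {
  hp <- 1 / sqrt(1 + (low / f)^(2 * order))
  lp <- 1 / sqrt(1 + (f / high)^(2 * order))
  hp * lp
}
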