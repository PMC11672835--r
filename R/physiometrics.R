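# Beat detection and epoch metric extraction (ME and RE forms).

SPECIES_IBI_BOUNDS <- list(human = c(300, 2000), canine = c(250, 1500))  # ms

#' Detect ECG R peaks (Pan-Tompkins style)
#'
#' Band-pass (5-15 Hz human, 5-25 Hz canine), derivative, squaring, 150 ms
#' moving-window integration and an adaptive threshold with a species
#' refractory period (200 ms human, 150 ms canine).  Peak times are refined
#' to the local ECG maximum.  Interbeat intervals outside the species
#' plausibility bounds, or deviating more than 30% from the median of the 5
#' surrounding IBIs, are flagged invalid (normal-sinus-beat proxy).
#'
#' @param channel an ECG `cai_channel`.
#' @param species `"human"` or `"canine"`.
#' @return List of class `beat_series`: `r_peak_times` (s), `ibi` (ms,
#'   `diff(peaks) * 1000`), `valid` (logical per IBI), `species`.
#' @export
detect_r_peaks <- function(channel, species = c("human", "canine")) {
  species <- match.arg(species)
  stopifnot(inherits(channel, "cai_channel"), channel$kind == "ECG")
  fs <- channel$fs
  x <- fill_na_linear(channel$values[, 1])
  band_hi <- if (species == "human") 15 else 25
  refractory <- if (species == "human") 0.200 else 0.150
  bf <- signal::butter(2, c(5, min(band_hi, 0.45 * fs)) / (fs / 2), "pass")
  xf <- signal::filtfilt(bf, x)
  d <- c(0, diff(xf)) * fs
  sq <- d^2
  w <- max(1L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  # adaptive threshold: running estimate of signal peak level
  cand <- local_maxima(integ)
  if (!length(cand)) {
    return(new_beat_series(numeric(0), species))
  }
  thr <- 0.25 * stats::quantile(integ[cand], 0.95, names = FALSE)
  peaks <- integer(0)
  spki <- stats::quantile(integ[cand], 0.95, names = FALSE)
  npki <- stats::quantile(integ[cand], 0.30, names = FALSE)
  last_t <- -Inf
  for (i in cand) {
    ti <- channel$t[i]
    if (integ[i] >= thr) {
      if (ti - last_t >= refractory) {
        peaks <- c(peaks, i)
        last_t <- ti
        spki <- 0.125 * integ[i] + 0.875 * spki
      } else if (length(peaks) && integ[i] > integ[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- i   # keep the larger within refractory
        last_t <- ti
      }
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  # refine to the local raw-ECG maximum within +-60 ms
  half <- round(0.060 * fs)
  ref <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    as.integer(lo + which.max(xf[lo:hi]) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  # drop refined duplicates closer than the refractory period
  if (length(ref) > 1) {
    keep <- c(TRUE, diff(channel$t[ref]) >= refractory)
    ref <- ref[keep]
  }
  new_beat_series(channel$t[ref], species)
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Construct a beat series from R-peak times
#'
#' Applies the IBI artifact-rejection rule (species bounds; >30% deviation
#' from the median of the 5 surrounding IBIs).
#'
#' @param r_peak_times R-peak times, s (strictly increasing).
#' @param species `"human"` or `"canine"`.
#' @return A `beat_series`.
#' @export
new_beat_series <- function(r_peak_times, species = "human") {
  if (is.unsorted(r_peak_times, strictly = TRUE)) {
    ds_stop("dyadsync_validation_error", "r_peak_times must be strictly increasing")
  }
  ibi <- diff(r_peak_times) * 1000
  b <- SPECIES_IBI_BOUNDS[[species]]
  valid <- ibi >= b[1] & ibi <= b[2]
  n <- length(ibi)
  if (n >= 3) {
    for (i in seq_len(n)) {
      nb <- setdiff(max(1, i - 2):min(n, i + 2), i)
      m <- median(ibi[nb])
      if (is.finite(m) && abs(ibi[i] - m) > 0.3 * m) valid[i] <- FALSE
    }
  }
  structure(list(r_peak_times = as.numeric(r_peak_times), ibi = ibi,
                 valid = valid, species = species), class = "beat_series")
}

#' Time-domain HRV over a window of IBIs
#'
#' SDNN is the sample standard deviation (n-1 denominator); RMSSD the root
#' mean square of successive differences over valid adjacent pairs; the
#' quotient SDNN/RMSSD is missing when RMSSD is zero.
#'
#' @param ibi IBI values, ms (already artifact-cleaned).
#' @return Named numeric `c(SDNN, RMSSD, SDNN_RMSSD)`; `NA` where
#'   insufficient beats (SDNN needs >= 2 IBIs, RMSSD >= 3 beats i.e. >= 2
#'   successive IBIs).
#' @examples
#' hrv_time_domain(c(800, 850, 790, 820))
#' @export
hrv_time_domain <- function(ibi) {
  ibi <- ibi[is.finite(ibi)]
  sdnn <- if (length(ibi) >= 2) sd(ibi) else NA_real_
  d <- diff(ibi)
  rmssd <- if (length(d) >= 1) sqrt(mean(d^2)) else NA_real_
  quot <- if (!is.na(sdnn) && !is.na(rmssd) && rmssd > 0) sdnn / rmssd else NA_real_
  c(SDNN = sdnn, RMSSD = rmssd, SDNN_RMSSD = quot)
}

#' Per-axis mean amplitude deviation and integral modulus of acceleration
#'
#' MAD per axis is `mean(|a_i - mean(a)|)`; IMA is the time-normalized
#' integral of the L1 modulus of the dynamic (gravity-removed) tri-axial
#' signal: `sum(|ax| + |ay| + |az|) * dt / T`, units m/s².
#'
#' @param acc n x 3 matrix of dynamic acceleration samples (m/s²).
#' @param fs sampling rate, Hz.
#' @return Named numeric `c(MAD_x, MAD_y, MAD_z, IMA)`.
#' @export
acc_mad_ima <- function(acc, fs) {
  acc <- as.matrix(acc)
  stopifnot(ncol(acc) == 3)
  ok <- stats::complete.cases(acc)
  if (!any(ok)) return(c(MAD_x = NA, MAD_y = NA, MAD_z = NA, IMA = NA))
  a <- acc[ok, , drop = FALSE]
  mads <- unname(apply(a, 2, function(col) mean(abs(col - mean(col)))))
  ima <- sum(abs(a)) / nrow(a)   # (sum |a| * dt) / T with dt = 1/fs, T = n/fs
  c(MAD_x = mads[1], MAD_y = mads[2], MAD_z = mads[3], IMA = ima)
}

#' Decompose EDA into tonic and phasic components and detect SCR peaks
#'
#' Tonic skin conductance level = 8 s running median; phasic = signal -
#' tonic.  An SCR peak is a local phasic maximum with an onset-to-peak rise
#' of at least `min_rise` µS within 5 s.
#'
#' @param channel an EDA `cai_channel`.
#' @param min_rise minimum onset-to-peak rise, µS.
#' @return List: `tonic`, `phasic` (vectors aligned to `channel$t`),
#'   `scr_peak_times` (s).
#' @export
eda_decompose_and_peaks <- function(channel, min_rise = 0.03) {
  stopifnot(inherits(channel, "cai_channel"), channel$kind == "EDA")
  x <- fill_na_linear(channel$values[, 1])
  fs <- channel$fs
  k <- 2L * floor(4 * fs) + 1L  # ~8 s, odd
  tonic <- runmed_na(x, min(k, 2L * floor((length(x) - 1) / 2) + 1L))
  phasic <- x - tonic
  pk <- local_maxima(phasic)
  win <- round(5 * fs)
  keep <- vapply(pk, function(i) {
    lo <- max(1L, i - win)
    trough <- min(phasic[lo:i])
    (phasic[i] - trough) >= min_rise
  }, logical(1))
  pk <- pk[keep]
  # collapse peaks closer than 1 s (one SCR can ripple)
  if (length(pk) > 1) {
    keep <- c(TRUE, diff(channel$t[pk]) >= 1)
    pk <- pk[keep]
  }
  list(tonic = tonic, phasic = phasic, scr_peak_times = channel$t[pk])
}
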