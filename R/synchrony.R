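# Interspecies physiological synchrony: mid-interaction RE slices,
# Pearson correlation and dynamic time warping.

SYNC_METRICS <- c("HR", "SDNN", "RMSSD", "IMA")

#' Extract the mid-interaction RE slice pair for one metric
#'
#' The slice is the 18-epoch (3 min, 1800 ticks at 10 Hz) half-open window
#' `[mid - 90, mid + 90)` centered on the subsession's temporal midpoint.
#' Edge-flagged ticks invalidate the slice; up to 5% missing ticks are
#' linearly interpolated, more make the slice unavailable.
#'
#' @param re_human,re_canine `re_series` data.frames covering the window.
#' @param subsession one row of the timeline (`t_start`, `t_end`).
#' @param out_fs tick rate, Hz.
#' @return List `human`, `canine` (numeric vectors of 1800 ticks), `t0`,
#'   `t1`, `metric`.
#' @export
extract_slice <- function(re_human, re_canine, subsession, out_fs = 10) {
  dur <- subsession$t_end - subsession$t_start
  if (dur < 180) {
    ds_stop("dyadsync_slice_error",
            "subsession of %g s too short for an 18-epoch slice", dur)
  }
  mid <- (subsession$t_start + subsession$t_end) / 2
  t0 <- mid - 90; t1 <- mid + 90
  take <- function(re) {
    sel <- re$t >= t0 - 1e-9 & re$t < t1 - 1e-9
    seg <- re[sel, , drop = FALSE]
    n_exp <- round(180 * out_fs)
    if (nrow(seg) != n_exp) {
      ds_stop("dyadsync_slice_error",
              "RE series does not cover the slice (%d of %d ticks)",
              nrow(seg), n_exp)
    }
    if (any(seg$edge)) {
      ds_stop("dyadsync_slice_error", "slice contains edge-flagged ticks")
    }
    miss <- !is.finite(seg$value)
    if (mean(miss) > 0.05) {
      ds_stop("dyadsync_slice_error", "slice has %.1f%% missing ticks (> 5%%)",
              100 * mean(miss))
    }
    v <- seg$value
    if (any(miss)) v <- fill_na_linear(v)
    v
  }
  list(human = take(re_human), canine = take(re_canine), t0 = t0, t1 = t1,
       metric = attr(re_human, "metric"))
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (length >= 3, non-constant).
#' @return r in `[-1, 1]`, or `NA` when either input is constant.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    ds_stop("dyadsync_parameter_error", "need >= 3 paired finite values")
  }
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  max(-1, min(1, r))
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming alignment over the full cost matrix with L1
#' local cost `|x_i - y_j|`, steps (1,0), (0,1), (1,1), no window
#' constraint, boundary-anchored path.  Distances are computed on raw
#' metric units by default; set `normalize = TRUE` to z-score both series
#' first (removes level offsets such as the canine-human heart-rate gap).
#'
#' @param x,y non-empty numeric sequences.
#' @param normalize z-score both inputs before aligning.
#' @param return_path also return the optimal warp path.
#' @return List `distance` (and `path`: data.frame `i`, `j`).
#' @export
dtw_distance <- function(x, y, normalize = FALSE, return_path = FALSE) {
  if (!length(x) || !length(y)) {
    ds_stop("dyadsync_parameter_error", "dtw: empty input sequence")
  }
  if (normalize) {
    x <- normalize_z(x)
    y <- normalize_z(y)
  }
  .dtw_core(as.numeric(x), as.numeric(y), isTRUE(return_path))
}

#' Per-interaction-subsession synchrony table for a dyad session
#'
#' For each interaction subsession and each torso metric (HR, SDNN, RMSSD
#' from the ECG; IMA from the chest/harness accelerometer), computes the
#' Pearson correlation and DTW distance (raw units, plus z-scored DTW) of
#' the mid-subsession 18-epoch RE slice pair.
#'
#' @param bundle preprocessed `cai_session`.
#' @param beats named list of `beat_series` per subject (`NULL`: detect from
#'   the ECG channels).
#' @param metrics subset of `c("HR", "SDNN", "RMSSD", "IMA")`.
#' @return data.frame `subsession, metric, pearson_r, dtw_distance, dtw_z`;
#'   unavailable slices yield `NA` rows.
#' @export
synchrony_table <- function(bundle, beats = NULL, metrics = SYNC_METRICS) {
  stopifnot(inherits(bundle, "cai_session"))
  species_of <- stats::setNames(bundle$subjects$species, bundle$subjects$id)
  hum <- bundle$subjects$id[bundle$subjects$species == "human"][1]
  can <- bundle$subjects$id[bundle$subjects$species == "canine"][1]
  beats <- beats %||% list()
  for (ch in bundle$channels) {
    if (ch$kind == "ECG" && is.null(beats[[ch$subject_id]]) &&
        ch$placement %in% c("chest", "harness")) {
      beats[[ch$subject_id]] <- detect_r_peaks(ch, species_of[[ch$subject_id]])
    }
  }
  acc_of <- function(sid) {
    for (ch in bundle$channels) {
      if (ch$kind == "ACC3" && ch$subject_id == sid &&
          ch$placement %in% c("chest", "harness")) return(ch)
    }
    NULL
  }
  tl <- bundle$timeline
  rows <- list()
  for (i in which(interaction_labels(tl$label))) {
    sub <- tl[i, ]
    for (met in metrics) {
      res <- tryCatch({
        if (met == "IMA") {
          ch_h <- acc_of(hum); ch_c <- acc_of(can)
          re_h <- rolling_re_ima(ch_h, sub$t_start, sub$t_end)
          re_c <- rolling_re_ima(ch_c, sub$t_start, sub$t_end)
        } else {
          re_h <- rolling_re_beats(beats[[hum]], met, sub$t_start, sub$t_end)
          re_c <- rolling_re_beats(beats[[can]], met, sub$t_start, sub$t_end)
        }
        sl <- extract_slice(re_h, re_c, sub)
        data.frame(subsession = sub$label, metric = met,
                   pearson_r = pearson_r(sl$human, sl$canine),
                   dtw_distance = dtw_distance(sl$human, sl$canine)$distance,
                   dtw_z = dtw_distance(sl$human, sl$canine,
                                        normalize = TRUE)$distance,
                   stringsAsFactors = FALSE)
      }, dyadsync_error = function(e) {
        data.frame(subsession = sub$label, metric = met,
                   pearson_r = NA_real_, dtw_distance = NA_real_,
                   dtw_z = NA_real_, stringsAsFactors = FALSE)
      })
      rows[[paste(i, met)]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
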