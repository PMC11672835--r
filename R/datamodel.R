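# Session data model: channels, timeline, epoch grid.

CHANNEL_KINDS <- c(ECG = "mV", ACC3 = "m/s^2", EDA = "uS", ST = "degC")
PLACEMENTS <- c("chest", "harness", "left_wrist", "right_wrist", "collar")

#' Construct a sensor channel
#'
#' @param subject_id subject identifier.
#' @param kind one of `"ECG"`, `"ACC3"`, `"EDA"`, `"ST"`.
#' @param placement device placement (chest, harness, left_wrist,
#'   right_wrist, collar).
#' @param fs nominal sampling rate, Hz.
#' @param t sample times (s, strictly increasing).
#' @param values numeric matrix, 1 column (3 for `ACC3`), physical units
#'   (mV, m/s², µS, °C).
#' @param mask optional logical vector marking samples excluded from
#'   analysis (outliers / dropouts).
#' @return Object of class `cai_channel`.
#' @export
cai_channel <- function(subject_id, kind, placement, fs, t, values,
                        mask = NULL) {
  kind <- match.arg(kind, names(CHANNEL_KINDS))
  placement <- match.arg(placement, PLACEMENTS)
  values <- as.matrix(values)
  if (length(t) != nrow(values)) {
    ds_stop("dyadsync_validation_error", "t/values length mismatch (%d vs %d)",
            length(t), nrow(values))
  }
  ncol_exp <- if (kind == "ACC3") 3L else 1L
  if (ncol(values) != ncol_exp) {
    ds_stop("dyadsync_validation_error", "%s channel needs %d value column(s)",
            kind, ncol_exp)
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    ds_stop("dyadsync_validation_error",
            "non-monotone time at row %d (t = %g)", which(dt <= 0)[1] + 1L,
            t[which(dt <= 0)[1] + 1L])
  }
  if (is.null(mask)) mask <- rep(FALSE, length(t))
  structure(list(subject_id = subject_id, kind = kind, placement = placement,
                 fs = fs, t = as.numeric(t), values = values,
                 mask = as.logical(mask), unit = CHANNEL_KINDS[[kind]]),
            class = "cai_channel")
}

#' @export
print.cai_channel <- function(x, ...) {
  cat(sprintf("<cai_channel> %s %s@%s, %d samples @ %g Hz [%s], %.1f-%.1f s\n",
              x$subject_id, x$kind, x$placement, length(x$t), x$fs, x$unit,
              min(x$t), max(x$t)))
  invisible(x)
}

#' Construct a session bundle
#'
#' One experimental day: subjects, the subsession timeline, raw channels,
#' per-rater behavior label streams and survey records.
#'
#' @param subjects data.frame with columns `id`, `species`
#'   (human/canine), `role`.
#' @param timeline data.frame with `label`, `t_start`, `t_end` (s), ordered
#'   and non-overlapping.
#' @param channels named list of [cai_channel()] objects.
#' @param behavior nested list `behavior[[rater]][[subject_id]]`: character
#'   vector with one code per second (`"-1"`, `"0"`, `"1"`, `"offscreen"`).
#' @param surveys data.frame `subject`, `timepoint`, `scale`, `value`.
#' @param meta free-form metadata list.
#' @return Object of class `cai_session`.
#' @export
cai_session <- function(subjects, timeline, channels, behavior = list(),
                        surveys = NULL, meta = list()) {
  validate_timeline(timeline)
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    stopifnot(inherits(ch, "cai_channel"))
    if (!ch$subject_id %in% subjects$id) {
      ds_stop("dyadsync_validation_error",
              "channel '%s' references unknown subject '%s'", nm, ch$subject_id)
    }
    if (min(ch$t) < min(timeline$t_start) - 1e-9 ||
        max(ch$t) > max(timeline$t_end) + 1e-9) {
      ds_stop("dyadsync_validation_error",
              "channel '%s' extends outside the session timeline", nm)
    }
  }
  structure(list(subjects = subjects, timeline = timeline,
                 channels = channels, behavior = behavior,
                 surveys = surveys, meta = meta),
            class = "cai_session")
}

#' @export
print.cai_session <- function(x, ...) {
  cat(sprintf("<cai_session> %d subjects, %d subsessions (%g s), %d channels\n",
              nrow(x$subjects), nrow(x$timeline), max(x$timeline$t_end),
              length(x$channels)))
  invisible(x)
}

validate_timeline <- function(timeline) {
  stopifnot(is.data.frame(timeline),
            all(c("label", "t_start", "t_end") %in% names(timeline)))
  if (any(timeline$t_end <= timeline$t_start)) {
    ds_stop("dyadsync_validation_error", "empty or inverted subsession")
  }
  if (nrow(timeline) > 1) {
    if (any(timeline$t_start[-1] < timeline$t_end[-nrow(timeline)] - 1e-9)) {
      ds_stop("dyadsync_validation_error", "overlapping or unordered subsessions")
    }
  }
  invisible(timeline)
}

#' Build the shared 10-second epoch grid
#'
#' Epochs are successive, non-overlapping half-open intervals
#' `[t0 + k*len, t0 + (k+1)*len)` laid out within each subsession; they never
#' straddle subsession boundaries, and a trailing partial interval shorter
#' than `epoch_len` is dropped so every epoch has identical support.
#'
#' @param timeline subsession timeline data.frame.
#' @param epoch_len epoch length, s (default 10).
#' @return data.frame with columns `subsession`, `epoch` (0-based within
#'   subsession), `t0`, `t1`; class `epoch_grid`.
#' @export
build_epoch_grid <- function(timeline, epoch_len = 10) {
  validate_timeline(timeline)
  rows <- lapply(seq_len(nrow(timeline)), function(i) {
    dur <- timeline$t_end[i] - timeline$t_start[i]
    n <- floor(dur / epoch_len)
    if (n == 0) {
      warning(sprintf("subsession %s shorter than one epoch (%g s); no epochs",
                      timeline$label[i], dur))
      return(NULL)
    }
    k <- seq_len(n) - 1L
    data.frame(subsession = timeline$label[i], epoch = k,
               t0 = timeline$t_start[i] + k * epoch_len,
               t1 = timeline$t_start[i] + (k + 1) * epoch_len,
               stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, rows)
  if (is.null(g)) {
    g <- data.frame(subsession = character(), epoch = integer(),
                    t0 = numeric(), t1 = numeric())
  }
  attr(g, "epoch_len") <- epoch_len
  class(g) <- c("epoch_grid", "data.frame")
  g
}

#' Resample all channels of a bundle onto uniform per-kind clocks
#'
#' Each channel is linearly interpolated onto a uniform grid at its nominal
#' rate anchored at the timeline origin.  Regions where the raw samples are
#' more than 2 s apart are flagged as missing (masked), never interpolated.
#' The operation is idempotent.
#'
#' @param bundle a `cai_session`.
#' @param max_gap gap threshold (s) beyond which data are treated as missing.
#' @return The bundle with resampled channels.
#' @export
synchronize <- function(bundle, max_gap = 2) {
  stopifnot(inherits(bundle, "cai_session"))
  origin <- min(bundle$timeline$t_start)
  bundle$channels <- lapply(bundle$channels, function(ch) {
    step <- 1 / ch$fs
    t_out <- seq(origin + ceiling((min(ch$t) - origin) / step) * step,
                 max(ch$t), by = step)
    vals <- matrix(NA_real_, length(t_out), ncol(ch$values))
    for (j in seq_len(ncol(ch$values))) {
      vals[, j] <- interp_with_gaps(ch$t, ch$values[, j], t_out, max_gap)
    }
    mask_in <- interp_with_gaps(ch$t, as.numeric(ch$mask), t_out, max_gap)
    mask <- is.na(vals[, 1]) | is.na(mask_in) | mask_in > 0
    cai_channel(ch$subject_id, ch$kind, ch$placement, ch$fs, t_out, vals, mask)
  })
  bundle
}
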