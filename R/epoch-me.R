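# ME extraction: average metric by 10 s epoch, tidy table form.

#' Preprocess every channel of a session bundle
#'
#' Synchronizes channels onto uniform clocks, masks outliers, and attaches
#' the filtered signal needed by each extractor: the band-passed dynamic
#' component for accelerometers (`$dyn`) and the tonic/phasic EDA
#' decomposition (`$eda_aux`).  Epoch means of EDA, ST and raw acceleration
#' are taken from the masked physical-unit samples.
#'
#' @param bundle a `cai_session`.
#' @return The bundle with preprocessed channels.
#' @export
preprocess_session <- function(bundle) {
  bundle <- synchronize(bundle)
  bundle$channels <- lapply(bundle$channels, function(ch) {
    ch <- remove_outliers(ch)
    if (ch$kind == "ACC3") {
      f <- bandpass(ch)
      ch$dyn <- f$values
    } else if (ch$kind == "EDA") {
      ch$eda_aux <- eda_decompose_and_peaks(ch)
    }
    ch
  })
  bundle
}

#' Extract the per-epoch metric table (ME)
#'
#' One row per (subsession, epoch, subject, placement, metric).  Beat
#' metrics use the beats whose R peak falls inside the epoch; HR is
#' `60000 / mean(valid IBI)`.  Epochs in which more than half of a channel's
#' samples are masked are missing for that channel's metrics.
#'
#' @param bundle preprocessed `cai_session` (see [preprocess_session()]).
#' @param grid an `epoch_grid`.
#' @param beats named list `beats[[subject_id]]` of `beat_series`; if a
#'   subject has an ECG channel and no entry here, peaks are detected with
#'   [detect_r_peaks()].
#' @return Tidy data.frame `subsession, epoch, subject, placement, metric,
#'   value`.
#' @export
epoch_me <- function(bundle, grid, beats = NULL) {
  stopifnot(inherits(bundle, "cai_session"), inherits(grid, "epoch_grid"))
  species_of <- stats::setNames(bundle$subjects$species, bundle$subjects$id)
  beats <- beats %||% list()
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df

  for (ch in bundle$channels) {
    if (ch$kind == "ECG" && is.null(beats[[ch$subject_id]])) {
      beats[[ch$subject_id]] <- detect_r_peaks(ch, species_of[[ch$subject_id]])
      attr(beats[[ch$subject_id]], "placement") <- ch$placement
    }
  }

  for (sid in names(beats)) {
    bs <- beats[[sid]]
    placement <- attr(bs, "placement") %||%
      if (species_of[[sid]] == "human") "chest" else "harness"
    add(beat_epoch_metrics(bs, grid, sid, placement))
  }

  for (ch in bundle$channels) {
    if (ch$kind == "ECG") next
    add(sample_epoch_metrics(ch, grid))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

beat_epoch_metrics <- function(bs, grid, sid, placement) {
  res <- lapply(seq_len(nrow(grid)), function(g) {
    # IBI belongs to the epoch of its closing R peak
    close_t <- bs$r_peak_times[-1]
    sel <- which(close_t >= grid$t0[g] & close_t < grid$t1[g] & bs$valid)
    ibi <- bs$ibi[sel]
    n <- length(ibi)
    mean_ibi <- if (n >= 1) mean(ibi) else NA_real_
    hr <- if (!is.na(mean_ibi)) 60000 / mean_ibi else NA_real_
    sdnn <- if (n >= 2) sd(ibi) else NA_real_
    # successive pairs require adjacent valid IBIs inside the epoch
    adj <- sel[which(diff(sel) == 1L)]
    d <- bs$ibi[adj + 1L] - bs$ibi[adj]
    rmssd <- if (n >= 3 && length(d) >= 1) sqrt(mean(d^2)) else NA_real_
    quot <- if (!is.na(sdnn) && !is.na(rmssd) && rmssd > 0) sdnn / rmssd else NA_real_
    c(HR = hr, IBI = mean_ibi, SDNN = sdnn, RMSSD = rmssd, SDNN_RMSSD = quot)
  })
  m <- do.call(rbind, res)
  data.frame(subsession = rep(grid$subsession, ncol(m)),
             epoch = rep(grid$epoch, ncol(m)),
             subject = sid, placement = placement,
             metric = rep(colnames(m), each = nrow(grid)),
             value = as.vector(m), stringsAsFactors = FALSE)
}

sample_epoch_metrics <- function(ch, grid) {
  idx <- findInterval(ch$t + 1e-9, grid$t0)
  # map each sample to its epoch row (or NA if in a dropped tail / gap)
  ep <- rep(NA_integer_, length(ch$t))
  ok <- idx >= 1
  ep[ok] <- idx[ok]
  ep[ok][ch$t[ok] >= grid$t1[idx[ok]]] <- NA_integer_
  res <- lapply(seq_len(nrow(grid)), function(g) {
    sel <- which(!is.na(ep) & ep == g)
    n_exp <- round((grid$t1[g] - grid$t0[g]) * ch$fs)
    usable <- sel[!ch$mask[sel]]
    if (length(sel) == 0 || length(usable) < 0.5 * n_exp) {
      return(epoch_metric_names(ch$kind) * NA_real_)
    }
    v <- ch$values[usable, , drop = FALSE]
    switch(ch$kind,
      ST = c(ST = mean(v[, 1])),
      EDA = {
        pk <- ch$eda_aux$scr_peak_times
        c(EDA_mean = mean(v[, 1]), EDA_max = max(v[, 1]),
          EDA_peak_ct = sum(pk >= grid$t0[g] & pk < grid$t1[g]))
      },
      ACC3 = {
        dyn <- ch$dyn[usable, , drop = FALSE]
        mi <- acc_mad_ima(dyn, ch$fs)
        c(ACC_mean_x = mean(v[, 1]), ACC_mean_y = mean(v[, 2]),
          ACC_mean_z = mean(v[, 3]),
          ACC_min_x = min(v[, 1]), ACC_min_y = min(v[, 2]),
          ACC_min_z = min(v[, 3]),
          ACC_max_x = max(v[, 1]), ACC_max_y = max(v[, 2]),
          ACC_max_z = max(v[, 3]), mi)
      })
  })
  m <- do.call(rbind, res)
  colnames(m) <- names(epoch_metric_names(ch$kind))
  data.frame(subsession = rep(grid$subsession, ncol(m)),
             epoch = rep(grid$epoch, ncol(m)),
             subject = ch$subject_id, placement = ch$placement,
             metric = rep(colnames(m), each = nrow(grid)),
             value = as.vector(m), stringsAsFactors = FALSE)
}

epoch_metric_names <- function(kind) {
  nm <- switch(kind,
    ST = "ST",
    EDA = c("EDA_mean", "EDA_max", "EDA_peak_ct"),
    ACC3 = c("ACC_mean_x", "ACC_mean_y", "ACC_mean_z",
             "ACC_min_x", "ACC_min_y", "ACC_min_z",
             "ACC_max_x", "ACC_max_y", "ACC_max_z",
             "MAD_x", "MAD_y", "MAD_z", "IMA"))
  stats::setNames(rep(1, length(nm)), nm)
}

#' Write an ME table as tidy CSV
#' @param me ME table from [epoch_me()]; @param path output file.
#' @export
write_me_table <- function(me, path) {
  write.csv(me, path, row.names = FALSE)
  invisible(path)
}
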