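# Composite representations: directional subsession heatmap, combined
# synchrony table, multimodal middle-minute correlation matrix.

#' Default metric direction map
#'
#' Maps each heatmap metric to a psychophysiological dimension and an
#' orientation.  Increases in HR, the EDA measures, ST and IMA indicate
#' elevated arousal (direct); increases in the time-domain HRV metrics SDNN
#' and RMSSD indicate decreased stress, i.e. a positive contribution on the
#' valence/stress dimension (inverse-to-stress).  The SDNN/RMSSD quotient
#' carries no agreed direction and is excluded by default.
#'
#' @return data.frame `metric, dimension, orientation` with orientation
#'   `+1` (a metric increase renders as a positive/solid cell) for every
#'   default entry; overrides may flip individual rows to `-1`.
#' @export
default_direction_map <- function() {
  data.frame(
    metric = c("SDNN", "RMSSD",
               "HR", "EDA_mean", "EDA_max", "EDA_peak_ct", "ST", "IMA"),
    dimension = c("valence_stress", "valence_stress",
                  rep("arousal", 6)),
    orientation = 1,
    stringsAsFactors = FALSE)
}

#' Per-metric epoch-to-epoch delta signs
#'
#' `sign(v_t - v_{t-1})` within each (subject, placement, metric,
#' subsession) series; the first epoch of a segment has no delta.  Exact
#' ties are treated as decreases (the rendering is binary solid/off);
#' the tie count is reported via the `"ties"` attribute.
#'
#' @param me ME table from [epoch_me()].
#' @return data.frame like `me` with `delta` (+1 increase / -1 decrease /
#'   `NA` missing or first epoch).
#' @export
epoch_deltas <- function(me) {
  key <- paste(me$subject, me$placement, me$metric, me$subsession, sep = "\r")
  ord <- order(key, me$epoch)
  me <- me[ord, ]
  key <- key[ord]
  d <- c(NA, diff(me$value))
  first <- !duplicated(key)
  d[first] <- NA
  prev_ok <- c(FALSE, is.finite(me$value[-length(me$value)]))
  d[!is.finite(me$value) | !prev_ok] <- NA
  ties <- sum(d == 0, na.rm = TRUE)
  me$delta <- ifelse(is.na(d), NA, ifelse(d > 0, 1, -1))
  attr(me, "ties") <- ties
  me
}

#' Build the directional heatmap matrix for an 18-epoch segment
#'
#' Rows are metrics grouped into a valence/stress block then an arousal
#' block, human rows above canine rows within each block; columns are the
#' segment's 17 epoch-to-epoch deltas.  Cell = delta composed with the
#' metric's orientation, so e.g. an SDNN increase renders as a positive
#' valence cell and an HR increase as an arousal increase.  Pre/post survey
#' scores may be attached as flanking annotations.
#'
#' @param deltas output of [epoch_deltas()].
#' @param subsession subsession label to render.
#' @param start_epoch first epoch (0-based) of the 18-epoch segment.
#' @param direction_map see [default_direction_map()].
#' @param surveys optional survey records data.frame for annotation.
#' @param species optional named character vector mapping subject id to
#'   species (default: ids starting with "C" are canine).
#' @return Object of class `cai_heatmap`: `matrix` (+1/-1/NA), `rows`
#'   (metric metadata), `subsession`, `annotations`.
#' @export
build_heatmap <- function(deltas, subsession, start_epoch = 0,
                          direction_map = default_direction_map(),
                          surveys = NULL, species = NULL) {
  epochs <- start_epoch + seq_len(18) - 1L
  sub <- deltas[deltas$subsession == subsession &
                  deltas$epoch %in% epochs &
                  deltas$metric %in% direction_map$metric, ]
  if (!nrow(sub)) {
    ds_stop("dyadsync_validation_error", "no mapped metrics in segment")
  }
  specs <- unique(sub[, c("subject", "placement", "metric")])
  dm <- stats::setNames(direction_map$orientation, direction_map$metric)
  dim_of <- stats::setNames(direction_map$dimension, direction_map$metric)
  specs$dimension <- dim_of[specs$metric]
  # order: valence block before arousal; humans before canines inside each
  is_can <- if (is.null(species)) grepl("^C", specs$subject) else
    species[specs$subject] == "canine"
  specs <- specs[order(specs$dimension == "arousal", is_can, specs$subject,
                       specs$metric), ]
  m <- matrix(NA_real_, nrow(specs), 17,
              dimnames = list(paste(specs$subject, specs$metric, sep = "_"),
                              paste0("d", epochs[-1])))
  for (k in seq_len(nrow(specs))) {
    sr <- sub[sub$subject == specs$subject[k] &
                sub$placement == specs$placement[k] &
                sub$metric == specs$metric[k], ]
    sr <- sr[order(sr$epoch), ]
    dd <- sr$delta[match(epochs[-1], sr$epoch)]
    m[k, ] <- dd * dm[[specs$metric[k]]]
  }
  structure(list(matrix = m, rows = specs, subsession = subsession,
                 annotations = surveys), class = "cai_heatmap")
}

#' Column-block directional coherence
#'
#' Share of agreeing cells (max of the increase share and the decrease
#' share) among defined cells of one delta column within one dimension
#' block; missing with fewer than 2 defined cells.
#'
#' @param heatmap a `cai_heatmap`.
#' @param column delta column index (1-17).
#' @param dimension `"valence_stress"` or `"arousal"`.
#' @return Fraction in `[0.5, 1]`, or `NA`.
#' @export
coherence <- function(heatmap, column, dimension) {
  sel <- heatmap$rows$dimension == dimension
  cells <- heatmap$matrix[sel, column]
  cells <- cells[!is.na(cells)]
  if (length(cells) < 2) return(NA_real_)
  max(mean(cells > 0), mean(cells < 0))
}

#' Export a heatmap as a signed-cell CSV (data-first representation)
#' @param heatmap a `cai_heatmap`; @param path output CSV.
#' @export
write_heatmap_csv <- function(heatmap, path) {
  df <- data.frame(row = rownames(heatmap$matrix),
                   dimension = heatmap$rows$dimension,
                   heatmap$matrix, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a directional heatmap
#' @param x a `cai_heatmap`; @param ... unused.
#' @export
plot.cai_heatmap <- function(x, ...) {
  m <- x$matrix
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = c("#f7e6e6", "#b22222"), zlim = c(-1, 1),
                  axes = FALSE, main = paste("Directional heatmap -", x$subsession))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Multimodal middle-minute correlation matrix across interaction sessions
#'
#' One observation per interaction subsession: the mean over the 6 central
#' epochs (the middle minute) of each (subject-species, metric) ME series
#' and of the consensus behavior code (indeterminate excluded), plus the
#' post-interaction survey scores.  Pairwise-complete Pearson correlations;
#' cells with fewer than `min_pairs` complete pairs are missing.
#'
#' @param feature_rows data.frame with one row per interaction subsession
#'   and one column per variable (see [study_feature_table()]).
#' @param min_pairs minimum complete pairs per cell (default 3).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(feature_rows, min_pairs = 3) {
  num <- feature_rows[, vapply(feature_rows, is.numeric, logical(1)),
                      drop = FALSE]
  keep <- vapply(num, function(col) sum(is.finite(col)) >= min_pairs &&
                   sd(col[is.finite(col)]) > 0, logical(1))
  num <- num[, keep, drop = FALSE]
  if (nrow(num) < min_pairs) {
    ds_stop("dyadsync_validation_error",
            "need >= %d interaction sessions", min_pairs)
  }
  p <- ncol(num)
  m <- matrix(NA_real_, p, p, dimnames = list(names(num), names(num)))
  for (i in seq_len(p)) {
    m[i, i] <- 1
    for (j in seq_len(p)[-i]) {
      ok <- is.finite(num[[i]]) & is.finite(num[[j]])
      if (sum(ok) >= min_pairs && sd(num[[i]][ok]) > 0 && sd(num[[j]][ok]) > 0) {
        m[i, j] <- pearson_r(num[[i]][ok], num[[j]][ok])
      }
    }
  }
  m
}

#' Middle-minute epochs of a subsession
#' @keywords internal
middle_minute_epochs <- function(n_epochs) {
  mid <- n_epochs / 2
  lo <- floor(mid - 3) + 1L
  seq(lo, lo + 5L) - 1L   # 6 central epochs, 0-based
}

#' Combined behavior + survey + physiology block for a dyad pairing
#'
#' One block per interaction subsession: Pearson r and DTW distance per
#' torso metric, per-subject behavior state percentages, XNOR same-state
#' percentage, pre/post SAM and PANAS scores, and the pair's MDORS total
#' (lower = stronger bond).
#'
#' @param sync synchrony table from [synchrony_table()].
#' @param becodes behavior code table from [behavior_epoch_codes()].
#' @param surveys survey records of the session.
#' @param bundle the `cai_session` (for subject ids and timeline).
#' @return data.frame in long form: `subsession, entry, value`.
#' @export
combined_pair_table <- function(sync, becodes, surveys, bundle) {
  hum <- bundle$subjects$id[bundle$subjects$species == "human"][1]
  can <- bundle$subjects$id[bundle$subjects$species == "canine"][1]
  grid <- build_epoch_grid(bundle$timeline)
  rows <- list()
  for (lab in unique(sync$subsession)) {
    s <- sync[sync$subsession == lab, ]
    for (k in seq_len(nrow(s))) {
      rows[[paste(lab, "r", s$metric[k])]] <- data.frame(
        subsession = lab, entry = paste0("Pcorr_", s$metric[k]),
        value = s$pearson_r[k])
      rows[[paste(lab, "d", s$metric[k])]] <- data.frame(
        subsession = lab, entry = paste0("DTW_", s$metric[k]),
        value = s$dtw_distance[k])
    }
    gsel <- grid[grid$subsession == lab, ]
    ch <- consensus_codes(becodes, hum, gsel)
    cc <- consensus_codes(becodes, can, gsel)
    ph <- tryCatch(state_percentages(ch), dyadsync_error = function(e) rep(NA_real_, 3))
    pc <- tryCatch(state_percentages(cc), dyadsync_error = function(e) rep(NA_real_, 3))
    for (st in c("pos", "neu", "neg")) {
      rows[[paste(lab, "h", st)]] <- data.frame(
        subsession = lab, entry = paste0("becode_", hum, "_", st, "_pct"),
        value = ph[[match(st, c("pos", "neu", "neg"))]])
      rows[[paste(lab, "c", st)]] <- data.frame(
        subsession = lab, entry = paste0("becode_", can, "_", st, "_pct"),
        value = pc[[match(st, c("pos", "neu", "neg"))]])
    }
    ss <- tryCatch(same_state_pct(ch, cc), dyadsync_error = function(e) NA_real_)
    rows[[paste(lab, "xnor")]] <- data.frame(
      subsession = lab, entry = "same_state_pct", value = ss)
    if (!is.null(surveys)) {
      tp_post <- paste0("after_", lab)
      labs <- bundle$timeline$label
      pre_lab <- labs[match(lab, labs) - 1L]
      tp_pre <- if (length(pre_lab)) paste0("after_", pre_lab) else NA
      for (sc in c("SAM_V", "SAM_A", "PANAS_PA", "PANAS_NA")) {
        for (side in c("pre", "post")) {
          tp <- if (side == "pre") tp_pre else tp_post
          v <- surveys$value[surveys$scale == sc & surveys$timepoint %in% tp]
          rows[[paste(lab, sc, side)]] <- data.frame(
            subsession = lab, entry = paste(sc, side, sep = "_"),
            value = if (length(v)) v[1] else NA_real_)
        }
      }
    }
  }
  md <- if (!is.null(surveys)) {
    v <- surveys$value[surveys$scale == "MDORS"]
    if (length(v)) v[1] else NA_real_
  } else NA_real_
  rows[["mdors"]] <- data.frame(subsession = "session", entry = "MDORS",
                                value = md)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a raw dual-trace ECG snapshot with event annotations
#'
#' @param ecg_human,ecg_canine ECG `cai_channel`s.
#' @param window `c(t0, t1)` seconds to display.
#' @param annotations optional data.frame `start`, `end`, `label`; intervals
#'   outside the window are skipped with a warning.
#' @param file optional PNG path; `NULL` draws on the active device.
#' @export
plot_raw_snapshot <- function(ecg_human, ecg_canine, window = NULL,
                              annotations = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 500)
    on.exit(grDevices::dev.off())
  }
  w <- window %||% c(max(min(ecg_human$t), min(ecg_canine$t)),
                     max(min(ecg_human$t), min(ecg_canine$t)) + 10)
  sel_h <- ecg_human$t >= w[1] & ecg_human$t <= w[2]
  sel_c <- ecg_canine$t >= w[1] & ecg_canine$t <= w[2]
  if (!is.null(annotations)) {
    out_of_range <- annotations$end < w[1] | annotations$start > w[2]
    if (any(out_of_range)) {
      warning(sprintf("annotation(s) outside plotted window skipped: %s",
                      paste(annotations$label[out_of_range], collapse = ", ")))
      annotations <- annotations[!out_of_range, , drop = FALSE]
    }
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  draw <- function(t, v, ttl) {
    graphics::plot(t, v, type = "l", xlab = "time (s)", ylab = "ECG (mV)",
                   main = ttl)
    if (!is.null(annotations)) {
      for (k in seq_len(nrow(annotations))) {
        a <- annotations[k, ]
        graphics::rect(max(a$start, w[1]), min(v), min(a$end, w[2]), max(v),
                       col = grDevices::adjustcolor("orange", 0.25), border = NA)
      }
    }
  }
  draw(ecg_human$t[sel_h], ecg_human$values[sel_h, 1], "human ECG")
  draw(ecg_canine$t[sel_c], ecg_canine$values[sel_c, 1], "canine ECG")
  invisible(NULL)
}
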