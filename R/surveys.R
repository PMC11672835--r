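# Survey scoring (SAM, PANAS-SF, MDORS) and session-type statistics.

#' Score a PANAS-SF response
#'
#' @param items 20 integer responses in 1-5; the first 10 are the positive
#'   affect items, the last 10 the negative affect items.
#' @return Named numeric `c(PA, NA)` sums, each in `[10, 50]`.
#' @export
score_panas <- function(items) {
  items <- as.numeric(items)
  if (length(items) != 20 || any(!is.finite(items)) ||
      any(items < 1 | items > 5) || any(items != round(items))) {
    ds_stop("dyadsync_validation_error",
            "PANAS-SF needs 20 integer responses in 1-5")
  }
  c(PA = sum(items[1:10]), "NA" = sum(items[11:20]))
}

#' Mean/SD survey summary by subsession, with pooled session-type rows
#'
#' One row per (scale, timepoint label); pooled `ALL_NEU` rows collapse the
#' baseline, neutral and post subsessions and `ALL_INT` the interaction
#' subsessions.  SD is the sample SD (missing for single records).
#'
#' @param records data.frame `subject, timepoint, scale, value` with
#'   timepoints `after_<LABEL>`.
#' @return data.frame `scale, timepoint, n, mean, sd`.
#' @export
summarize_by_subsession <- function(records) {
  r <- records[records$timepoint != "session", , drop = FALSE]
  r$label <- sub("^after_", "", r$timepoint)
  r$pool <- ifelse(interaction_labels(r$label), "ALL_INT", "ALL_NEU")
  cell <- function(vals) {
    c(n = length(vals), mean = mean(vals),
      sd = if (length(vals) >= 2) sd(vals) else NA_real_)
  }
  rows <- list()
  for (sc in unique(r$scale)) {
    rs <- r[r$scale == sc, ]
    for (lb in unique(rs$label)) {
      st <- cell(rs$value[rs$label == lb])
      rows[[paste(sc, lb)]] <- data.frame(scale = sc, timepoint = lb,
        n = st[["n"]], mean = st[["mean"]], sd = st[["sd"]])
    }
    for (pl in c("ALL_NEU", "ALL_INT")) {
      v <- rs$value[rs$pool == pl]
      if (length(v)) {
        st <- cell(v)
        rows[[paste(sc, pl)]] <- data.frame(scale = sc, timepoint = pl,
          n = st[["n"]], mean = st[["mean"]], sd = st[["sd"]])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wilcoxon signed-rank test with exact small-sample p-value
#'
#' Zero differences are dropped (Wilcoxon's original treatment); ties in
#' `|d|` are mid-ranked.  For 12 or fewer nonzero differences the two-sided
#' p-value is computed by full enumeration of all 2^n sign assignments
#' (tie-aware); beyond that a normal approximation with continuity
#' correction and tie-corrected variance is used.
#'
#' @param x,y paired numeric vectors (or `y` omitted: `x` are differences).
#' @param exact_max maximum n for exact enumeration (default 12).
#' @return List `statistic` (W = sum of positive-difference ranks),
#'   `p_value` (two-sided), `n` (nonzero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 12) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    ds_stop("dyadsync_validation_error",
            "all differences are zero: signed-rank test undefined")
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # enumerate all sign assignments; with mid-ranks the null distribution
    # of W is the distribution of a random subset-sum of the ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% r)
    # two-sided: double the smaller inclusive tail, capped at 1
    p_lo <- mean(ws <= w)
    p_hi <- mean(ws >= w)
    p <- min(1, 2 * min(p_lo, p_hi))
    list(statistic = w, p_value = p, n = n, method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    list(statistic = w, p_value = p, n = n, method = "normal")
  }
}

#' Compare session types (neutral vs interaction) for a scale or metric
#'
#' Forms one paired observation per session: the mean of the value over
#' neutral-type timepoints/subsessions versus over interaction-type ones,
#' then applies the signed-rank test across sessions.
#'
#' @param df data.frame with columns `session`, `type` (values `NEU`/`INT`)
#'   and `value`.
#' @return List `n_pairs`, `mean_neu`, `mean_int`, `statistic`, `p_value`
#'   (elements `NA` when fewer than 2 usable pairs).
#' @export
compare_session_types <- function(df) {
  stopifnot(all(c("session", "type", "value") %in% names(df)))
  agg <- stats::aggregate(value ~ session + type, df, mean, na.rm = TRUE)
  wide <- merge(agg[agg$type == "NEU", c("session", "value")],
                agg[agg$type == "INT", c("session", "value")],
                by = "session", suffixes = c("_neu", "_int"))
  wide <- wide[is.finite(wide$value_neu) & is.finite(wide$value_int), ]
  if (nrow(wide) < 2 || all(wide$value_int == wide$value_neu)) {
    return(list(n_pairs = nrow(wide), mean_neu = mean(wide$value_neu),
                mean_int = mean(wide$value_int), statistic = NA_real_,
                p_value = NA_real_))
  }
  wt <- wilcoxon_signed_rank(wide$value_int, wide$value_neu)
  list(n_pairs = nrow(wide), mean_neu = mean(wide$value_neu),
       mean_int = mean(wide$value_int), statistic = wt$statistic,
       p_value = wt$p_value)
}

# Long survey records from several sessions -> session-type comparison rows
# for each scale.
survey_session_type_table <- function(survey_list) {
  rows <- list()
  for (sc in c("SAM_V", "SAM_A", "PANAS_PA", "PANAS_NA")) {
    df <- do.call(rbind, lapply(seq_along(survey_list), function(i) {
      s <- survey_list[[i]]
      s <- s[s$scale == sc & s$timepoint != "session", , drop = FALSE]
      if (!nrow(s)) return(NULL)
      lab <- sub("^after_", "", s$timepoint)
      data.frame(session = i,
                 type = ifelse(interaction_labels(lab), "INT", "NEU"),
                 value = s$value)
    }))
    cmp <- compare_session_types(df)
    rows[[sc]] <- data.frame(scale = sc, n_pairs = cmp$n_pairs,
                             mean_neu = cmp$mean_neu, mean_int = cmp$mean_int,
                             p_value = cmp$p_value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
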