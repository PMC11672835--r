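# PPSA behavior coding: per-epoch state assignment, state percentages,
# XNOR dyadic synchrony, inter-rater Cohen's kappa.

#' Collapse per-second behavior labels onto the epoch grid (PPSA)
#'
#' Each epoch's code is the strict-majority state among its seconds.  Any
#' non-strict majority — a tie involving neutral, or a positive/negative tie
#' — codes neutral (the schema's deliberate neutral bias: 5 s of neutral
#' with 5 s of positive or negative is always neutral).  Epochs with 5 or
#' more off-screen seconds are indeterminate; fewer off-screen seconds are
#' simply excluded from the majority count.
#'
#' @param labels character (or integer) vector, one label per second from
#'   session start: `"-1"`, `"0"`, `"1"` or `"offscreen"`.
#' @param grid an `epoch_grid`.
#' @return Integer vector of per-epoch codes aligned to `grid` rows:
#'   -1, 0, 1 or `NA` (indeterminate).
#' @export
ppsa_code <- function(labels, grid) {
  stopifnot(inherits(grid, "epoch_grid"))
  labels <- as.character(labels)
  need <- max(grid$t1)
  if (length(labels) < need) {
    ds_stop("dyadsync_validation_error",
            "label stream has %d seconds; epoch grid needs %d",
            length(labels), need)
  }
  vapply(seq_len(nrow(grid)), function(g) {
    secs <- labels[(grid$t0[g] + 1):grid$t1[g]]
    ppsa_code_epoch(secs)
  }, integer(1))
}

# Majority rule for one epoch's seconds.
ppsa_code_epoch <- function(secs) {
  off <- sum(secs == "offscreen")
  if (off >= length(secs) / 2) return(NA_integer_)
  on <- secs[secs != "offscreen"]
  cnt <- c(neg = sum(on == "-1"), neu = sum(on == "0"), pos = sum(on == "1"))
  mx <- max(cnt)
  winners <- names(cnt)[cnt == mx]
  if (length(winners) > 1L) return(0L)      # any tie -> neutral
  switch(winners, neg = -1L, neu = 0L, pos = 1L)
}

#' Percentage of determinate epochs in each psychophysiological state
#'
#' @param codes integer per-epoch codes (-1/0/1, `NA` = indeterminate).
#' @return Named numeric `c(pos, neu, neg)` percentages summing to 100.
#' @export
state_percentages <- function(codes) {
  det <- codes[!is.na(codes)]
  if (!length(det)) {
    ds_stop("dyadsync_validation_error", "all epochs indeterminate")
  }
  100 * c(pos = mean(det == 1), neu = mean(det == 0), neg = mean(det == -1))
}

#' XNOR dyadic behavior synchrony
#'
#' Percentage of epochs in which both dyad members carry the identical
#' state code, among epochs where both are determinate.
#'
#' @param human,canine per-epoch code vectors on the same grid.
#' @return Percentage in `[0, 100]`.
#' @export
same_state_pct <- function(human, canine) {
  stopifnot(length(human) == length(canine))
  both <- !is.na(human) & !is.na(canine)
  if (!any(both)) {
    ds_stop("dyadsync_validation_error", "no jointly determinate epochs")
  }
  100 * mean(human[both] == canine[both])
}

#' Cohen's kappa between two raters' epoch codes
#'
#' Unweighted kappa on the three-category nominal scale;
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement from the
#' marginal code frequencies.  Indeterminate epochs of either rater are
#' excluded.  Returns `NA` when expected agreement is 1.
#'
#' @param a,b per-epoch code vectors from two raters.
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohens_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  both <- !is.na(a) & !is.na(b)
  a <- a[both]; b <- b[both]
  if (!length(a)) {
    ds_stop("dyadsync_validation_error", "no jointly determinate epochs")
  }
  cats <- c(-1, 0, 1)
  p_o <- mean(a == b)
  pa <- vapply(cats, function(k) mean(a == k), numeric(1))
  pb <- vapply(cats, function(k) mean(b == k), numeric(1))
  p_e <- sum(pa * pb)
  if (abs(1 - p_e) < 1e-12) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Mean pairwise Cohen's kappa across several raters
#'
#' @param series list of per-epoch code vectors (one per rater).
#' @return Mean of all pairwise kappas (undefined pairs dropped).
#' @export
multi_rater_kappa <- function(series) {
  n <- length(series)
  stopifnot(n >= 2)
  ks <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ks <- c(ks, cohens_kappa(series[[i]], series[[j]]))
    }
  }
  mean(ks, na.rm = TRUE)
}

#' Per-epoch behavior codes for every rater and subject of a bundle
#'
#' @param bundle a `cai_session`; @param grid an `epoch_grid`.
#' @return data.frame `subsession, epoch, subject, rater, code`.
#' @export
behavior_epoch_codes <- function(bundle, grid) {
  rows <- list()
  for (rater in names(bundle$behavior)) {
    for (sid in names(bundle$behavior[[rater]])) {
      codes <- ppsa_code(bundle$behavior[[rater]][[sid]], grid)
      rows[[paste(rater, sid)]] <-
        data.frame(subsession = grid$subsession, epoch = grid$epoch,
                   subject = sid, rater = rater, code = codes,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Majority consensus code across raters per epoch (ties -> neutral,
# all-indeterminate -> NA); used by the composite tables.
consensus_codes <- function(codes_df, sid, grid) {
  sub <- codes_df[codes_df$subject == sid, ]
  key <- paste(sub$subsession, sub$epoch)
  gkey <- paste(grid$subsession, grid$epoch)
  vapply(gkey, function(k) {
    v <- sub$code[key == k]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    tab <- table(v)
    mx <- names(tab)[tab == max(tab)]
    if (length(mx) > 1L) 0L else as.integer(mx)
  }, integer(1), USE.NAMES = FALSE)
}
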