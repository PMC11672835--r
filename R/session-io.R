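# On-disk session layout: manifest.yaml, one CSV per channel, per-second
# behavior label CSVs, surveys.csv, optional ground_truth.json.

#' Write a session bundle to a directory
#'
#' Layout: `manifest.yaml` (subjects, timeline, channel registry with units
#' and sampling rates), `channels/<subject>_<kind>_<placement>.csv` with
#' header `time_s,value` (or `time_s,ax,ay,az`),
#' `behavior_<rater>_<subject>.csv` with `second,code`, and `surveys.csv`.
#'
#' @param bundle a `cai_session`.
#' @param path target directory (created if absent).
#' @param truth optional ground-truth list, written as `ground_truth.json`.
#' @return `path`, invisibly.
#' @export
write_session <- function(bundle, path, truth = NULL) {
  stopifnot(inherits(bundle, "cai_session"))
  dir.create(file.path(path, "channels"), recursive = TRUE, showWarnings = FALSE)
  registry <- list()
  for (nm in names(bundle$channels)) {
    ch <- bundle$channels[[nm]]
    fn <- paste0(gsub("[^A-Za-z0-9]", "_", nm), ".csv")
    df <- if (ch$kind == "ACC3") {
      data.frame(time_s = ch$t, ax = ch$values[, 1], ay = ch$values[, 2],
                 az = ch$values[, 3])
    } else {
      data.frame(time_s = ch$t, value = ch$values[, 1])
    }
    write.csv(df, file.path(path, "channels", fn), row.names = FALSE)
    registry[[nm]] <- list(file = file.path("channels", fn),
                           subject = ch$subject_id, kind = ch$kind,
                           placement = ch$placement, fs = ch$fs,
                           unit = ch$unit)
  }
  beh_files <- list()
  for (rater in names(bundle$behavior)) {
    for (sid in names(bundle$behavior[[rater]])) {
      codes <- bundle$behavior[[rater]][[sid]]
      fn <- sprintf("behavior_%s_%s.csv", rater, sid)
      write.csv(data.frame(second = seq_along(codes), code = codes),
                file.path(path, fn), row.names = FALSE)
      beh_files[[length(beh_files) + 1L]] <-
        list(file = fn, rater = rater, subject = sid)
    }
  }
  if (!is.null(bundle$surveys)) {
    write.csv(bundle$surveys, file.path(path, "surveys.csv"),
              row.names = FALSE)
  }
  manifest <- list(
    subjects = lapply(seq_len(nrow(bundle$subjects)), function(i)
      as.list(bundle$subjects[i, , drop = FALSE])),
    timeline = lapply(seq_len(nrow(bundle$timeline)), function(i)
      as.list(bundle$timeline[i, , drop = FALSE])),
    channels = registry,
    behavior = beh_files,
    surveys = if (!is.null(bundle$surveys)) "surveys.csv",
    meta = bundle$meta)
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"))
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a session bundle from a directory
#'
#' Validates the manifest, the presence of every referenced file, channel
#' units and time monotonicity; errors name the offending file/row.
#'
#' @param path session directory containing `manifest.yaml`.
#' @return A `cai_session`.
#' @export
read_session <- function(path) {
  mf_path <- file.path(path, "manifest.yaml")
  if (!file.exists(mf_path)) {
    ds_stop("dyadsync_io_error", "missing manifest: %s", mf_path)
  }
  mf <- yaml::read_yaml(mf_path)
  subjects <- do.call(rbind, lapply(mf$subjects, function(s)
    data.frame(id = s$id, species = s$species,
               role = s$role %||% NA_character_, stringsAsFactors = FALSE)))
  timeline <- do.call(rbind, lapply(mf$timeline, function(s)
    data.frame(label = s$label, t_start = s$t_start, t_end = s$t_end,
               stringsAsFactors = FALSE)))
  channels <- list()
  for (nm in names(mf$channels)) {
    reg <- mf$channels[[nm]]
    fp <- file.path(path, reg$file)
    if (!file.exists(fp)) {
      ds_stop("dyadsync_io_error", "missing channel file: %s", fp)
    }
    df <- read.csv(fp)
    vals <- if (reg$kind == "ACC3") {
      as.matrix(df[, c("ax", "ay", "az")])
    } else {
      matrix(df$value, ncol = 1)
    }
    if (!is.null(reg$unit) && reg$unit != CHANNEL_KINDS[[reg$kind]]) {
      ds_stop("dyadsync_io_error", "unit mismatch for '%s': %s (expected %s)",
              nm, reg$unit, CHANNEL_KINDS[[reg$kind]])
    }
    channels[[nm]] <- cai_channel(reg$subject, reg$kind, reg$placement,
                                  reg$fs, df$time_s, vals)
  }
  behavior <- list()
  for (bf in mf$behavior) {
    fp <- file.path(path, bf$file)
    if (!file.exists(fp)) {
      ds_stop("dyadsync_io_error", "missing behavior file: %s", fp)
    }
    df <- read.csv(fp, colClasses = c(second = "integer", code = "character"))
    behavior[[bf$rater]][[bf$subject]] <- df$code
  }
  surveys <- NULL
  if (!is.null(mf$surveys)) {
    fp <- file.path(path, mf$surveys)
    if (!file.exists(fp)) ds_stop("dyadsync_io_error", "missing %s", fp)
    surveys <- read.csv(fp, stringsAsFactors = FALSE)
  }
  cai_session(subjects, timeline, channels, behavior, surveys,
              meta = mf$meta %||% list())
}
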