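# Multi-session study simulation and the end-to-end report pipeline.

#' Simulate a multi-session CAI study
#'
#' Sessions rotate over three humans interacting with one dog: the owner
#' (strong bond), a friend (moderate) and a stranger (weak).  Bond strength
#' drives the physiological coupling, the behavior-copy probability, the
#' positive-state occupancy and the MDORS total (lower = stronger bond).
#'
#' @param n_sessions number of sessions (default 22).
#' @param seed master seed; each session derives its own.
#' @param render_raw_ecg render raw ECG waveforms (slow); `FALSE` places
#'   ground-truth beats directly in each session's truth.
#' @param subsession_plan timeline plan shared by every session.
#' @return List of `list(bundle, truth, role, human, session)` entries.
#' @export
simulate_study <- function(n_sessions = 22, seed = 1L, render_raw_ecg = FALSE,
                           subsession_plan = default_subsession_plan()) {
  roles <- data.frame(
    human = c("H1", "H2", "H3"),
    role = c("owner", "friend", "stranger"),
    bond = c(0.9, 0.6, 0.3))
  out <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    r <- roles[(s - 1L) %% nrow(roles) + 1L, ]
    occ_pos <- 0.10 + 0.25 * r$bond
    occ_neg <- 0.05 * (1 - r$bond)
    cfg <- sim_config(
      seed = stream_seed(seed, paste0("session/", s)),
      subsession_plan = subsession_plan,
      coupling_rho = r$bond,
      copy_prob_kappa = 0.9 * r$bond,
      state_occupancy = c(neg = occ_neg, neu = 1 - occ_pos - occ_neg,
                          pos = occ_pos),
      render_raw_ecg = render_raw_ecg,
      human_id = r$human, canine_id = "C1", role = r$role)
    sim <- simulate_session(cfg)
    out[[s]] <- list(bundle = sim$bundle, truth = sim$truth,
                     role = r$role, human = r$human, session = s)
  }
  out
}

#' Beat series per subject taken from simulator ground truth
#'
#' @param bundle a `cai_session`; @param truth its ground-truth list.
#' @return Named list of `beat_series`.
#' @export
beats_from_truth <- function(bundle, truth) {
  species_of <- stats::setNames(bundle$subjects$species, bundle$subjects$id)
  out <- list()
  for (sid in names(truth$r_peak_times)) {
    pk <- as.numeric(truth$r_peak_times[[sid]])
    out[[sid]] <- new_beat_series(pk, species_of[[sid]])
    attr(out[[sid]], "placement") <-
      if (species_of[[sid]] == "human") "chest" else "harness"
  }
  out
}

#' Analyze one session end to end
#'
#' Runs preprocess -> ME metrics -> behavior coding -> synchrony -> deltas,
#' returning every intermediate product.
#'
#' @param bundle a `cai_session`.
#' @param truth optional simulator truth; when given and the bundle carries
#'   no ECG channels, beats come from the truth instead of peak detection.
#' @return List `grid`, `me`, `becodes`, `sync`, `deltas`, `beats`,
#'   `bundle` (preprocessed).
#' @export
analyze_session <- function(bundle, truth = NULL) {
  bundle <- preprocess_session(bundle)
  grid <- build_epoch_grid(bundle$timeline)
  has_ecg <- any(vapply(bundle$channels, function(ch) ch$kind == "ECG",
                        logical(1)))
  beats <- if (!has_ecg && !is.null(truth)) beats_from_truth(bundle, truth)
  me <- epoch_me(bundle, grid, beats)
  becodes <- behavior_epoch_codes(bundle, grid)
  sync <- synchrony_table(bundle, beats)
  deltas <- epoch_deltas(me)
  list(grid = grid, me = me, becodes = becodes, sync = sync,
       deltas = deltas, beats = beats, bundle = bundle)
}

#' Session-level feature rows for the multimodal correlation matrix
#'
#' One row per interaction subsession across sessions: middle-minute means
#' of each core metric by species, the consensus behavior code mean
#' (indeterminate excluded), and the post-interaction survey scores.
#'
#' @param analyses list of [analyze_session()] results.
#' @param bundles matching list of session bundles.
#' @return data.frame, one row per (session, interaction subsession).
#' @export
study_feature_table <- function(analyses, bundles) {
  core <- c("HR", "SDNN", "RMSSD", "IMA", "EDA_mean", "EDA_max",
            "EDA_peak_ct", "ST")
  rows <- list()
  for (s in seq_along(analyses)) {
    an <- analyses[[s]]
    b <- bundles[[s]]
    species_of <- stats::setNames(b$subjects$species, b$subjects$id)
    tl <- b$timeline
    for (lab in tl$label[interaction_labels(tl$label)]) {
      gsel <- an$grid[an$grid$subsession == lab, ]
      mm <- middle_minute_epochs(nrow(gsel))
      row <- list(session = s, subsession = lab)
      for (met in core) {
        for (sp in c("human", "canine")) {
          sel <- an$me$subsession == lab & an$me$epoch %in% mm &
            an$me$metric == met & species_of[an$me$subject] == sp
          v <- an$me$value[sel]
          nm <- paste0(substr(sp, 1, 1), "_", met)
          row[[nm]] <- if (any(is.finite(v))) mean(v, na.rm = TRUE) else NA_real_
        }
      }
      for (sp in c("human", "canine")) {
        sid <- b$subjects$id[b$subjects$species == sp][1]
        cons <- consensus_codes(an$becodes, sid, gsel)
        v <- cons[gsel$epoch %in% mm]
        v <- v[!is.na(v)]
        row[[paste0(substr(sp, 1, 1), "_becode")]] <-
          if (length(v)) mean(v) else NA_real_
      }
      if (!is.null(b$surveys)) {
        tp <- paste0("after_", lab)
        for (sc in c("SAM_V", "SAM_A", "PANAS_PA", "PANAS_NA")) {
          v <- b$surveys$value[b$surveys$scale == sc & b$surveys$timepoint == tp]
          row[[sc]] <- if (length(v)) v[1] else NA_real_
        }
      }
      rows[[paste(s, lab)]] <- as.data.frame(row, check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Physiological metric session-type comparison across a study
#'
#' For each core metric: per-session means over neutral-type vs
#' interaction-type subsession epochs, compared with the signed-rank test.
#'
#' @param analyses list of [analyze_session()] results.
#' @param bundles matching session bundles.
#' @param metrics metric ids to compare.
#' @return data.frame `metric, subject_species, n_pairs, mean_neu,
#'   mean_int, p_value`.
#' @export
physio_session_type_table <- function(analyses, bundles,
                                      metrics = c("HR", "SDNN", "RMSSD",
                                                  "IMA", "EDA_mean",
                                                  "EDA_max", "ST")) {
  rows <- list()
  for (met in metrics) {
    for (sp in c("human", "canine")) {
      df <- do.call(rbind, lapply(seq_along(analyses), function(s) {
        an <- analyses[[s]]
        b <- bundles[[s]]
        species_of <- stats::setNames(b$subjects$species, b$subjects$id)
        sel <- an$me$metric == met & species_of[an$me$subject] == sp
        if (!any(sel)) return(NULL)
        lab <- an$me$subsession[sel]
        data.frame(session = s,
                   type = ifelse(interaction_labels(lab), "INT", "NEU"),
                   value = an$me$value[sel])
      }))
      if (is.null(df) || !nrow(df) || all(is.na(df$value))) next
      cmp <- compare_session_types(df[is.finite(df$value), ])
      rows[[paste(met, sp)]] <- data.frame(
        metric = met, subject_species = sp, n_pairs = cmp$n_pairs,
        mean_neu = cmp$mean_neu, mean_int = cmp$mean_int,
        p_value = cmp$p_value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full study report
#'
#' Produces the survey summary and session-type comparisons, per-session
#' behavior percentages with XNOR synchrony, the physiological session-type
#' table, per-session synchrony tables, a directional heatmap per
#' interaction subsession of the first session, and the multimodal
#' correlation matrix.  Tables are written as CSV when `out_dir` is given.
#'
#' @param study list from [simulate_study()] (or equivalent
#'   bundle/truth pairs).
#' @param out_dir optional output directory for CSV/PNG artifacts.
#' @return List of all tables and matrices.
#' @export
run_report <- function(study, out_dir = NULL) {
  bundles <- lapply(study, `[[`, "bundle")
  analyses <- lapply(study, function(s) analyze_session(s$bundle, s$truth))

  survey_summary <- summarize_by_subsession(
    do.call(rbind, lapply(bundles, `[[`, "surveys")))
  survey_tests <- survey_session_type_table(lapply(bundles, `[[`, "surveys"))

  behavior_rows <- list()
  for (s in seq_along(analyses)) {
    an <- analyses[[s]]
    b <- bundles[[s]]
    for (lab in b$timeline$label[interaction_labels(b$timeline$label)]) {
      gsel <- an$grid[an$grid$subsession == lab, ]
      hum <- b$subjects$id[b$subjects$species == "human"][1]
      can <- b$subjects$id[b$subjects$species == "canine"][1]
      ch <- consensus_codes(an$becodes, hum, gsel)
      cc <- consensus_codes(an$becodes, can, gsel)
      ph <- tryCatch(state_percentages(ch),
                     dyadsync_error = function(e) rep(NA_real_, 3))
      pc <- tryCatch(state_percentages(cc),
                     dyadsync_error = function(e) rep(NA_real_, 3))
      ss <- tryCatch(same_state_pct(ch, cc),
                     dyadsync_error = function(e) NA_real_)
      behavior_rows[[paste(s, lab)]] <- data.frame(
        session = s, human = hum, subsession = lab,
        h_pos = ph[[1]], h_neu = ph[[2]], h_neg = ph[[3]],
        c_pos = pc[[1]], c_neu = pc[[2]], c_neg = pc[[3]],
        same_state_pct = ss)
    }
  }
  behavior_table <- do.call(rbind, behavior_rows)
  rownames(behavior_table) <- NULL

  physio_table <- physio_session_type_table(analyses, bundles)
  sync_tables <- lapply(analyses, `[[`, "sync")
  features <- study_feature_table(analyses, bundles)
  cormat <- correlation_matrix(features[, !(names(features) %in%
                                              c("session", "subsession"))])

  species <- stats::setNames(bundles[[1]]$subjects$species,
                             bundles[[1]]$subjects$id)
  heatmaps <- list()
  an1 <- analyses[[1]]
  for (lab in bundles[[1]]$timeline$label[
      interaction_labels(bundles[[1]]$timeline$label)]) {
    gsel <- an1$grid[an1$grid$subsession == lab, ]
    start <- max(0L, floor(nrow(gsel) / 2) - 9L)
    heatmaps[[lab]] <- build_heatmap(an1$deltas, lab, start_epoch = start,
                                     surveys = bundles[[1]]$surveys,
                                     species = species)
  }

  out <- list(survey_summary = survey_summary, survey_tests = survey_tests,
              behavior_table = behavior_table, physio_table = physio_table,
              sync_tables = sync_tables, features = features,
              correlation_matrix = cormat, heatmaps = heatmaps,
              analyses = analyses)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(survey_summary, file.path(out_dir, "survey_summary.csv"),
              row.names = FALSE)
    write.csv(survey_tests, file.path(out_dir, "survey_tests.csv"),
              row.names = FALSE)
    write.csv(behavior_table, file.path(out_dir, "behavior_synchrony.csv"),
              row.names = FALSE)
    write.csv(physio_table, file.path(out_dir, "physio_session_types.csv"),
              row.names = FALSE)
    sync_all <- do.call(rbind, lapply(seq_along(sync_tables), function(i)
      cbind(session = i, sync_tables[[i]])))
    write.csv(sync_all, file.path(out_dir, "synchrony.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(cormat), file.path(out_dir,
              "correlation_matrix.csv"))
    for (lab in names(heatmaps)) {
      write_heatmap_csv(heatmaps[[lab]],
                        file.path(out_dir, paste0("heatmap_", lab, ".csv")))
    }
  }
  out
}
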