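# Full-session synthetic dyad generator.

#' Build a validated simulation configuration
#'
#' Defines one synthetic canine-assisted-interaction (CAI) session: the
#' subsession timeline (baseline, two 10-min interactions couched in neutral
#' subsessions, post-line), per-subject heart-rate and HRV targets, the
#' dyadic physiological coupling and behavior-copy parameters, channel
#' sampling rates and survey-effect sizes.
#'
#' @param seed master integer seed; every random stream derives from it.
#' @param subsession_plan data.frame with columns `label` (from BASE, INT1,
#'   NEU1, INT2, NEU2, POST; INT* are interaction subsessions) and
#'   `duration` (s).
#' @param human_hr_mean,canine_hr_mean mean heart rate, beats/min.
#' @param sdnn_target,rmssd_target named numeric `c(human = , canine = )`
#'   HRV targets, ms.
#' @param coupling_rho dyadic physiological coupling in `[0, 1]`: the squared
#'   loading of both subjects' IBI fluctuations on a shared latent
#'   Ornstein-Uhlenbeck driver during interaction subsessions, so the
#'   expected Pearson correlation of their smoothed heart-rate series is
#'   `coupling_rho`.
#' @param copy_prob_kappa behavior-state coupling in `[0, 1]` (probability
#'   per second that the canine copies the human's state).
#' @param scr_rate human skin-conductance-response rate at rest, events/min
#'   (doubled during interactions).
#' @param activity_bout_schedule optional list keyed by subsession label,
#'   each a data.frame `start`, `end` (s, subsession-relative), `amplitude`
#'   (m/s²); `NULL` auto-generates movement bouts.
#' @param st_baseline,st_drift skin temperature baseline (°C) and drift
#'   (°C/min).
#' @param ecg_fs,acc_fs,eda_fs,st_fs channel sampling rates, Hz.
#' @param render_raw_ecg if `FALSE`, skip waveform rendering; beat series are
#'   then taken from ground truth (fast mode for large simulation studies).
#' @param state_occupancy stationary probabilities `c(neg, neu, pos)` of the
#'   behavior chain during interactions.
#' @param rater_error per-rater per-second misread probabilities.
#' @param offscreen_rate expected fraction of interaction seconds in which
#'   the dyad is out of camera view.
#' @param human_id,canine_id,role subject labels; `role` is the human's
#'   relationship to the dog (owner/friend/stranger).
#' @param mdors_total optional Monash Dog Owner Relationship Scale total for
#'   the pair (lower = stronger bond).
#' @param survey_effects list of effect sizes on the post-interaction survey
#'   constructs (see Details in the package vignette).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       subsession_plan = default_subsession_plan(),
                       human_hr_mean = 75, canine_hr_mean = 95,
                       sdnn_target = c(human = 50, canine = 60),
                       rmssd_target = c(human = 40, canine = 40),
                       coupling_rho = 0.6, copy_prob_kappa = 0.5,
                       scr_rate = 3, activity_bout_schedule = NULL,
                       st_baseline = 31, st_drift = 0.05,
                       ecg_fs = 250, acc_fs = 32, eda_fs = 4, st_fs = 4,
                       render_raw_ecg = TRUE,
                       state_occupancy = c(neg = 0.02, neu = 0.68, pos = 0.30),
                       rater_error = c(0.03, 0.05, 0.07),
                       offscreen_rate = 0.05,
                       human_id = "H1", canine_id = "C1", role = "owner",
                       mdors_total = NULL,
                       survey_effects = default_survey_effects()) {
  stopifnot(is.data.frame(subsession_plan),
            all(c("label", "duration") %in% names(subsession_plan)))
  bad <- setdiff(subsession_plan$label,
                 c("BASE", "INT1", "NEU1", "INT2", "NEU2", "POST"))
  if (length(bad)) {
    ds_stop("dyadsync_parameter_error", "unknown subsession label(s): %s",
            paste(bad, collapse = ", "))
  }
  if (any(subsession_plan$duration <= 0)) {
    ds_stop("dyadsync_parameter_error", "subsession durations must be > 0")
  }
  assert_scalar_in(human_hr_mean, "human_hr_mean", 20, 300, open = TRUE)
  assert_scalar_in(canine_hr_mean, "canine_hr_mean", 20, 300, open = TRUE)
  assert_scalar_in(coupling_rho, "coupling_rho", 0, 1)
  assert_scalar_in(copy_prob_kappa, "copy_prob_kappa", 0, 1)
  for (sp in c("human", "canine")) {
    ibi_phi(sdnn_target[[sp]], rmssd_target[[sp]])  # feasibility check
  }
  if (ecg_fs < 100) {
    ds_stop("dyadsync_parameter_error", "ecg_fs must be >= 100 Hz")
  }
  stopifnot(abs(sum(state_occupancy) - 1) < 1e-9, all(state_occupancy >= 0))
  cfg <- list(seed = as.integer(seed), subsession_plan = subsession_plan,
              human_hr_mean = human_hr_mean, canine_hr_mean = canine_hr_mean,
              sdnn_target = sdnn_target, rmssd_target = rmssd_target,
              coupling_rho = coupling_rho, copy_prob_kappa = copy_prob_kappa,
              scr_rate = scr_rate,
              activity_bout_schedule = activity_bout_schedule,
              st_baseline = st_baseline, st_drift = st_drift,
              ecg_fs = ecg_fs, acc_fs = acc_fs, eda_fs = eda_fs, st_fs = st_fs,
              render_raw_ecg = isTRUE(render_raw_ecg),
              state_occupancy = state_occupancy, rater_error = rater_error,
              offscreen_rate = offscreen_rate,
              human_id = human_id, canine_id = canine_id, role = role,
              mdors_total = mdors_total, survey_effects = survey_effects)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_subsession_plan <- function() {
  data.frame(label = c("BASE", "INT1", "NEU1", "INT2", "POST"),
             duration = c(300, 600, 300, 600, 300))
}

#' @rdname sim_config
#' @export
default_survey_effects <- function() {
  list(arousal_shift = 1.0,   # construct units gained after an interaction
       valence_shift = 0.8,   # positive-valence gain after an interaction
       pa_shift = 0.5,        # PANAS positive-affect item-mean gain
       na_shift = -0.2,       # PANAS negative-affect item-mean change
       arousal_pa_load = 0.4) # shared session arousal -> PA loading
}

interaction_labels <- function(labels) labels %in% c("INT1", "INT2")

# ---------------------------------------------------------------------------

#' Simulate a complete synthetic CAI session with ground truth
#'
#' Generates one experimental day for a human-canine dyad: coupled
#' interbeat-interval processes (optionally rendered to raw ECG), tri-axial
#' accelerometer channels with activity bouts, human EDA and skin
#' temperature, per-second behavior-state streams observed by three raters,
#' and interstitial SAM/PANAS surveys (no survey precedes the baseline).
#' Canine channels are absent during neutral (NEU*) subsessions, when the
#' dog is removed from the research space.
#'
#' Physiological coupling: during interaction subsessions both subjects'
#' IBI fluctuations load with weight `sqrt(coupling_rho)` on a shared latent
#' Ornstein-Uhlenbeck driver sampled on a common 4 Hz clock, and with weight
#' `sqrt(1 - coupling_rho)` on private drivers with the same correlation
#' time, so smoothed heart-rate series correlate at `coupling_rho` in
#' expectation.
#'
#' @param config a [sim_config()].
#' @return List with elements `bundle` (a `cai_session`) and `truth`
#'   (ground-truth R-peak times, SCR times, per-second state sequences and
#'   the realized coupling).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  plan <- cfg$subsession_plan
  t_end <- cumsum(plan$duration)
  timeline <- data.frame(label = plan$label,
                         t_start = c(0, head(t_end, -1)), t_end = t_end)
  total <- max(timeline$t_end)
  is_int <- interaction_labels(timeline$label)
  is_neu <- grepl("^NEU", timeline$label)

  subjects <- data.frame(
    id = c(cfg$human_id, cfg$canine_id),
    species = c("human", "canine"),
    role = c(cfg$role, NA_character_), stringsAsFactors = FALSE)

  # --- latent coupled drivers on a common 4 Hz grid, per subsession -------
  grid_fs <- 4
  tau <- vapply(c("human", "canine"), function(sp) {
    hr <- if (sp == "human") cfg$human_hr_mean else cfg$canine_hr_mean
    phi <- ibi_phi(cfg$sdnn_target[[sp]], cfg$rmssd_target[[sp]])
    if (phi <= 0) {
      ds_stop("dyadsync_parameter_error",
              paste0("session coupling requires positive IBI lag-1 ",
                     "autocorrelation (rmssd < sdnn * sqrt(2)); got phi = %g ",
                     "for %s"), phi, sp)
    }
    -(60 / hr) / log(phi)
  }, numeric(1))
  tau_z <- sqrt(tau[["human"]] * tau[["canine"]])

  latents <- lapply(seq_len(nrow(timeline)), function(i) {
    dur <- timeline$t_end[i] - timeline$t_start[i]
    tg <- seq(0, dur, by = 1 / grid_fs)
    z  <- ou_path(tg, tau_z, stream_seed(cfg$seed, paste0("latent/z/", i)))
    eh <- ou_path(tg, tau[["human"]],
                  stream_seed(cfg$seed, paste0("latent/h/", i)))
    ec <- ou_path(tg, tau[["canine"]],
                  stream_seed(cfg$seed, paste0("latent/c/", i)))
    rho <- if (is_int[i]) cfg$coupling_rho else 0
    list(t = tg + timeline$t_start[i],
         human = sqrt(rho) * z + sqrt(1 - rho) * eh,
         canine = sqrt(rho) * z + sqrt(1 - rho) * ec)
  })
  latent_fun <- function(subject) {
    tt <- unlist(lapply(latents, `[[`, "t"))
    xx <- unlist(lapply(latents, `[[`, subject))
    keep <- !duplicated(tt)   # subsession boundaries share a grid point
    stats::approxfun(tt[keep], xx[keep], rule = 2)
  }
  x_h <- latent_fun("human")
  x_c <- latent_fun("canine")

  # --- beats ---------------------------------------------------------------
  truth <- list(r_peak_times = list(), scr_times = numeric(),
                state_sequence = list(), realized_coupling = cfg$coupling_rho)
  channels <- list()

  for (sp in c("human", "canine")) {
    sid <- if (sp == "human") cfg$human_id else cfg$canine_id
    hr <- if (sp == "human") cfg$human_hr_mean else cfg$canine_hr_mean
    base_ibi <- 60000 / hr
    xfun <- if (sp == "human") x_h else x_c
    placement <- if (sp == "human") "chest" else "harness"
    present <- if (sp == "human") rep(TRUE, nrow(timeline)) else !is_neu

    peaks <- numeric(0)
    for (i in which(present)) {
      t0 <- timeline$t_start[i]; t1 <- timeline$t_end[i]
      pk <- beat_times_segment(t0 + 0.3, t1, base_ibi, cfg$sdnn_target[[sp]],
                               xfun)
      peaks <- c(peaks, pk)
    }
    truth$r_peak_times[[sid]] <- peaks

    if (cfg$render_raw_ecg) {
      seg_t <- numeric(0); seg_v <- numeric(0)
      for (i in which(present)) {
        t0 <- timeline$t_start[i]; t1 <- timeline$t_end[i]
        pk <- peaks[peaks >= t0 & peaks < t1]
        if (length(pk) < 2L) next
        ibi_ms <- diff(pk) * 1000
        ec <- render_ecg(ibi_ms, cfg$ecg_fs,
                         seed = stream_seed(cfg$seed, paste0("ecg/", sp, i)),
                         t0 = pk[1] - t0)
        keep <- ec$t < (t1 - t0)
        seg_t <- c(seg_t, ec$t[keep] + t0)
        seg_v <- c(seg_v, ec$ecg[keep])
      }
      channels[[paste(sid, "ECG", placement, sep = ".")]] <-
        cai_channel(sid, "ECG", placement, cfg$ecg_fs, seg_t,
                    matrix(seg_v, ncol = 1))
    }

    # accelerometer
    seg_t <- numeric(0); seg_v <- NULL
    for (i in which(present)) {
      t0 <- timeline$t_start[i]
      dur <- timeline$t_end[i] - t0
      sch <- bout_schedule(cfg, sp, timeline$label[i], dur, i)
      env <- local({
        off <- t0
        function(tt) pmax(0.1, 1 + 0.6 * xfun(tt + off))
      })
      ac <- simulate_accelerometer(dur, cfg$acc_fs, sch,
             seed = stream_seed(cfg$seed, paste0("acc/", sp, i)),
             envelope = env)
      keep <- ac$t < dur
      seg_t <- c(seg_t, ac$t[keep] + t0)
      seg_v <- rbind(seg_v, ac$acc[keep, , drop = FALSE])
    }
    channels[[paste(sid, "ACC3", placement, sep = ".")]] <-
      cai_channel(sid, "ACC3", placement, cfg$acc_fs, seg_t, seg_v)
  }

  # --- human EDA + ST ------------------------------------------------------
  scr_times <- scr_event_times(cfg, timeline, is_int)
  truth$scr_times <- scr_times
  amp <- withr_seed(stream_seed(cfg$seed, "eda/amp"),
                    runif(length(scr_times), 0.2, 0.8))
  tonic_int <- int_indicator_fun(timeline, is_int)
  eda <- simulate_eda(total, cfg$eda_fs, scr_times, amp,
                      tonic_level = 2, drift = 0.02,
                      seed = stream_seed(cfg$seed, "eda/noise"))
  eda$eda <- eda$eda + 0.5 * tonic_int(eda$t)  # arousal-linked tonic shift
  channels[[paste(cfg$human_id, "EDA", "right_wrist", sep = ".")]] <-
    cai_channel(cfg$human_id, "EDA", "right_wrist", cfg$eda_fs, eda$t,
                matrix(eda$eda, ncol = 1))

  st <- simulate_st(total, cfg$st_fs, cfg$st_baseline, cfg$st_drift,
                    seed = stream_seed(cfg$seed, "st"))
  channels[[paste(cfg$human_id, "ST", "right_wrist", sep = ".")]] <-
    cai_channel(cfg$human_id, "ST", "right_wrist", cfg$st_fs, st$t,
                matrix(st$st, ncol = 1))

  # --- behavior ------------------------------------------------------------
  beh <- simulate_session_behavior(cfg, timeline, is_int, is_neu)
  truth$state_sequence <- beh$truth

  # --- surveys -------------------------------------------------------------
  surveys <- simulate_surveys(cfg, timeline)

  bundle <- cai_session(subjects, timeline, channels, beh$observed, surveys,
                        meta = list(seed = cfg$seed, role = cfg$role,
                                    coupling_rho = cfg$coupling_rho,
                                    copy_prob_kappa = cfg$copy_prob_kappa))
  list(bundle = bundle, truth = truth)
}

# Ornstein-Uhlenbeck path with unit marginal variance on time grid `tg`.
ou_path <- function(tg, tau, seed) {
  withr_seed(seed, {
    n <- length(tg)
    x <- numeric(n)
    x[1] <- rnorm(1)
    if (n > 1) {
      a <- exp(-diff(tg) / tau)
      e <- rnorm(n - 1)
      for (i in 2:n) x[i] <- a[i - 1] * x[i - 1] + sqrt(1 - a[i - 1]^2) * e[i - 1]
    }
    x
  })
}

# Sequential beat-time generation: IBI_i = base + sdnn * x(t_i), clipped at
# 30% of base so pathological latent draws cannot produce non-positive IBIs.
beat_times_segment <- function(t0, t1, base_ibi, sdnn, xfun) {
  n_max <- ceiling((t1 - t0) * 1000 / base_ibi * 1.6) + 8L
  out <- numeric(n_max)
  t <- t0; k <- 0L
  while (t < t1 && k < n_max) {
    k <- k + 1L
    out[k] <- t
    ibi <- max(0.3 * base_ibi, base_ibi + sdnn * xfun(t))
    t <- t + ibi / 1000
  }
  out[seq_len(k)]
}

# Default movement-bout schedule (subsession-relative times).
bout_schedule <- function(cfg, sp, label, dur, idx) {
  if (!is.null(cfg$activity_bout_schedule) &&
      !is.null(cfg$activity_bout_schedule[[label]])) {
    return(cfg$activity_bout_schedule[[label]])
  }
  seed <- stream_seed(cfg$seed, paste0("bouts/", sp, "/", idx))
  withr_seed(seed, {
    if (label %in% c("INT1", "INT2")) {
      amp0 <- if (sp == "human") 1.2 else 1.8
      starts <- seq(5, dur - 40, by = 60)
      starts <- starts + runif(length(starts), 0, 10)
      data.frame(start = starts,
                 end = pmin(dur, starts + runif(length(starts), 20, 35)),
                 amplitude = amp0 * runif(length(starts), 0.8, 1.2))
    } else {
      # sparse low-level movement at rest (more for the dog)
      amp0 <- if (sp == "human") 0.25 else 0.6
      n <- max(1L, floor(dur / 120))
      starts <- sort(runif(n, 0, max(1, dur - 15)))
      # enforce disjoint intervals
      ends <- pmin(dur, starts + 10)
      if (n > 1) for (i in 2:n) starts[i] <- max(starts[i], ends[i - 1] + 1)
      ends <- pmin(dur, starts + 10)
      keep <- ends > starts
      data.frame(start = starts[keep], end = ends[keep],
                 amplitude = rep(amp0, sum(keep)))
    }
  })
}

# Poisson SCR event times over the session; rate doubles during interactions.
scr_event_times <- function(cfg, timeline, is_int) {
  ev <- numeric(0)
  for (i in seq_len(nrow(timeline))) {
    rate <- cfg$scr_rate / 60 * if (is_int[i]) 2 else 1
    dur <- timeline$t_end[i] - timeline$t_start[i]
    n <- withr_seed(stream_seed(cfg$seed, paste0("scr/n/", i)),
                    stats::rpois(1, rate * dur))
    if (n > 0) {
      tt <- withr_seed(stream_seed(cfg$seed, paste0("scr/t/", i)),
                       sort(runif(n, 0, dur - 6)))
      ev <- c(ev, tt + timeline$t_start[i])
    }
  }
  sort(ev)
}

# Indicator-of-interaction as a function of time (for tonic EDA shift).
int_indicator_fun <- function(timeline, is_int) {
  function(t) {
    out <- numeric(length(t))
    for (i in which(is_int)) {
      out[t >= timeline$t_start[i] & t < timeline$t_end[i]] <- 1
    }
    out
  }
}

# Per-second behavior truth + three rater observations for the whole session.
simulate_session_behavior <- function(cfg, timeline, is_int, is_neu) {
  P_int <- occupancy_transition(cfg$state_occupancy, stickiness = 0.7)
  P_rest <- occupancy_transition(c(neg = 0.01, neu = 0.89, pos = 0.10), 0.7)
  n_total <- max(timeline$t_end)
  truth_h <- integer(n_total); truth_c <- integer(n_total)
  off_c <- logical(n_total)  # canine physically absent
  for (i in seq_len(nrow(timeline))) {
    secs <- (timeline$t_start[i] + 1):timeline$t_end[i]
    n <- length(secs)
    if (is_int[i]) {
      bc <- simulate_behavior_codes(n, P_int, cfg$copy_prob_kappa,
              seed = stream_seed(cfg$seed, paste0("beh/", i)))
      truth_h[secs] <- bc$human; truth_c[secs] <- bc$canine
    } else if (is_neu[i]) {
      truth_h[secs] <- 0L            # instructed neutral activity
      truth_c[secs] <- 0L
      off_c[secs] <- TRUE            # dog out of the research space
    } else {
      bc <- simulate_behavior_codes(n, P_rest, 0,
              seed = stream_seed(cfg$seed, paste0("beh/", i)))
      truth_h[secs] <- 0L            # human resting quietly
      truth_c[secs] <- bc$canine
    }
  }
  # shared out-of-view seconds (camera), in short segments
  off_shared <- withr_seed(stream_seed(cfg$seed, "beh/offscreen"), {
    z <- runif(n_total) < cfg$offscreen_rate / 4
    # dilate each hit into a ~4 s segment
    hits <- which(z)
    off <- logical(n_total)
    for (h in hits) off[h:min(n_total, h + 3L)] <- TRUE
    off
  })
  observed <- list()
  for (r in seq_along(cfg$rater_error)) {
    rid <- paste0("rater", r)
    observed[[rid]] <- list()
    observed[[rid]][[cfg$human_id]] <-
      rater_observe(truth_h, cfg$rater_error[r], which(off_shared),
                    stream_seed(cfg$seed, paste0("rater/", r, "/h")))
    observed[[rid]][[cfg$canine_id]] <-
      rater_observe(truth_c, cfg$rater_error[r],
                    which(off_shared | off_c),
                    stream_seed(cfg$seed, paste0("rater/", r, "/c")))
  }
  list(truth = list(human = truth_h, canine = truth_c), observed = observed)
}

# Row-stochastic matrix with given stationary distribution:
# P = (1 - s) * 1 pi' + s * I  (stationary = pi for any stickiness s).
occupancy_transition <- function(pi, stickiness = 0.7) {
  pi <- pi / sum(pi)
  (1 - stickiness) * matrix(pi, 3, 3, byrow = TRUE) + stickiness * diag(3)
}

# Interstitial surveys: one record set after every subsession (none before
# the baseline).  SAM orientation follows the source convention: larger
# SAM_V = more unhappiness, larger SAM_A = more calmness.
simulate_surveys <- function(cfg, timeline) {
  eff <- cfg$survey_effects
  a_s <- withr_seed(stream_seed(cfg$seed, "survey/session"), rnorm(1, 0, 0.5))
  rows <- list()
  for (i in seq_len(nrow(timeline))) {
    after_int <- interaction_labels(timeline$label[i])
    tp <- paste0("after_", timeline$label[i])
    sd_ <- stream_seed(cfg$seed, paste0("survey/", i))
    rec <- withr_seed(sd_, {
      arousal <- 0 + eff$arousal_shift * after_int + 0.6 * a_s + rnorm(1, 0, 0.4)
      valence <- 0 + eff$valence_shift * after_int + rnorm(1, 0, 0.4)
      sam_a <- clamp_int(3.5 - arousal, 1, 5)   # calmer = larger
      sam_v <- clamp_int(2.8 - valence, 1, 5)   # unhappier = larger
      pa_mu <- 2.6 + eff$pa_shift * after_int + eff$arousal_pa_load * a_s
      na_mu <- 1.7 + eff$na_shift * after_int
      pa_items <- clamp_int(rnorm(10, pa_mu, 0.7), 1, 5)
      na_items <- clamp_int(rnorm(10, na_mu, 0.5), 1, 5)
      sc <- score_panas(c(pa_items, na_items))
      data.frame(subject = cfg$human_id, timepoint = tp,
                 scale = c("SAM_V", "SAM_A", "PANAS_PA", "PANAS_NA"),
                 value = c(sam_v, sam_a, sc[["PA"]], sc[["NA"]]),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  mdors <- cfg$mdors_total
  if (is.null(mdors)) {
    bond <- (cfg$coupling_rho + cfg$copy_prob_kappa) / 2
    mdors <- withr_seed(stream_seed(cfg$seed, "survey/mdors"),
                        round(115 - 55 * bond + rnorm(1, 0, 4)))
  }
  rbind(out, data.frame(subject = cfg$human_id, timepoint = "session",
                        scale = "MDORS", value = mdors,
                        stringsAsFactors = FALSE))
}

clamp_int <- function(x, lo, hi) as.integer(pmin(hi, pmax(lo, round(x))))
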