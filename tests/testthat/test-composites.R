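# Directional heatmap, coherence, correlation matrix, combined table.

mk_me <- function(values, metric = "HR", subject = "H1",
                  placement = "chest", subsession = "INT1") {
  data.frame(subsession = subsession, epoch = seq_along(values) - 1L,
             subject = subject, placement = placement, metric = metric,
             value = values, stringsAsFactors = FALSE)
}

test_that("epoch deltas: signs, tie rule, missing propagation", {
  d <- epoch_deltas(mk_me(c(3, 5, 4)))
  expect_equal(d$delta, c(NA, 1, -1))
  d2 <- epoch_deltas(mk_me(c(2, 2)))
  expect_equal(d2$delta, c(NA, -1))  # ties render as decrease
  expect_equal(attr(d2, "ties"), 1)
  d3 <- epoch_deltas(mk_me(c(1, NA, 3)))
  expect_true(all(is.na(d3$delta)))
  dc <- epoch_deltas(mk_me(rep(7, 5)))
  expect_equal(attr(dc, "ties"), 4)
})

test_that("deltas are computed within each series even from shuffled rows", {
  set.seed(17)
  me <- rbind(mk_me(c(1, 3, 2, 5), "HR"),
              mk_me(c(9, 7, 8, 6), "SDNN"),
              mk_me(c(4, 4, 1, 2), "HR", subject = "C1",
                    placement = "harness"))
  d <- epoch_deltas(me[sample(nrow(me)), ])
  pick <- function(subj, met) {
    s <- d[d$subject == subj & d$metric == met, ]
    s$delta[order(s$epoch)]
  }
  expect_equal(pick("H1", "HR"), c(NA, 1, -1, 1))
  expect_equal(pick("H1", "SDNN"), c(NA, -1, 1, -1))
  expect_equal(pick("C1", "HR"), c(NA, -1, -1, 1))  # tie -> decrease
})

test_that("heatmap composes deltas with metric orientation", {
  me <- rbind(mk_me(seq(50, 101, by = 3), "SDNN"),
              mk_me(seq(80, 131, by = 3), "HR"),
              mk_me(seq(131, 80, by = -3), "HR", subject = "C1",
                    placement = "harness"))
  deltas <- epoch_deltas(me)
  hm <- build_heatmap(deltas, "INT1", start_epoch = 0)
  expect_equal(dim(hm$matrix), c(3, 17))
  # SDNN rising -> positive valence cells; HR rising -> arousal increase
  expect_true(all(hm$matrix["H1_SDNN", ] == 1))
  expect_true(all(hm$matrix["H1_HR", ] == 1))
  expect_true(all(hm$matrix["C1_HR", ] == -1))
  # row order: valence block before arousal, human before canine
  expect_equal(rownames(hm$matrix), c("H1_SDNN", "H1_HR", "C1_HR"))
  expect_equal(hm$rows$dimension, c("valence_stress", "arousal", "arousal"))

  # orientation flip is an involution affecting exactly that row
  dm <- default_direction_map()
  dm$orientation[dm$metric == "HR"] <- -1
  hm2 <- build_heatmap(deltas, "INT1", start_epoch = 0, direction_map = dm)
  expect_true(all(hm2$matrix["H1_HR", ] == -1))
  expect_true(all(hm2$matrix["C1_HR", ] == 1))
  expect_identical(hm2$matrix["H1_SDNN", ], hm$matrix["H1_SDNN", ])
})

test_that("heatmap cell count is metrics x 17 and coherence counts shares", {
  set.seed(3)
  mets <- c("HR", "SDNN", "RMSSD", "EDA_mean", "EDA_max", "ST")
  me <- do.call(rbind, lapply(mets, function(m) mk_me(rnorm(18, 100), m)))
  hm <- build_heatmap(epoch_deltas(me), "INT1", 0)
  expect_equal(sum(!is.na(hm$matrix)), length(mets) * 17)

  # arousal block has 4 rows (HR, EDA_mean, EDA_max, ST), valence has 2
  hm$matrix[hm$rows$dimension == "arousal", 4] <- c(1, 1, 1, -1)
  expect_equal(coherence(hm, 4, "arousal"), 0.75)
  hm$matrix[hm$rows$dimension == "valence_stress", 4] <- c(1, -1)
  expect_equal(coherence(hm, 4, "valence_stress"), 0.5)
  hm$matrix[, 5] <- 1
  expect_equal(coherence(hm, 5, "arousal"), 1)
  hm$matrix[hm$rows$dimension == "valence_stress", 6] <- c(1, NA)
  expect_true(is.na(coherence(hm, 6, "valence_stress")))
})

test_that("correlation matrix is symmetric, unit-diagonal, bounded", {
  set.seed(9)
  n <- 20
  a <- rnorm(n)
  feats <- data.frame(a = a, b = a + rnorm(n, 0, 0.3), c = rnorm(n),
                      dup = a)
  m <- correlation_matrix(feats)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 1))
  expect_true(all(m >= -1 & m <= 1, na.rm = TRUE))
  expect_equal(m["a", "dup"], 1)
  expect_gt(m["a", "b"], 0.8)
  expect_error(correlation_matrix(feats[1:2, ]), ">= 3")
})

test_that("middle-minute epochs are the 6 central ones", {
  expect_equal(middle_minute_epochs(60), 27:32)
  expect_equal(middle_minute_epochs(24), 9:14)
})

test_that("combined pair table separates bonded from unbonded dyads", {
  plan <- data.frame(label = c("BASE", "INT1"), duration = c(60, 360))
  run_one <- function(bond, seed) {
    occ_pos <- 0.10 + 0.25 * bond
    cfg <- sim_config(seed = seed, coupling_rho = bond,
                      copy_prob_kappa = 0.9 * bond,
                      state_occupancy = c(neg = 0.05 * (1 - bond),
                                          neu = 1 - occ_pos - 0.05 * (1 - bond),
                                          pos = occ_pos),
                      render_raw_ecg = FALSE, subsession_plan = plan,
                      role = if (bond > 0.5) "owner" else "stranger")
    sim <- simulate_session(cfg)
    an <- analyze_session(sim$bundle, sim$truth)
    combined_pair_table(an$sync, an$becodes, sim$bundle$surveys, an$bundle)
  }
  # average positive-state share over a few seeds to damp chain noise
  pos_share <- function(bond) {
    mean(sapply(1:3, function(s) {
      tb <- run_one(bond, 600 + s)
      mean(tb$value[grepl("becode_.*_pos_pct", tb$entry)], na.rm = TRUE)
    }))
  }
  expect_gt(pos_share(0.9), pos_share(0.2))
  tb <- run_one(0.9, 601)
  expect_true("MDORS" %in% tb$entry)
  expect_true(any(grepl("Pcorr_HR", tb$entry)))
  expect_true(any(grepl("same_state_pct", tb$entry)))
})

test_that("raw snapshot plot renders to file and flags stray annotations", {
  ec_h <- render_ecg(rep(800, 12), 250, noise_sd = 0.01)
  ec_c <- render_ecg(rep(630, 15), 250, noise_sd = 0.01)
  ch_h <- cai_channel("H1", "ECG", "chest", 250, ec_h$t,
                      matrix(ec_h$ecg, ncol = 1))
  ch_c <- cai_channel("C1", "ECG", "harness", 250, ec_c$t,
                      matrix(ec_c$ecg, ncol = 1))
  f <- tempfile(fileext = ".png")
  expect_warning(
    plot_raw_snapshot(ch_h, ch_c, window = c(0, 8),
                      annotations = data.frame(start = 20, end = 21,
                                               label = "late"),
                      file = f),
    "outside")
  expect_true(file.exists(f) && file.size(f) > 0)
  unlink(f)
})
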