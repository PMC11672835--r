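# HRV formulas, activity metrics, EDA decomposition, beat detection,
# epoch (ME) and rolling (RE) extraction.

test_that("time-domain HRV matches hand-evaluated closed forms", {
  h <- hrv_time_domain(c(800, 850, 790, 820))
  expect_equal(h[["SDNN"]], sqrt(2100 / 3), tolerance = 1e-9)
  expect_equal(h[["RMSSD"]], sqrt((50^2 + 60^2 + 30^2) / 3), tolerance = 1e-9)
  expect_equal(h[["SDNN_RMSSD"]], sqrt(2100 / 3) / sqrt(7000 / 3),
               tolerance = 1e-6)

  h2 <- hrv_time_domain(c(800, 900))
  expect_equal(h2[["SDNN"]], sqrt(5000), tolerance = 1e-9)  # 70.711
  expect_equal(h2[["RMSSD"]], 100)

  hc <- hrv_time_domain(rep(800, 10))
  expect_equal(hc[["SDNN"]], 0)
  expect_equal(hc[["RMSSD"]], 0)
  expect_true(is.na(hc[["SDNN_RMSSD"]]))  # division guard
})

test_that("MAD and IMA match direct summation and are homogeneous", {
  # square wave on x: MAD_x = 1, IMA = 1
  ax <- rep(c(1, -1), 50)
  acc <- cbind(ax, 0, 0)
  r <- acc_mad_ima(acc, fs = 10)
  expect_equal(r[["MAD_x"]], 1)
  expect_equal(r[["IMA"]], 1)
  expect_equal(r[["MAD_y"]], 0)

  z <- acc_mad_ima(matrix(0, 100, 3), 10)
  expect_true(all(z == 0))

  a2 <- matrix(rnorm(300), 100, 3)
  r1 <- acc_mad_ima(a2, 32)
  r2 <- acc_mad_ima(2 * a2, 32)
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
})

test_that("beat detection recovers truth peaks on clean synthetic ECG", {
  for (sp in c("human", "canine")) {
    hr <- if (sp == "human") 75 else 95
    ibi <- simulate_ibi_series(hr, 50, 40, 300, seed = 7)
    ec <- render_ecg(ibi, 250, seed = 8, noise_sd = 0.05)
    ch <- cai_channel("S", "ECG", "chest", 250, ec$t,
                      matrix(ec$ecg, ncol = 1))
    bs <- detect_r_peaks(ch, sp)
    nearest <- vapply(ec$r_peak_times, function(tt)
      min(abs(bs$r_peak_times - tt)), numeric(1))
    expect_gte(mean(nearest <= 0.020), 0.99)
    hr_est <- 60000 / mean(bs$ibi[bs$valid])
    hr_true <- 60000 / mean(diff(ec$r_peak_times) * 1000)
    expect_lt(abs(hr_est - hr_true), 1)
  }
  # flatline yields no beats
  t <- seq(0, 40, by = 1 / 250)
  flat <- cai_channel("S", "ECG", "chest", 250, t,
                      matrix(0, length(t), 1))
  expect_equal(length(detect_r_peaks(flat, "human")$r_peak_times), 0)
})

test_that("IBI artifact rejection flags ectopic-like deviations", {
  pk <- cumsum(rep(0.8, 100))
  pk[50] <- pk[50] - 0.3  # one early beat: short IBI then long IBI
  bs <- new_beat_series(pk, "human")
  expect_false(all(bs$valid[48:50]))
  expect_true(mean(bs$valid) > 0.9)
})

test_that("EDA decomposition counts injected SCRs, ramps give none", {
  e <- simulate_eda(120, 4, scr_times = c(30, 34, 38), scr_amplitudes = 0.5,
                    tonic_level = 2, noise_sd = 0.002, seed = 1)
  ch <- cai_channel("H1", "EDA", "right_wrist", 4, e$t, matrix(e$eda, ncol = 1))
  dec <- eda_decompose_and_peaks(ch)
  in_epoch <- dec$scr_peak_times[dec$scr_peak_times >= 30 &
                                   dec$scr_peak_times < 45]
  expect_equal(length(in_epoch), 3)

  ramp <- simulate_eda(300, 4, drift = 0.2, tonic_level = 1, noise_sd = 0)
  chr <- cai_channel("H1", "EDA", "right_wrist", 4, ramp$t,
                     matrix(ramp$eda, ncol = 1))
  decr <- eda_decompose_and_peaks(chr)
  expect_equal(length(decr$scr_peak_times), 0)
  expect_lt(max(abs(decr$phasic[20:1180])), 1e-6)
})

test_that("ME table: HR from in-epoch beats, means, missing propagation", {
  # constant IBI of 815 ms -> every full epoch's HR = 60000/815
  pk <- seq(0.2, 120, by = 0.815)
  bs <- new_beat_series(pk, "human")
  tl <- data.frame(label = "BASE", t_start = 0, t_end = 120)
  grid <- build_epoch_grid(tl)
  t4 <- seq(0, 119.99, by = 0.25)
  st_vals <- 30 + (t4 / 120)  # 30 -> 31 linear
  b <- cai_session(
    data.frame(id = "H1", species = "human", role = NA), tl,
    list(st = cai_channel("H1", "ST", "right_wrist", 4, t4,
                          matrix(st_vals, ncol = 1))))
  b <- preprocess_session(b)
  beats <- list(H1 = bs)
  me <- epoch_me(b, grid, beats)
  hr <- me$value[me$metric == "HR"]
  expect_true(all(abs(hr - 60000 / 815) < 1e-9))
  # ST epoch mean of a linear ramp is its midpoint value
  st <- me$value[me$metric == "ST"]
  mids <- 30 + (grid$t0 + 5 - 0.125) / 120  # sample-average of the ramp
  expect_equal(st, mids, tolerance = 1e-2)
  # fully masked epoch -> missing
  b2 <- b
  b2$channels$st$mask[1:44] <- TRUE  # 11 s of 4 Hz samples
  me2 <- epoch_me(b2, grid, beats)
  expect_true(is.na(me2$value[me2$metric == "ST"][1]))
  expect_false(is.na(me2$value[me2$metric == "ST"][3]))
  # invariant: EDA_max >= EDA_mean, variability metrics >= 0
  expect_true(all(me$value[me$metric %in% c("SDNN", "RMSSD")] >= 0,
                  na.rm = TRUE))
})

test_that("RE series: constant record, ME agreement, edge flags", {
  pk <- seq(0.5, 300, by = 0.8)
  bs <- new_beat_series(pk, "human")
  re <- rolling_re_beats(bs, "HR", 0, 300)
  inner <- !re$edge
  expect_true(any(inner))
  expect_true(all(abs(re$value[inner] - 60000 / 800) < 1e-9))
  # edge policy: ticks whose window is truncated are flagged
  expect_true(all(re$edge[re$t < 30.5]))
  expect_true(all(!re$edge[re$t > 31 & re$t < 269]))

  # stationary noisy record: RE averaged over an aligned epoch ~ overall HR
  ibi <- simulate_ibi_series(75, 15, 12, 300, seed = 3)
  pk2 <- 0.2 + c(0, cumsum(ibi)) / 1000
  bs2 <- new_beat_series(pk2, "human")
  re2 <- rolling_re_beats(bs2, "HR", 0, 300)
  re_epoch <- mean(re2$value[re2$t >= 140 & re2$t < 150])
  hr_all <- 60000 / mean(ibi)
  expect_lt(abs(re_epoch - hr_all) / hr_all, 0.01)

  # windowed SDNN/RMSSD agree with direct evaluation at a probe tick
  re_s <- rolling_re_beats(bs2, "SDNN", 0, 300)
  probe <- which(abs(re_s$t - 150) < 1e-9)
  stopifnot(all(bs2$valid))
  w <- which(pk2[-1] >= 120 & pk2[-1] < 180)  # IBIs by closing peak time
  expect_equal(re_s$value[probe], oracle_sdnn(ibi[w]), tolerance = 1e-9)
  re_r <- rolling_re_beats(bs2, "RMSSD", 0, 300)
  jm <- seq_len(length(ibi) - 1)          # pair j: (ibi[j], ibi[j+1])
  sel <- pk2[jm + 2] >= 120 & pk2[jm + 2] < 180  # timestamped at pk[j+2]
  expect_equal(re_r$value[probe],
               sqrt(mean((ibi[jm[sel] + 1] - ibi[jm[sel]])^2)),
               tolerance = 1e-9)
})
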