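# Synthetic dyad generator: parameter recovery, determinism, coupling.

test_that("IBI simulator hits SDNN/RMSSD targets and degenerates cleanly", {
  # degenerate zero-variance case
  ibi0 <- simulate_ibi_series(75, sdnn = 0, rmssd = 0, duration = 60, seed = 3)
  expect_true(all(ibi0 == 60000 / 75))
  expect_equal(oracle_rmssd(ibi0), 0)

  # infeasible pair names the bound
  expect_error(simulate_ibi_series(75, sdnn = 10, rmssd = 40, duration = 60),
               "2 \\* sdnn")

  # stochastic targets averaged over seeds
  sdnns <- rmssds <- numeric(20)
  for (s in 1:20) {
    ibi <- simulate_ibi_series(75, 50, 40, 300, seed = s)
    sdnns[s] <- oracle_sdnn(ibi)
    rmssds[s] <- oracle_rmssd(ibi)
  }
  expect_lt(abs(mean(sdnns) - 50) / 50, 0.15)
  # AR(1) identity: RMSSD/SDNN ratio should track the target ratio 0.8
  expect_lt(abs(mean(rmssds / sdnns) - 0.8), 0.1)
})

test_that("rendered ECG places one dominant R wave per beat at truth times", {
  ec <- render_ecg(rep(800, 10), fs = 250, noise_sd = 0)
  # R maxima spacing: 800 ms = 200 samples
  expect_equal(length(ec$r_peak_times), 10)
  idx <- vapply(ec$r_peak_times, function(tt) which.min(abs(ec$t - tt)),
                integer(1))
  expect_true(all(diff(idx) == 200))
  # noiseless: argmax in each beat window equals the recorded truth sample
  for (k in seq_along(ec$r_peak_times)) {
    win <- which(abs(ec$t - ec$r_peak_times[k]) <= 0.3)
    expect_equal(ec$t[win[which.max(ec$ecg[win])]], ec$r_peak_times[k])
  }
  # peak count via independent oracle: local maxima above half the R amplitude
  ibi <- simulate_ibi_series(90, 40, 30, 60, seed = 5)
  ec2 <- render_ecg(ibi, 250, noise_sd = 0)
  x <- ec2$ecg
  n <- length(x)
  peaks <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                   x[2:(n - 1)] > 0.5) + 1L
  expect_equal(length(peaks), length(ibi))
  expect_error(render_ecg(rep(800, 5), fs = 50), "100 Hz")
})

test_that("EDA simulator: flat, ramp and SCR-count behavior", {
  flat <- simulate_eda(60, 4, tonic_level = 2, drift = 0, noise_sd = 0)
  expect_true(all(abs(flat$eda - 2) < 1e-12))

  ramp <- simulate_eda(600, 4, drift = 0.1, tonic_level = 1, noise_sd = 0)
  first_min <- mean(ramp$eda[ramp$t < 60])
  last_min <- mean(ramp$eda[ramp$t >= 540])
  expect_gt(last_min - first_min, 0.75)
  expect_lt(last_min - first_min, 1.0)

  withscr <- simulate_eda(60, 4, scr_times = c(10, 25, 40),
                          scr_amplitudes = 0.5, noise_sd = 0)
  ph <- withscr$eda - 2  # tonic level, drift 0
  n <- length(ph)
  super <- which(ph[2:(n - 1)] > ph[1:(n - 2)] & ph[2:(n - 1)] >= ph[3:n] &
                   ph[2:(n - 1)] > 0.25) + 1L
  expect_equal(length(super), 3)
  # each injected SCR produces a rise of at least 0.9 x amplitude
  for (tt in c(10, 25, 40)) {
    seg <- ph[withscr$t >= tt & withscr$t <= tt + 5]
    expect_gte(max(seg), 0.45)
  }
  expect_error(simulate_eda(10, 4, scr_times = 1, scr_amplitudes = -1),
               "negative")
})

test_that("accelerometer bouts elevate exactly the scheduled epochs", {
  sch <- data.frame(start = c(20, 60), end = c(30, 70), amplitude = 2)
  ac <- simulate_accelerometer(100, 32, sch, seed = 4, rest_sd = 0.02)
  dyn <- ac$acc; dyn[, 3] <- dyn[, 3] - 9.81
  epoch_of <- floor(ac$t / 10)
  ima <- tapply(rowSums(abs(dyn)), epoch_of, mean)[1:10]
  bout_epochs <- c(3, 7)  # epochs [20,30) and [60,70), 1-indexed
  expect_true(all(ima[bout_epochs] > 5 * max(ima[-bout_epochs])))
  # rest-only record stays under the noise floor
  rest <- simulate_accelerometer(50, 32, NULL, seed = 5, rest_sd = 0.02)
  rd <- rest$acc; rd[, 3] <- rd[, 3] - 9.81
  expect_lt(mean(rowSums(abs(rd))), 0.2)
  expect_error(
    simulate_accelerometer(100, 32,
      data.frame(start = c(0, 5), end = c(10, 15), amplitude = 1)),
    "overlap")
})

test_that("behavior coupling: copy probability governs same-state fraction", {
  P <- matrix(1 / 3, 3, 3)
  full <- simulate_behavior_codes(500, P, 1, seed = 9)
  expect_identical(full$human, full$canine)

  zero <- simulate_behavior_codes(5000, P, 0, seed = 9)
  # independent uniform chains agree ~1/3 of the time
  expect_lt(abs(mean(zero$human == zero$canine) - 1 / 3), 0.04)

  k8 <- simulate_behavior_codes(5000, P, 0.8, seed = 9)
  agree <- mean(k8$human == k8$canine)
  # expected agreement = kappa + (1 - kappa) * chance
  expect_lt(abs(agree - (0.8 + 0.2 / 3)), 0.04)

  bad <- matrix(c(0.5, 0.5, 0.1, rep(1 / 3, 6)), 3, 3, byrow = TRUE)
  expect_error(simulate_behavior_codes(10, bad, 0.5), "sum to 1")
})

test_that("same seed and config give byte-identical sessions", {
  cfg <- sim_config(seed = 11, render_raw_ecg = FALSE,
                    subsession_plan = tiny_plan())
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("canine heart rate exceeds human in every subsession", {
  cfg <- sim_config(seed = 2, render_raw_ecg = FALSE,
                    subsession_plan = tiny_plan())
  sim <- simulate_session(cfg)
  tl <- sim$bundle$timeline
  for (i in seq_len(nrow(tl))) {
    h <- sim$truth$r_peak_times$H1
    c_ <- sim$truth$r_peak_times$C1
    h <- h[h >= tl$t_start[i] & h < tl$t_end[i]]
    c_ <- c_[c_ >= tl$t_start[i] & c_ < tl$t_end[i]]
    if (length(c_) < 2) next  # dog absent (NEU)
    expect_gt(60 / mean(diff(c_)), 60 / mean(diff(h)))
  }
})

test_that("surveys appear only after subsessions, none before baseline", {
  cfg <- sim_config(seed = 3, render_raw_ecg = FALSE,
                    subsession_plan = tiny_plan())
  sim <- simulate_session(cfg)
  tps <- unique(sim$bundle$surveys$timepoint)
  expect_setequal(tps, c(paste0("after_", tiny_plan()$label), "session"))
  expect_false("before_BASE" %in% tps)
})
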