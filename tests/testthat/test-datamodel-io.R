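# Data model, epoch grid, session IO, synchronization.

test_that("epoch grid follows the floor rule and partitions subsessions", {
  tl <- data.frame(label = c("BASE", "INT1", "NEU1"),
                   t_start = c(0, 600, 1200), t_end = c(600, 1200, 1505))
  g <- build_epoch_grid(tl)
  expect_equal(sum(g$subsession == "INT1"), 60)
  expect_equal(sum(g$subsession == "NEU1"), 30)  # 5 s tail dropped
  # partition: disjoint, ordered, within subsession bounds
  expect_true(all(g$t1 - g$t0 == 10))
  expect_true(all(diff(g$t0) > 0))
  for (i in seq_len(nrow(tl))) {
    gs <- g[g$subsession == tl$label[i], ]
    expect_equal(gs$t0[1], tl$t_start[i])
    expect_lte(max(gs$t1), tl$t_end[i])
    expect_true(all(diff(gs$t0) == 10))
  }
  # degenerate: sub-epoch subsession yields no epochs with a warning
  tl9 <- data.frame(label = "BASE", t_start = 0, t_end = 9)
  expect_warning(g9 <- build_epoch_grid(tl9), "shorter than one epoch")
  expect_equal(nrow(g9), 0)
})

test_that("session write/read round-trips values and metadata", {
  cfg <- sim_config(seed = 21, render_raw_ecg = FALSE,
                    subsession_plan = tiny_plan())
  sim <- simulate_session(cfg)
  dir <- tempfile("sess")
  write_session(sim$bundle, dir, truth = sim$truth)
  back <- read_session(dir)
  expect_equal(back$subjects, sim$bundle$subjects)
  expect_equal(back$timeline, sim$bundle$timeline)
  expect_setequal(names(back$channels), names(sim$bundle$channels))
  for (nm in names(back$channels)) {
    expect_equal(back$channels[[nm]]$t, sim$bundle$channels[[nm]]$t,
                 tolerance = 1e-12)
    expect_equal(back$channels[[nm]]$values, sim$bundle$channels[[nm]]$values,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(back$behavior, sim$bundle$behavior)
  expect_equal(back$surveys$value, sim$bundle$surveys$value)
  unlink(dir, recursive = TRUE)
})

test_that("IO validation names missing files and bad rows", {
  cfg <- sim_config(seed = 22, render_raw_ecg = FALSE,
                    subsession_plan = tiny_plan())
  sim <- simulate_session(cfg)
  dir <- tempfile("sess")
  write_session(sim$bundle, dir)
  # remove a referenced channel file
  f <- list.files(file.path(dir, "channels"), full.names = TRUE)[1]
  file.remove(f)
  expect_error(read_session(dir), "missing channel file")
  # duplicated timestamp triggers a named monotonicity error
  write_session(sim$bundle, dir)
  f <- list.files(file.path(dir, "channels"), full.names = TRUE)[1]
  df <- read.csv(f)
  df$time_s[5] <- df$time_s[4]
  write.csv(df, f, row.names = FALSE)
  expect_error(read_session(dir), "non-monotone time at row 5")
  unlink(dir, recursive = TRUE)
})

test_that("synchronize is near-identity on uniform data and idempotent", {
  t <- seq(0, 10, by = 0.01)
  ch <- cai_channel("H1", "EDA", "right_wrist", 100, t,
                    matrix(sin(t), ncol = 1))
  tl <- data.frame(label = "BASE", t_start = 0, t_end = 10.5)
  b <- cai_session(data.frame(id = "H1", species = "human", role = NA),
                   tl, list(e = ch))
  s1 <- synchronize(b)
  expect_equal(s1$channels$e$values[, 1],
               sin(s1$channels$e$t), tolerance = 1e-6)
  s2 <- synchronize(s1)
  expect_equal(s2$channels$e$values, s1$channels$e$values, tolerance = 1e-12)
  expect_equal(s2$channels$e$t, s1$channels$e$t, tolerance = 1e-12)
})

test_that("synchronize realigns offset channels and masks long gaps", {
  # impulse train offset by +0.05 s at 200 Hz gets shifted back onto grid
  fs <- 200
  t <- seq(0, 10, by = 1 / fs) + 0.05
  x <- numeric(length(t))
  x[seq(1, length(t), by = fs)] <- 1  # impulses at t = 0.05, 1.05, ...
  tl <- data.frame(label = "BASE", t_start = 0, t_end = 11)
  b <- cai_session(data.frame(id = "H1", species = "human", role = NA),
                   tl, list(e = cai_channel("H1", "ECG", "chest", fs, t,
                                            matrix(x, ncol = 1))))
  s <- synchronize(b)
  ts <- s$channels$e$t
  # grid is anchored at the timeline origin: ticks are multiples of 1/fs
  expect_true(all(abs(ts * fs - round(ts * fs)) < 1e-9))
  # interpolated peak mass sits at the samples bracketing each impulse time
  v <- s$channels$e$values[, 1]
  pk <- ts[which(v > 0.5)]
  expect_true(all(abs((pk %% 1) - 0.05) < 1 / fs + 1e-9))

  # a 5 s dropout is masked, not interpolated
  keep <- !(t > 3 & t < 8)
  b2 <- cai_session(data.frame(id = "H1", species = "human", role = NA),
                    tl, list(e = cai_channel("H1", "ECG", "chest", fs,
                                             t[keep], matrix(x[keep], ncol = 1))))
  s2 <- synchronize(b2)
  gap <- s2$channels$e$t > 3.1 & s2$channels$e$t < 7.9
  expect_true(all(s2$channels$e$mask[gap]))
})

test_that("channel and bundle validation reject malformed input", {
  expect_error(cai_channel("H", "ECG", "chest", 10, c(0, 1, 1, 2),
                           matrix(0, 4, 1)), "non-monotone")
  expect_error(cai_channel("H", "ACC3", "chest", 10, 0:3, matrix(0, 4, 1)),
               "3 value column")
  tl <- data.frame(label = c("A", "B"), t_start = c(0, 5), t_end = c(6, 10))
  expect_error(validate_timeline <- dyadsync:::validate_timeline(tl),
               "overlapping")
})
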