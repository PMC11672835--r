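# PPSA coding rules, state percentages, XNOR synchrony, Cohen's kappa.

grid1 <- function(n = 1) {
  build_epoch_grid(data.frame(label = "INT1", t_start = 0, t_end = 10 * n))
}

test_that("PPSA majority/tie/offscreen rules match stated examples", {
  g <- grid1()
  expect_equal(ppsa_code(c(rep("1", 6), rep("0", 4)), g), 1L)
  expect_equal(ppsa_code(c(rep("0", 5), rep("1", 5)), g), 0L)   # 5/5 -> neutral
  expect_equal(ppsa_code(c(rep("-1", 5), rep("1", 5)), g), 0L)  # pos/neg tie
  expect_true(is.na(ppsa_code(rep("offscreen", 10), g)))
  # 4 offscreen seconds are excluded, majority over the rest
  expect_equal(ppsa_code(c(rep("offscreen", 4), rep("-1", 4), rep("0", 2)), g),
               -1L)
  expect_true(is.na(ppsa_code(c(rep("offscreen", 5), rep("1", 5)), g)))
  expect_error(ppsa_code(rep("0", 5), g), "label stream")
})

test_that("PPSA rule agrees with independent oracle over all compositions", {
  # every composition of 10 seconds into (pos, neu, neg, offscreen)
  g <- grid1()
  for (npos in 0:10) for (nneu in 0:(10 - npos)) {
    for (nneg in 0:(10 - npos - nneu)) {
      noff <- 10 - npos - nneu - nneg
      secs <- c(rep("1", npos), rep("0", nneu), rep("-1", nneg),
                rep("offscreen", noff))
      expected <- oracle_ppsa(secs)
      got <- ppsa_code(secs, g)
      expect_identical(got, expected)
      # order within the epoch is irrelevant
      got_shuffled <- ppsa_code(sample(secs), g)
      expect_identical(got_shuffled, expected)
    }
  }
})

test_that("state percentages exclude indeterminate epochs and sum to 100", {
  expect_equal(state_percentages(c(1, 1, 0, 0)),
               c(pos = 50, neu = 50, neg = 0))
  p <- state_percentages(c(1, 0, NA, -1))
  expect_equal(unname(p), rep(100 / 3, 3), tolerance = 1e-9)
  expect_equal(sum(p), 100, tolerance = 1e-9)
  expect_equal(state_percentages(c(0, 0, 0)),
               c(pos = 0, neu = 100, neg = 0))
  expect_error(state_percentages(c(NA, NA)), "indeterminate")
})

test_that("XNOR same-state percentage is symmetric and exact", {
  expect_equal(same_state_pct(c(1, 0, -1), c(1, 0, -1)), 100)
  h <- c(1, 0, 0, -1); c_ <- c(1, 0, 1, 0)
  expect_equal(same_state_pct(h, c_), 50)
  expect_equal(same_state_pct(c_, h), same_state_pct(h, c_))
  expect_error(same_state_pct(c(NA, NA), c(1, 0)), "jointly determinate")
  # equals 100 iff determinate codes identical
  expect_lt(same_state_pct(c(1, 1, NA), c(1, 0, 1)), 100)
  expect_equal(same_state_pct(c(1, 1, NA), c(1, 1, 0)), 100)
})

test_that("Cohen's kappa: hand contingency, chance level, oracle agreement", {
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 0, 0, 1)), 0)
  expect_equal(cohens_kappa(c(1, 0, -1, 1), c(1, 0, -1, 1)), 1)
  # expected-agreement-1 guard
  expect_true(is.na(cohens_kappa(rep(1, 5), rep(1, 5))))
  # independent uniform codes -> kappa near 0
  set.seed(42)
  a <- sample(c(-1, 0, 1), 3000, replace = TRUE)
  b <- sample(c(-1, 0, 1), 3000, replace = TRUE)
  expect_lt(abs(cohens_kappa(a, b)), 0.05)
  # random-instance agreement with the brute-force oracle
  for (i in 1:50) {
    a <- sample(c(-1, 0, 1), 30, replace = TRUE)
    b <- ifelse(runif(30) < 0.6, a, sample(c(-1, 0, 1), 30, replace = TRUE))
    if (abs(1 - sum(sapply(c(-1, 0, 1), function(k)
      mean(a == k) * mean(b == k)))) < 1e-12) next
    expect_equal(cohens_kappa(a, b), oracle_kappa(a, b), tolerance = 1e-9)
  }
  # multi-rater mean pairwise kappa
  expect_equal(multi_rater_kappa(list(a, a, a)), 1)
})

test_that("XNOR synchrony on kappa-coupled chains recovers >= kappa", {
  g <- build_epoch_grid(data.frame(label = "INT1", t_start = 0, t_end = 3000))
  P <- dyadsync:::occupancy_transition(c(0.05, 0.65, 0.30), 0.6)
  for (k in c(0.5, 0.9)) {
    bc <- simulate_behavior_codes(3000, P, k, seed = 100 + k * 10)
    ch <- ppsa_code(as.character(bc$human), g)
    cc <- ppsa_code(as.character(bc$canine), g)
    # epoch-majority smoothing keeps agreement at or above the copy rate
    expect_gte(same_state_pct(ch, cc), 100 * k - 8)
  }
})
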