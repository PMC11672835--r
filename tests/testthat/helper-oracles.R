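# Independent brute-force oracles used across the suite.  These deliberately
# re-derive each quantity from its definition, without touching the package's
# computation paths.

oracle_sdnn <- function(ibi) {
  n <- length(ibi)
  if (n < 2) return(NA_real_)
  m <- sum(ibi) / n
  sqrt(sum((ibi - m)^2) / (n - 1))
}

oracle_rmssd <- function(ibi) {
  d <- ibi[-1] - ibi[-length(ibi)]
  if (!length(d)) return(NA_real_)
  sqrt(sum(d^2) / length(d))
}

oracle_mad <- function(a) {
  m <- sum(a) / length(a)
  sum(abs(a - m)) / length(a)
}

oracle_ima <- function(acc) {
  # time-normalized integral of the L1 modulus
  sum(abs(acc)) / nrow(acc)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_kappa <- function(a, b) {
  cats <- c(-1, 0, 1)
  po <- sum(a == b) / length(a)
  pe <- 0
  for (k in cats) pe <- pe + (sum(a == k) / length(a)) * (sum(b == k) / length(b))
  (po - pe) / (1 - pe)
}

# Exhaustive monotone boundary-anchored warping paths (steps (1,0),(0,1),(1,1))
# by recursion; feasible only for short sequences.
oracle_dtw <- function(x, y) {
  n <- length(x); m <- length(y)
  memo <- new.env()
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    c0 <- abs(x[i] - y[j])
    v <- if (i == 1 && j == 1) {
      c0
    } else if (i == 1) {
      c0 + rec(1, j - 1)
    } else if (j == 1) {
      c0 + rec(i - 1, 1)
    } else {
      c0 + min(rec(i - 1, j), rec(i, j - 1), rec(i - 1, j - 1))
    }
    memo[[key]] <- v
    v
  }
  rec(n, m)
}

# Exact two-sided signed-rank p by direct enumeration over sign vectors,
# written independently of the package's vectorized version.
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    s <- as.numeric(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L))
    ws[mask + 1] <- sum(r * s)
  }
  p_lo <- mean(ws <= w_obs)
  p_hi <- mean(ws >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Direct evaluation of the PPSA epoch rule from its verbal definition.
oracle_ppsa <- function(secs) {
  if (sum(secs == "offscreen") >= 5) return(NA_integer_)
  on <- secs[secs != "offscreen"]
  npos <- sum(on == "1"); nneu <- sum(on == "0"); nneg <- sum(on == "-1")
  if (npos > nneu && npos > nneg) return(1L)
  if (nneg > nneu && nneg > npos) return(-1L)
  0L
}

# Small fast session plan used by pipeline tests.
tiny_plan <- function() {
  data.frame(label = c("BASE", "INT1", "NEU1", "INT2", "POST"),
             duration = c(60, 240, 60, 240, 60))
}
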