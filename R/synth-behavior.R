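# Coupled three-state behavior simulation.

#' Simulate coupled per-second behavior state streams for a dyad
#'
#' The human stream is a three-state Markov chain over
#' \{-1 (negative), 0 (neutral), +1 (positive)\}.  Each second the canine
#' copies the human's current state with probability `copy_prob_kappa`;
#' otherwise it advances its own independent chain with the same transition
#' matrix.  Expected same-state fraction is therefore at least
#' `copy_prob_kappa`.
#'
#' @param n_seconds stream length, s.
#' @param transition_matrix 3x3 row-stochastic matrix over states
#'   (-1, 0, +1) in that row/column order.
#' @param copy_prob_kappa copy probability in `[0, 1]`.
#' @param seed integer seed.
#' @return List with integer vectors `human` and `canine` of length
#'   `n_seconds`, values in \{-1, 0, 1\}.
#' @export
simulate_behavior_codes <- function(n_seconds, transition_matrix,
                                    copy_prob_kappa, seed = 1L) {
  assert_scalar_in(copy_prob_kappa, "copy_prob_kappa", 0, 1)
  P <- as.matrix(transition_matrix)
  if (!all(dim(P) == c(3L, 3L)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-9)) {
    ds_stop("dyadsync_parameter_error",
            "transition_matrix rows must be non-negative and sum to 1 (+-1e-9)")
  }
  states <- c(-1L, 0L, 1L)
  withr_seed(seed, {
    h <- integer(n_seconds)
    c_own <- integer(n_seconds)  # canine's private chain (state index 1..3)
    hi <- sample.int(3L, 1L)
    ci <- sample.int(3L, 1L)
    copy <- runif(n_seconds) < copy_prob_kappa
    cvec <- integer(n_seconds)
    for (s in seq_len(n_seconds)) {
      if (s > 1L) {
        hi <- sample.int(3L, 1L, prob = P[hi, ])
        ci <- sample.int(3L, 1L, prob = P[ci, ])
      }
      h[s] <- states[hi]
      cvec[s] <- if (copy[s]) states[hi] else states[ci]
    }
    list(human = h, canine = cvec)
  })
}

# Stationary distribution of a row-stochastic matrix (left eigenvector).
markov_stationary <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# Degrade a true per-second stream into one rater's observation: each second
# is misread with probability `error_prob` (replaced by a draw from the
# remaining two states, biased toward neutral), and seconds listed in
# `offscreen` become "offscreen".
rater_observe <- function(truth, error_prob, offscreen, seed) {
  withr_seed(seed, {
    obs <- as.character(truth)
    flip <- runif(length(truth)) < error_prob
    for (i in which(flip)) {
      others <- setdiff(c(-1L, 0L, 1L), truth[i])
      w <- ifelse(others == 0L, 0.8, 0.2)
      obs[i] <- as.character(sample(others, 1L, prob = w))
    }
    obs[offscreen] <- "offscreen"
    obs
  })
}
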