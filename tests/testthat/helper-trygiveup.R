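# shared fixtures, built in code

# tiny instance within the brute-force oracle's guard
tiny_config <- function(trials = 3L, n_try = 2L, n_gu = 2L) {
  task_config(try_spec = matrix_spec(1, 14, 0.1, n_try),
              giveup_spec = matrix_spec(1, 2, 0.5, n_gu),
              trials_per_round = trials, rounds_per_block = 1L,
              analysis_window = trials)
}

# random small instance + level-order-preserving random scheme
random_instance <- function(seed) {
  set.seed(seed)
  trials <- sample(1:4, 1)
  tl <- sample(0:3, 1); th <- tl + sample(0:13, 1)
  gl <- sample(0:2, 1); gh <- gl + sample(0:3, 1)
  cfg <- task_config(
    try_spec = matrix_spec(tl, th, stats::runif(1), sample(1:3, 1)),
    giveup_spec = matrix_spec(gl, gh, stats::runif(1), sample(1:3, 1)),
    trials_per_round = trials, rounds_per_block = 1L,
    analysis_window = trials)
  repeat {
    dt <- sort(sample(-2:2, 2, replace = TRUE)) # keeps low <= high deltas valid
    dg <- sort(sample(-2:2, 2, replace = TRUE))
    if (th + dt[2] >= tl + dt[1] && gh + dg[2] >= gl + dg[1]) break
  }
  sch <- custom_scheme(delta_try = c(low = dt[1], high = dt[2]),
                       delta_giveup = c(low = dg[1], high = dg[2]),
                       cost_try = sample(0:3, 1), cost_giveup = sample(0:3, 1))
  list(config = cfg, scheme = sch)
}

# independent closed-form oracles for the two pure strategies (test-side
# implementations, deliberately separate from the package's evaluator)
oracle_pure_giveup <- function(t, g = 0, p = 0.5, lo = 1, hi = 2, cost = 2,
                               n_keys = 12) {
  if (t == 0) return(0)
  if (g >= n_keys) return(if (g > 0) t * lo else 0)
  (p * hi + (1 - p) * lo - cost) + p * (t - 1) * hi +
    (1 - p) * oracle_pure_giveup(t - 1, g + 1, p, lo, hi, cost, n_keys)
}

oracle_pure_try <- function(t, f = 0, p = 0.1, lo = 1, hi = 14, cost = 2,
                            n_keys = 12, tail = oracle_pure_giveup) {
  if (t == 0) return(0)
  if (f >= n_keys) return(tail(t))
  (p * hi + (1 - p) * lo - cost) + p * (t - 1) * hi +
    (1 - p) * oracle_pure_try(t - 1, f + 1, p, lo, hi, cost, n_keys, tail)
}

# small synthetic experiment, generated once and cached for the test session
.fixture_cache <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    design <- cohort_design(
      n_per_condition = c(minus_giveup = 10, minus_giveup_minus_trylow = 10,
                          plus_try = 10, plus_try_explore = 10))
    .fixture_cache$cohort <- generate_cohort(design, seed = 7001)
  }
  .fixture_cache$cohort
}

# replay a recorded choice sequence under another scheme on the same latent
# board (the round must have been generated with sample_round-compatible
# seeding, i.e. play_round with a fixed-strategy agent)
replay_round <- function(round_log, config, sch, seed) {
  st <- sample_round(config, seed)
  net <- numeric(nrow(round_log))
  for (i in seq_len(nrow(round_log))) {
    out <- step_round(st, config, sch, round_log$matrix[i], round_log$key_id[i])
    net[i] <- out$record$net_points
    st <- out$state
  }
  net
}
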