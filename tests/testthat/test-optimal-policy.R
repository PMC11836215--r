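test_that("single-trial values follow one-step expected-value arithmetic", {
  cf1 <- task_config(trials_per_round = 1, analysis_window = 1)
  p <- solve_dp(cf1, "baseline")
  # exploring Try: .9*1 + .1*14 - 2 = 0.3 beats Give-Up's 1.5 - 2 = -0.5
  root <- policy_action(p, 1, "none", "none", 12, 12)
  expect_equal(root$action, "EXPLORE_TRY")
  expect_equal(root$value, 0.3)
  expect_equal(root_value(p), 0.3)
  expect_equal(brute_force_value(tiny_config(trials = 1), "baseline"), 0.3)
})

test_that("a known high Try key is exploited for all remaining trials", {
  p <- solve_dp(task_config(), "baseline")
  for (t in c(1, 5, 12)) for (bg in c("none", "low", "high")) {
    st <- policy_action(p, t, "high", bg, 8, 12)
    expect_equal(st$action, "EXPLOIT_TRY_HIGH")
    expect_equal(st$value, 14 * t) # no cost, fixed outcome to round end
  }
})

test_that("a hopeless Try matrix sends the solver to Give-Up search", {
  cf <- tiny_config(trials = 3)
  cf$try_spec$p_high <- 0
  p <- solve_dp(cf, "baseline")
  root <- policy_action(p, 3, "none", "none", 2, 2)
  expect_equal(root$action, "EXPLORE_GIVEUP")
  expect_equal(root_value(p), brute_force_value(cf, "baseline"), tolerance = 1e-12)
})

test_that("backward induction matches the brute-force oracle on random instances", {
  for (i in 1:12) {
    inst <- random_instance(6000 + i)
    expect_lt(abs(root_value(solve_dp(inst$config, inst$scheme)) -
                    brute_force_value(inst$config, inst$scheme)), 1e-9)
  }
})

test_that("brute force refuses instances beyond its combinatorial guard", {
  expect_error(brute_force_value(task_config(), "baseline"), "refuses")
  big <- task_config(try_spec = matrix_spec(1, 14, .1, 4),
                     giveup_spec = matrix_spec(1, 2, .5, 2),
                     trials_per_round = 3, analysis_window = 3)
  expect_error(brute_force_value(big, "baseline"), "refuses")
})

test_that("optimal value is monotone in horizon, success odds and cost", {
  base <- function(trials, p_high, cost) {
    cf <- task_config(try_spec = matrix_spec(1, 14, p_high, 12),
                      trials_per_round = trials, analysis_window = 1)
    sch <- custom_scheme(cost_try = cost, cost_giveup = cost)
    root_value(solve_dp(cf, sch))
  }
  v_t <- vapply(1:6, function(t) base(t, 0.1, 2), 0)
  expect_true(all(diff(v_t) >= -1e-12))
  v_p <- vapply(c(0, 0.05, 0.1, 0.2, 0.5), function(p) base(6, p, 2), 0)
  expect_true(all(diff(v_p) >= -1e-12))
  v_c <- vapply(c(0, 1, 2, 4), function(co) base(6, 0.1, co), 0)
  expect_true(all(diff(v_c) <= 1e-12))
})

test_that("waiving Try exploration costs cannot lower the optimal value", {
  cf <- task_config()
  expect_gte(root_value(solve_dp(cf, "plus_try_explore")),
             root_value(solve_dp(cf, "baseline")))
})

test_that("simulated optimal play matches the solved root value", {
  cf <- task_config()
  p <- solve_dp(cf, "baseline")
  ag <- agent_spec("dp_optimal")
  n <- 10000
  pay <- vapply(seq_len(n), function(r) {
    sum(play_round(ag, cf, "baseline", seed = derive_seed(81, r),
                   policy = p)$net_points)
  }, 0)
  se <- stats::sd(pay) / sqrt(n)
  expect_lt(abs(mean(pay) - root_value(p)), 3 * se)
})

test_that("policy tables round-trip through their JSON export", {
  cf <- tiny_config(trials = 2)
  p <- solve_dp(cf, "baseline")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_policy_json(p, path)
  back <- read_policy_json(path)
  expect_equal(back$scheme, "baseline")
  root_key <- paste(2, "none", "none", 2, 2, sep = "|")
  expect_equal(back$states[[root_key]]$value, root_value(p))
  st <- policy_action(p, 1, "low", "high", 1, 1)
  k <- paste(1, "low", "high", 1, 1, sep = "|")
  expect_equal(back$states[[k]]$action, st$action)
  expect_equal(back$states[[k]]$value, st$value)
})

test_that("choice classification partitions all cases and flags the benchmark", {
  cf <- task_config()
  empty <- list(rev_try = rep(NA_real_, 12), rev_gu = rep(NA_real_, 12))
  c1 <- classify_choice(empty, "try", 0, cf)
  expect_equal(c1$category, "TRY_EXPLORE")
  expect_true(c1$optimal_consistent)
  h <- empty; h$rev_try[1] <- 1
  c2 <- classify_choice(h, "try", 0, cf)
  expect_equal(c2$category, "TRY_LOW_EXPLOIT")
  expect_false(c2$optimal_consistent)
  h2 <- empty; h2$rev_try[5] <- 14
  c3 <- classify_choice(h2, "try", 4, cf)
  expect_equal(c3$category, "TRY_HIGH_EXPLOIT")
  expect_true(c3$optimal_consistent)
  # fresh exploration while a high key is already known is off-benchmark
  c4 <- classify_choice(h2, "try", 0, cf)
  expect_equal(c4$category, "TRY_EXPLORE")
  expect_false(c4$optimal_consistent)
  c5 <- classify_choice(h2, "giveup", 3, cf)
  expect_equal(c5$category, "GIVEUP")
  expect_false(c5$optimal_consistent)
  # property: exactly one category fires for randomised histories
  set.seed(99)
  for (i in 1:200) {
    hh <- empty
    nrev <- sample(0:12, 1)
    if (nrev) hh$rev_try[sample(12, nrev)] <- sample(c(1, 14), nrev, TRUE)
    ngu <- sample(0:12, 1)
    if (ngu) hh$rev_gu[sample(12, ngu)] <- sample(c(1, 2), ngu, TRUE)
    res <- classify_choice(hh, sample(c("try", "giveup"), 1), sample(0:11, 1), cf)
    expect_true(res$category %in%
                  c("GIVEUP", "TRY_EXPLORE", "TRY_LOW_EXPLOIT", "TRY_HIGH_EXPLOIT"))
    expect_type(res$optimal_consistent, "logical")
  }
})

test_that("label_log replays classification identically to classify_choice", {
  cf <- task_config()
  ag <- agent_spec("threshold_try", m = 12)
  log <- play_round(ag, cf, "baseline", seed = 314)
  labelled <- label_log(log, cf)
  rev_try <- rep(NA_real_, 12); rev_gu <- rep(NA_real_, 12)
  for (i in seq_len(nrow(log))) {
    ref <- classify_choice(list(rev_try = rev_try, rev_gu = rev_gu),
                           log$matrix[i], log$key_id[i], cf)
    expect_equal(labelled$label[i], ref$category)
    expect_equal(labelled$optimal_consistent[i] == 1L, ref$optimal_consistent)
    k <- log$key_id[i] + 1L
    if (log$matrix[i] == "try") rev_try[k] <- log$raw_outcome[i]
    else rev_gu[k] <- log$raw_outcome[i]
  }
})
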