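test_that("named schemes reproduce the study's displayed incentive table", {
  # displayed outcome = latent value + scheme delta
  disp <- function(sch, mat, level, value) {
    value + apply_scheme(scheme(sch), mat, level, FALSE)$delta
  }
  expect_equal(disp("baseline", "giveup", "low", 1), 1)
  expect_equal(disp("baseline", "try", "high", 14), 14)
  expect_equal(disp("minus_giveup", "giveup", "low", 1), -1)
  expect_equal(disp("minus_giveup", "giveup", "high", 2), 0)
  expect_equal(disp("minus_giveup", "try", "low", 1), 1)
  expect_equal(disp("minus_giveup_minus_trylow", "try", "low", 1), -1)
  expect_equal(disp("minus_giveup_minus_trylow", "try", "high", 14), 14)
  expect_equal(disp("minus_giveup_minus_trylow", "giveup", "high", 2), 0)
  expect_equal(disp("plus_try", "try", "low", 1), 3)
  expect_equal(disp("plus_try", "try", "high", 14), 16)
  expect_equal(disp("plus_try", "giveup", "low", 1), 1)
  for (s in list_schemes()) {
    sc <- scheme(s)
    expect_equal(unname(sc$cost["giveup"]), 2)
    expect_equal(unname(sc$cost["try"]), if (s == "plus_try_explore") 0 else 2)
  }
  expect_error(scheme("bogus"))
})

test_that("apply_scheme charges exploration cost only on first press", {
  a <- apply_scheme("plus_try_explore", "try", "high", first_press = TRUE)
  expect_equal(a$cost, 0) # cost waived for Try under the exploration reward
  b <- apply_scheme("plus_try_explore", "giveup", "low", first_press = TRUE)
  expect_equal(b$cost, 2) # Give-Up keys keep their cost
  d <- apply_scheme("baseline", "try", "high", first_press = TRUE)
  expect_equal(14 + d$delta - d$cost, 12)
  e <- apply_scheme("baseline", "try", "high", first_press = FALSE)
  expect_equal(e$cost, 0)
})

test_that("step_round reveals, charges and decomposes net points", {
  cf <- task_config()
  st <- sample_round(cf, seed = 42)
  st$latent$giveup[3] <- 2
  out <- step_round(st, cf, "baseline", "giveup", key_id = 2)
  expect_equal(out$record$net_points, 0) # 2 - 2 exploration cost
  expect_equal(out$record$first_press, 1L)
  # second press of the same key: no cost, same outcome
  out2 <- step_round(out$state, cf, "baseline", "giveup", key_id = 2)
  expect_equal(out2$record$cost_charged, 0)
  expect_equal(out2$record$raw_outcome, out$record$raw_outcome)
  expect_equal(out2$record$net_points, 2)
  # exploration-cost waiver nets the full high outcome
  st2 <- sample_round(cf, seed = 43)
  st2$latent$try[1] <- 14
  out3 <- step_round(st2, cf, "plus_try_explore", "try", 0)
  expect_equal(out3$record$net_points, 14)
  # bounds and end-of-round guards
  expect_error(step_round(st, cf, "baseline", "try", 12), "out of bounds")
  st$trial_index <- cf$trials_per_round + 1L
  expect_error(step_round(st, cf, "baseline", "try", 0), "round is over")
})

test_that("payoff decomposition and outcome persistence hold on random play", {
  cf <- task_config()
  for (s in list_schemes()) {
    set.seed(500 + match(s, list_schemes()))
    st <- sample_round(cf)
    seen <- list(try = rep(NA_real_, 12), giveup = rep(NA_real_, 12))
    for (i in 1:12) {
      m <- sample(c("try", "giveup"), 1)
      k <- sample(0:11, 1)
      out <- step_round(st, cf, s, m, k)
      rec <- out$record
      expect_equal(rec$net_points,
                   rec$raw_outcome + rec$scheme_delta - rec$cost_charged)
      expect_true(rec$cost_charged == 0 || rec$first_press == 1L)
      prev <- seen[[m]][k + 1]
      if (!is.na(prev)) {
        expect_equal(rec$raw_outcome, prev)
        expect_equal(rec$first_press, 0L)
      }
      seen[[m]][k + 1] <- rec$raw_outcome
      st <- out$state
    }
    # revealed keys are exactly the pressed keys
    expect_identical(is.na(st$revealed$try), is.na(seen$try))
    expect_identical(is.na(st$revealed$giveup), is.na(seen$giveup))
  }
})

test_that("sample_round is reproducible and honours degenerate probabilities", {
  cf <- task_config()
  expect_identical(sample_round(cf, 99), sample_round(cf, 99))
  all_high <- task_config(try_spec = matrix_spec(1, 14, 1, 12))
  expect_true(all(sample_round(all_high, 1)$latent$try == 14))
  all_low <- task_config(try_spec = matrix_spec(1, 14, 0, 12))
  expect_true(all(sample_round(all_low, 1)$latent$try == 1))
})

test_that("high-key counts match the binomial expectation over many rounds", {
  cf <- task_config()
  n <- 10000
  counts <- vapply(seq_len(n), function(i) {
    sum(sample_round(cf, seed = derive_seed(3000, i))$latent$try == 14)
  }, 0)
  se <- sqrt(12 * 0.1 * 0.9 / n)
  expect_lt(abs(mean(counts) - 1.2), 3 * se)
})

test_that("config validation rejects inconsistent structures", {
  expect_error(matrix_spec(1, 14, 1.5, 12), "probability")
  expect_error(matrix_spec(14, 1, 0.5, 12), "high_value")
  expect_error(matrix_spec(1, 14, 0.1, 0), "n_keys")
  expect_error(task_config(trials_per_round = 0), "trials_per_round")
  expect_error(task_config(analysis_window = 13), "analysis_window")
})
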