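make_round_log <- function(matrix, key_id, raw, first, net = NULL,
                           pid = "p1", cond = "minus_giveup", block = 1L) {
  n <- length(matrix)
  delta <- rep(0, n)
  cost <- ifelse(first == 1L, 2, 0)
  data.frame(participant_id = pid, condition = cond, block = block,
             round = 1L, trial = seq_len(n), matrix = matrix, key_id = key_id,
             first_press = first, raw_outcome = raw, scheme_delta = delta,
             cost_charged = cost,
             net_points = if (is.null(net)) raw + delta - cost else net)
}

test_that("rates are category counts over the windowed trial count", {
  # 3 Give-Up choices + 6 fresh Try explorations in a 9-trial window
  log <- make_round_log(
    matrix = c("giveup", "giveup", "giveup", rep("try", 6)),
    key_id = c(0L, 1L, 2L, 0:5), raw = c(1, 2, 1, rep(1, 6)),
    first = rep(1L, 9))
  r <- compute_rates(log, window = 1:9)
  expect_equal(r$giveup_rate, 1 / 3)
  expect_equal(r$trylow_rate, 0)
  expect_equal(r$optimal_rate, 2 / 3)
  expect_equal(r$n_trials, 9L)
  # an all-benchmark log scores 1 on the optimal rate and 0 elsewhere
  log2 <- make_round_log(matrix = rep("try", 9), key_id = c(0:3, rep(4L, 5)),
                         raw = c(1, 1, 1, 1, rep(14, 5)),
                         first = c(rep(1L, 5), rep(0L, 4)))
  r2 <- compute_rates(log2, window = 1:9)
  expect_equal(r2$optimal_rate, 1)
  expect_equal(r2$giveup_rate, 0)
  expect_equal(r2$trylow_rate, 0)
})

test_that("widening the window changes the denominator", {
  log <- small_cohort()
  r9 <- compute_rates(log, window = 1:9)
  r12 <- compute_rates(log, window = 1:12)
  expect_true(all(r9$n_trials == 15 * 9))
  expect_true(all(r12$n_trials == 15 * 12))
  # exploitation keeps accumulating after trial 9, so the windowed
  # Try-low rate shifts when the denominator widens
  expect_false(isTRUE(all.equal(r9$trylow_rate, r12$trylow_rate)))
})

test_that("category shares sum to one on every participant-block window", {
  r <- compute_rates(small_cohort())
  shares <- r$giveup_rate + r$trylow_rate + r$tryexplore_rate + r$tryhigh_rate
  expect_equal(shares, rep(1, nrow(r)))
})

test_that("incentive stripping inverts scheme deltas and restores waived costs", {
  # a +Try low-key exploitation showing +3 strips to +1
  log <- make_round_log(matrix = "try", key_id = 0L, raw = 1, first = 0L)
  log$scheme_delta <- 2; log$net_points <- 3
  s <- strip_incentives(log)
  expect_equal(s$net_points_stripped, 1)
  # a cost-waived first Try press netting +1 strips to -1
  log2 <- make_round_log(matrix = "try", key_id = 0L, raw = 1, first = 1L)
  log2$cost_charged <- 0; log2$net_points <- 1
  s2 <- strip_incentives(log2)
  expect_equal(s2$net_points_stripped, -1)
  # baseline logs are unchanged
  base <- small_cohort()[block == 1]
  sb <- strip_incentives(base)
  expect_equal(sb$net_points_stripped, sb$net_points)
})

test_that("stripped payoffs equal a baseline replay of the same choices", {
  cf <- task_config()
  agents <- list(agent_spec("giveup_searcher"), agent_spec("trylow_settler"),
                 agent_spec("threshold_try", m = 9))
  for (s in setdiff(list_schemes(), "baseline")) {
    for (i in 1:10) {
      seed <- derive_seed(7700, match(s, list_schemes()), i)
      ag <- agents[[1 + (i %% length(agents))]]
      log <- play_round(ag, cf, s, seed = seed)
      stripped <- strip_incentives(log)$net_points_stripped
      expect_identical(stripped, replay_round(log, cf, "baseline", seed))
    }
  }
})

test_that("difference scores are zero with symmetric CIs on identical blocks", {
  r1 <- data.frame(participant_id = rep(sprintf("p%d", 1:4), each = 3),
                   condition = "plus_try", block = rep(1:3, 4),
                   giveup_rate = 0.5, trylow_rate = 0.2, optimal_rate = 0.3,
                   mean_payoff = 2)
  ds <- difference_scores(r1)
  expect_true(all(ds$summary$mean == 0))
  expect_true(all(ds$summary$ci_lo == 0 & ds$summary$ci_hi == 0))
  expect_true(all(ds$participant$difference == 0))
})

test_that("the one-way F matches the textbook decomposition", {
  vals <- c(1, 2, 3, 2, 3, 4, 5, 6, 7)
  grp <- rep(c("a", "b", "c"), each = 3)
  # independent hand computation of the between/within decomposition
  gm <- mean(vals)
  means <- tapply(vals, grp, mean)
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum((vals - means[grp])^2)
  f_ref <- (ssb / 2) / (ssw / 6)
  out <- anova_oneway(vals, grp)
  expect_equal(out$F, f_ref)
  expect_equal(out$df1, 2)
  expect_equal(out$df2, 6)
  expect_equal(out$p, stats::pf(f_ref, 2, 6, lower.tail = FALSE))
  # degenerate: zero within-group variance diverges with a warning
  expect_warning(res <- anova_oneway(c(0, 0, 0, 1, 1, 1),
                                     rep(c("a", "b"), each = 3)),
                 "divergent")
  expect_identical(res$F, Inf)
  expect_identical(res$p, 0)
  # inference refused for underpopulated groups
  expect_error(anova_oneway(c(1, 2, 3), c("a", "a", "b")), "refused")
})

test_that("correlations clamp at the unit boundary for the Fisher average", {
  rows <- data.frame(condition = rep(c("plus_try", "minus_giveup"), each = 5),
                     giveup_rate = rep(seq(0, 1, length.out = 5), 2))
  rows$optimal_rate <- 1 - rows$giveup_rate
  res <- dv_correlation(rows)
  expect_equal(res$by_condition$r, c(-1, -1))
  expect_true(is.finite(res$r_fisher_mean))
  expect_equal(res$r_fisher_mean, -1, tolerance = 1e-6)
})

test_that("give-up and benchmark rates anticorrelate in learning cohorts", {
  r <- compute_rates(small_cohort())
  res <- dv_correlation(r)
  expect_true(all(res$by_condition$r < 0))
  expect_lt(res$r_fisher_mean, 0)
})

test_that("the condition table reports rates in percentage points", {
  log <- strip_incentives(small_cohort())
  tab <- report_condition_table(compute_rates(log))
  expect_setequal(unique(tab$phase), c("treatment", "retention"))
  expect_true(all(tab$ci_lo <= tab$mean & tab$mean <= tab$ci_hi))
  rate_rows <- tab[tab$dv == "giveup_rate"]
  expect_equal(unique(rate_rows$unit), "percentage points")
  payoff_rows <- tab[tab$dv == "mean_payoff_stripped"]
  expect_equal(unique(payoff_rows$unit), "points per trial")
})
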