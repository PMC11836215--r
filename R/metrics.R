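RATE_DVS <- c("giveup_rate", "trylow_rate", "optimal_rate")

#' Per-participant, per-block choice rates and payoffs
#'
#' Computes the dependent variables on the analysis window (by default the
#' first nine trials of every round, where the optimal benchmark is
#' search-then-exploit): the Give-Up choice rate, the Try-low exploitation
#' rate (re-pressing familiar low Try keys), the rate of benchmark-consistent
#' choices, and mean net points per trial. If the log carries a
#' `net_points_stripped` column (see [strip_incentives()]) its windowed mean
#' is reported as `mean_payoff_stripped`. Denominators are the windowed trial
#' count, so the four category shares sum to 1.
#'
#' @param log A trial log; labels are recomputed by replay if absent.
#' @param window Trial window, e.g. `1:9`; defaults to the config's
#'   `analysis_window`.
#' @param config A [task_config()].
#' @return data.table: one row per participant x condition x block.
#' @export
compute_rates <- function(log, window = NULL, config = task_config()) {
  dt <- data.table::as.data.table(log)
  req <- c("participant_id", "condition", "block", "round", "trial", "matrix",
           "first_press", "raw_outcome", "net_points")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("log is missing columns: ", paste(miss, collapse = ", "))
  if (!all(c("label", "optimal_consistent") %in% names(dt)))
    dt <- label_log(dt, config)
  if (is.null(window)) window <- seq_len(config$analysis_window)
  w <- dt[trial %in% window]
  has_strip <- "net_points_stripped" %in% names(w)
  out <- w[, {
    res <- list(
      giveup_rate = mean(label == "GIVEUP"),
      trylow_rate = mean(label == "TRY_LOW_EXPLOIT"),
      tryexplore_rate = mean(label == "TRY_EXPLORE"),
      tryhigh_rate = mean(label == "TRY_HIGH_EXPLOIT"),
      optimal_rate = mean(optimal_consistent == 1L),
      mean_payoff = mean(net_points),
      n_trials = .N)
    if (has_strip) res$mean_payoff_stripped <- mean(net_points_stripped)
    res
  }, by = .(participant_id, condition, block)]
  data.table::setorder(out, condition, participant_id, block)
  out[]
}

#' Recompute payoffs under the baseline scheme
#'
#' Adds `net_points_stripped`: each trial's net points with
#' treatment-specific rewards and punishments removed, i.e. the raw outcome
#' under the baseline exploration cost for the same press history. This is
#' the exact inverse of the scheme deltas and restores the baseline cost
#' where a scheme had waived it, so stripped payoffs equal a baseline replay
#' of the identical choice sequence.
#'
#' @param log A trial log.
#' @param baseline The reference scheme (default `"baseline"`).
#' @return The log with a `net_points_stripped` column.
#' @export
strip_incentives <- function(log, baseline = scheme("baseline")) {
  baseline <- as_scheme(baseline)
  dt <- data.table::as.data.table(log)
  cost <- ifelse(dt$matrix == "try", baseline$cost[["try"]],
                 baseline$cost[["giveup"]])
  dt[, net_points_stripped := raw_outcome - (first_press == 1L) * cost]
  dt[]
}

#' Difference scores with confidence intervals
#'
#' For each participant and dependent variable, the treatment effect
#' (block 2 - block 1) and retention effect (block 3 - block 1); summarised
#' per condition as the mean difference with a 95% normal-approximation CI
#' (`mean +/- 1.96 * SE` across participants), optionally a percentile
#' bootstrap.
#'
#' @param rates Output of [compute_rates()].
#' @param dvs Dependent-variable columns to difference.
#' @param ci `"normal"` or `"bootstrap"`.
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @return List with `participant` (per-participant differences, long form)
#'   and `summary` (condition x dv x phase: mean, ci_lo, ci_hi, n).
#' @export
difference_scores <- function(rates,
                              dvs = c(RATE_DVS,
                                      intersect("mean_payoff_stripped",
                                                names(rates)),
                                      "mean_payoff"),
                              ci = c("normal", "bootstrap"),
                              n_boot = 2000L, seed = NULL) {
  ci <- match.arg(ci)
  dt <- data.table::as.data.table(rates)
  dvs <- intersect(dvs, names(dt))
  wide <- data.table::dcast(dt, participant_id + condition ~ block,
                            value.var = dvs)
  if (length(dvs) == 1L)  # dcast drops the value-var prefix for a single dv
    data.table::setnames(wide, as.character(1:3), paste0(dvs, "_", 1:3),
                         skip_absent = TRUE)
  one <- function(dv) {
    b1 <- wide[[paste0(dv, "_1")]]
    b2 <- wide[[paste0(dv, "_2")]]
    b3 <- wide[[paste0(dv, "_3")]]
    data.table::data.table(
      participant_id = rep(wide$participant_id, 2L),
      condition = rep(wide$condition, 2L),
      dv = dv,
      phase = rep(c("treatment", "retention"), each = nrow(wide)),
      difference = c(b2 - b1, b3 - b1))
  }
  part <- data.table::rbindlist(lapply(dvs, one))
  if (ci == "bootstrap" && !is.null(seed)) set.seed(seed)
  summ <- part[, {
    n <- .N
    m <- mean(difference)
    if (ci == "normal") {
      se <- stats::sd(difference) / sqrt(n)
      list(mean = m, ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se, n = n)
    } else {
      bs <- replicate(n_boot, mean(sample(difference, n, replace = TRUE)))
      list(mean = m, ci_lo = unname(stats::quantile(bs, 0.025)),
           ci_hi = unname(stats::quantile(bs, 0.975)), n = n)
    }
  }, by = .(condition, dv, phase)]
  list(participant = part[], summary = summ[])
}

#' One-way between-subjects ANOVA
#'
#' Standard between/within decomposition via `lm`/`anova`. Groups with fewer
#' than two observations make inference impossible and are refused. A zero
#' within-group mean square (all groups internally constant) yields a
#' divergent statistic, reported as `Inf` with a warning.
#'
#' @param values Numeric response (e.g. per-participant difference scores).
#' @param groups Grouping factor (e.g. condition).
#' @return List `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  cnt <- table(groups)
  if (any(cnt < 2))
    stop("inference refused: group(s) with < 2 observations: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  if (all(tapply(values, groups, stats::var) == 0)) {
    if (stats::var(tapply(values, groups, mean)) == 0) {
      return(list(F = NaN, df1 = df1, df2 = df2, p = NaN)) # no variation at all
    }
    warning("zero within-group variance: F statistic is divergent")
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  a <- stats::anova(stats::lm(values ~ groups))
  list(F = a$`F value`[1], df1 = df1, df2 = df2, p = a$`Pr(>F)`[1])
}

#' Correlation between Give-Up and benchmark-consistent rates
#'
#' Per-condition Pearson correlation between two dependent variables
#' (defaults: Give-Up rate vs optimal rate) plus their Fisher-z average
#' (correlations clamped just inside the open unit interval before the z
#' transform).
#'
#' @param rows data.frame with a `condition` column and the two variables.
#' @param x,y Column names to correlate.
#' @return List: `by_condition` (data.table of condition, r, n) and
#'   `r_fisher_mean`.
#' @export
dv_correlation <- function(rows, x = "giveup_rate", y = "optimal_rate") {
  dt <- data.table::as.data.table(rows)
  by_cond <- dt[, .(r = stats::cor(get(x), get(y)), n = .N), by = condition]
  clamp <- pmin(pmax(by_cond$r, -1 + 1e-12), 1 - 1e-12)
  list(by_condition = by_cond[],
       r_fisher_mean = tanh(mean(atanh(clamp))))
}

#' Condition-by-DV difference grid
#'
#' The condition x dependent-variable x (treatment, retention) summary grid
#' of mean differences and 95% CIs, with rate DVs expressed as percentage
#' points and payoffs in points per trial.
#'
#' @param rates Output of [compute_rates()] (stripped payoffs included when
#'   present).
#' @param ... Passed to [difference_scores()].
#' @return data.table: condition, dv, phase, mean, ci_lo, ci_hi, n, unit.
#' @export
report_condition_table <- function(rates, ...) {
  ds <- difference_scores(rates, ...)
  out <- data.table::copy(ds$summary)
  is_rate <- out$dv %in% c(RATE_DVS, "tryexplore_rate", "tryhigh_rate")
  scale <- ifelse(is_rate, 100, 1)
  for (col in c("mean", "ci_lo", "ci_hi"))
    data.table::set(out, j = col, value = out[[col]] * scale)
  out[, unit := ifelse(is_rate, "percentage points", "points per trial")]
  data.table::setorderv(out, c("phase", "dv", "condition"))
  out[]
}
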