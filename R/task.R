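#' Specify one outcome matrix
#'
#' A matrix is a set of `n_keys` keys whose latent outcome is drawn once per
#' round: `high_value` with probability `p_high`, otherwise `low_value`.
#'
#' @param low_value,high_value Outcome points, `high_value >= low_value`.
#' @param p_high Probability a key is a high key.
#' @param n_keys Number of keys (>= 1).
#' @return A `matrix_spec` object.
#' @export
matrix_spec <- function(low_value, high_value, p_high, n_keys = 12L) {
  if (!is.numeric(p_high) || length(p_high) != 1 || p_high < 0 || p_high > 1)
    stop("p_high must be a probability in [0, 1]")
  if (n_keys < 1) stop("n_keys must be >= 1")
  if (high_value < low_value) stop("high_value must be >= low_value")
  structure(list(low_value = as.numeric(low_value),
                 high_value = as.numeric(high_value),
                 p_high = as.numeric(p_high),
                 n_keys = as.integer(n_keys)),
            class = "matrix_spec")
}

#' Task configuration
#'
#' Defaults reproduce the study's incentive structure: a Try matrix paying +1
#' with probability .9 and +14 with probability .1, a Give-Up matrix paying +1
#' or +2 with equal probability, 12 keys per matrix, 12 trials per round,
#' 15 rounds per block, three blocks (baseline / treatment / baseline) and a
#' 9-trial analysis window.
#'
#' @param try_spec,giveup_spec [matrix_spec()] objects.
#' @param trials_per_round Trials in a round (>= 1).
#' @param rounds_per_block Rounds in a block.
#' @param block_schemes Character vector of scheme names, one per block; the
#'   placeholder `"<treatment>"` in position 2 is substituted per condition by
#'   the cohort generator.
#' @param analysis_window Number of leading trials used by the metrics
#'   (<= `trials_per_round`).
#' @return A `task_config` object.
#' @export
task_config <- function(try_spec = matrix_spec(1, 14, 0.1, 12L),
                        giveup_spec = matrix_spec(1, 2, 0.5, 12L),
                        trials_per_round = 12L,
                        rounds_per_block = 15L,
                        block_schemes = c("baseline", "<treatment>", "baseline"),
                        analysis_window = 9L) {
  stopifnot(inherits(try_spec, "matrix_spec"), inherits(giveup_spec, "matrix_spec"))
  if (trials_per_round < 1) stop("trials_per_round must be >= 1")
  if (analysis_window > trials_per_round)
    stop("analysis_window must be <= trials_per_round")
  structure(list(try_spec = try_spec, giveup_spec = giveup_spec,
                 trials_per_round = as.integer(trials_per_round),
                 rounds_per_block = as.integer(rounds_per_block),
                 block_schemes = block_schemes,
                 analysis_window = as.integer(analysis_window)),
            class = "task_config")
}

spec_for <- function(config, matrix) {
  if (matrix == "try") config$try_spec else config$giveup_spec
}

level_of <- function(spec, value) {
  if (value == spec$high_value) "high" else "low"
}

#' Derive a child seed from a master seed and indices
#'
#' Deterministic integer hash so any sub-unit (participant, block, round) of a
#' simulation can be regenerated independently. Kept within 32-bit integer
#' range.
#'
#' @param master Integer master seed.
#' @param ... Integer indices (participant, block, round, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483587
  s <- as.numeric(master) %% m
  mult <- c(1000003, 10007, 101, 7)
  for (i in seq_along(idx)) {
    k <- mult[((i - 1) %% length(mult)) + 1]
    s <- (s * 31 + as.numeric(idx[i]) * k) %% m
  }
  as.integer(s) + 1L
}

#' Sample a fresh round
#'
#' Draws the latent outcome of every key in both matrices (i.i.d. high with
#' `p_high`) and returns an unrevealed round state.
#'
#' @param config A [task_config()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return A `round_state`: latent values, revealed masks, 1-based
#'   `trial_index`, `cumulative_points`.
#' @export
sample_round <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(sp) {
    ifelse(stats::runif(sp$n_keys) < sp$p_high, sp$high_value, sp$low_value)
  }
  structure(list(
    latent = list(try = draw(config$try_spec), giveup = draw(config$giveup_spec)),
    revealed = list(try = rep(NA_real_, config$try_spec$n_keys),
                    giveup = rep(NA_real_, config$giveup_spec$n_keys)),
    trial_index = 1L,
    cumulative_points = 0
  ), class = "round_state")
}

#' Press one key
#'
#' Advances the round by one trial: reveals the key if unseen (charging the
#' scheme's exploration cost), applies the scheme's outcome delta, and emits
#' the trial record. Repeated presses of a key always return its latent value
#' ("its outcome remained set until the end of that round").
#'
#' @param state A `round_state`.
#' @param config A [task_config()].
#' @param sch A scheme or scheme name.
#' @param matrix `"try"` or `"giveup"`.
#' @param key_id 0-based key index within the matrix.
#' @return List with `record` (one-row data.frame: matrix, key_id,
#'   first_press, raw_outcome, scheme_delta, cost_charged, net_points, trial)
#'   and the advanced `state`.
#' @export
step_round <- function(state, config, sch, matrix, key_id) {
  sch <- as_scheme(sch)
  matrix <- match.arg(matrix, c("try", "giveup"))
  if (state$trial_index > config$trials_per_round)
    stop("round is over: trial_index exceeds trials_per_round")
  sp <- spec_for(config, matrix)
  k <- as.integer(key_id) + 1L
  if (k < 1L || k > sp$n_keys) stop("key_id out of bounds for ", matrix, " matrix")
  first <- is.na(state$revealed[[matrix]][k])
  raw <- state$latent[[matrix]][k]
  ap <- apply_scheme(sch, matrix, level_of(sp, raw), first)
  net <- raw + ap$delta - ap$cost
  if (first) state$revealed[[matrix]][k] <- raw
  rec <- data.frame(trial = state$trial_index, matrix = matrix,
                    key_id = as.integer(key_id),
                    first_press = as.integer(first),
                    raw_outcome = raw, scheme_delta = ap$delta,
                    cost_charged = ap$cost, net_points = net,
                    stringsAsFactors = FALSE)
  state$trial_index <- state$trial_index + 1L
  state$cumulative_points <- state$cumulative_points + net
  list(record = rec, state = state)
}

# Fast internal round player. `policy` is a function(obs) -> c(matrix_code,
# key1) with matrix_code 1 = try, 2 = giveup and key1 a 1-based index; obs
# exposes only revealed values, so agents cannot read latent outcomes.
# Returns parallel vectors for the round's trials.
play_round_impl <- function(policy, config, sch, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tsp <- config$try_spec; gsp <- config$giveup_spec
  lat_t <- ifelse(stats::runif(tsp$n_keys) < tsp$p_high, tsp$high_value, tsp$low_value)
  lat_g <- ifelse(stats::runif(gsp$n_keys) < gsp$p_high, gsp$high_value, gsp$low_value)
  rev_t <- rep(NA_real_, tsp$n_keys); rev_g <- rep(NA_real_, gsp$n_keys)
  nT <- config$trials_per_round
  d_t <- sch$delta$try; d_g <- sch$delta$giveup
  c_t <- unname(sch$cost["try"]); c_g <- unname(sch$cost["giveup"])
  mat <- integer(nT); key <- integer(nT); fp <- integer(nT)
  raw <- numeric(nT); del <- numeric(nT); cst <- numeric(nT); net <- numeric(nT)
  for (i in seq_len(nT)) {
    ch <- policy(list(trials_remaining = nT - i + 1L,
                      rev_try = rev_t, rev_gu = rev_g))
    m <- ch[1L]; k <- ch[2L]
    if (m == 1L) {
      first <- is.na(rev_t[k]); r <- lat_t[k]
      d <- if (r == tsp$high_value) d_t[["high"]] else d_t[["low"]]
      co <- if (first) c_t else 0
      if (first) rev_t[k] <- r
    } else {
      first <- is.na(rev_g[k]); r <- lat_g[k]
      d <- if (r == gsp$high_value) d_g[["high"]] else d_g[["low"]]
      co <- if (first) c_g else 0
      if (first) rev_g[k] <- r
    }
    mat[i] <- m; key[i] <- k - 1L; fp[i] <- as.integer(first)
    raw[i] <- r; del[i] <- d; cst[i] <- co; net[i] <- r + d - co
  }
  list(trial = seq_len(nT), matrix = c("try", "giveup")[mat], key_id = key,
       first_press = fp, raw_outcome = raw, scheme_delta = del,
       cost_charged = cst, net_points = net)
}
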