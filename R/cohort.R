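#' Default agent population for synthetic cohorts
#'
#' All participants are propensity-learning agents; heterogeneity comes from
#' truncated-normal draws of the learning rate, softmax temperature and
#' retention decay. The shipped values were calibrated once so that a default
#' cohort shows the qualitative phenomena the design assumes (declining
#' Give-Up rates under learning, treatment-block shifts in all conditions,
#' partial retention); they are population knobs, not estimates of human
#' parameters.
#'
#' @return List with `mixture` (weights over agent kinds), truncated-normal
#'   parameter specs `alpha`, `tau`, `rho` (each `mean`, `sd`, `min`, `max`),
#'   and `init_propensities`.
#' @export
default_population <- function() {
  list(mixture = c(adaptive_learner = 1),
       alpha = c(mean = 0.35, sd = 0.15, min = 0.05, max = 0.90),
       tau = c(mean = 5, sd = 2, min = 1, max = 12),
       rho = c(mean = 0.40, sd = 0.20, min = 0.00, max = 0.95),
       init_propensities = c(giveup_search = 14, trylow_settle = 10,
                             try_search = 6))
}

#' Design of a synthetic experiment
#'
#' Defaults reproduce the study design: four between-subject conditions with
#' 53, 55, 54 and 54 participants, three blocks (baseline / treatment /
#' baseline) of 15 rounds by 12 trials.
#'
#' @param n_per_condition Named integer vector: participants per treatment
#'   condition (names are scheme names other than baseline).
#' @param config A [task_config()].
#' @param agent_population See [default_population()]; mixture weights must
#'   sum to 1.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(n_per_condition = c(minus_giveup = 53,
                                              minus_giveup_minus_trylow = 55,
                                              plus_try = 54,
                                              plus_try_explore = 54),
                          config = task_config(),
                          agent_population = default_population()) {
  if (is.null(names(n_per_condition)) ||
      !all(names(n_per_condition) %in% setdiff(list_schemes(), "baseline")))
    stop("n_per_condition must be named by treatment scheme names")
  if (any(n_per_condition < 1)) stop("each condition needs >= 1 participant")
  w <- agent_population$mixture
  if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1")
  structure(list(n_per_condition = n_per_condition, config = config,
                 agent_population = agent_population),
            class = "cohort_design")
}

# inverse-CDF truncated normal draw (deterministic under the current stream)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

draw_agent <- function(pop) {
  kind <- names(pop$mixture)[
    findInterval(stats::runif(1), cumsum(pop$mixture / sum(pop$mixture))) + 1L]
  if (kind == "adaptive_learner") {
    a <- pop$alpha; tpar <- pop$tau; r <- pop$rho
    agent_spec("adaptive_learner",
               alpha = rtrunc_norm(1, a["mean"], a["sd"], a["min"], a["max"]),
               tau = rtrunc_norm(1, tpar["mean"], tpar["sd"], tpar["min"], tpar["max"]),
               rho = rtrunc_norm(1, r["mean"], r["sd"], r["min"], r["max"]),
               init_propensities = pop$init_propensities)
  } else if (kind == "threshold_try") {
    agent_spec("threshold_try", m = pop$m)
  } else {
    agent_spec(kind)
  }
}

#' Generate a full synthetic experiment
#'
#' One row per trial: participants x 3 blocks x rounds x trials. Each
#' participant is an independently drawn agent with persistent parameters;
#' block 2 runs the participant's treatment scheme, blocks 1 and 3 the
#' baseline. For learning agents, propensities persist across blocks but
#' decay toward their initial values by the participant's `rho` at each
#' scheme change. Deterministic given `seed`: every participant, block and
#' round seed is derived from it.
#'
#' @param design A [cohort_design()].
#' @param seed Master seed (required: simulation without a seed is refused).
#' @return A labelled trial-log `data.table` (columns `participant_id`,
#'   `condition`, `block`, `round`, `trial`, `matrix`, `key_id`,
#'   `first_press`, `raw_outcome`, `scheme_delta`, `cost_charged`,
#'   `net_points`, `label`, `optimal_consistent`) with attribute
#'   `"participants"`: the realised per-participant agent parameters.
#' @export
generate_cohort <- function(design, seed) {
  if (missing(seed) || is.null(seed))
    stop("generate_cohort requires a master seed (reproducibility contract)")
  config <- design$config
  pop <- design$agent_population
  conds <- names(design$n_per_condition)
  logs <- list(); parts <- list(); gidx <- 0L
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    schemes <- c("baseline", cond, "baseline")
    for (i in seq_len(design$n_per_condition[[ci]])) {
      gidx <- gidx + 1L
      pid <- sprintf("p%03d", gidx)
      pseed <- derive_seed(seed, ci, i)
      set.seed(pseed)
      agent <- draw_agent(pop)
      prop <- if (agent$kind == "adaptive_learner") agent$init_propensities
      for (b in 1:3) {
        if (b > 1L && agent$kind == "adaptive_learner" &&
            schemes[b] != schemes[b - 1L])
          prop <- decay_propensities(prop, agent$init_propensities, agent$rho)
        res <- play_block(agent, config, schemes[b],
                          n_rounds = config$rounds_per_block,
                          seed = derive_seed(pseed, b),
                          propensities = prop)
        prop <- res$propensities
        bl <- res$log
        bl[, `:=`(participant_id = pid, condition = cond, block = b)]
        logs[[length(logs) + 1L]] <- bl
      }
      parts[[gidx]] <- data.table::data.table(
        participant_id = pid, condition = cond, kind = agent$kind,
        alpha = agent$alpha %||% NA_real_, tau = agent$tau %||% NA_real_,
        rho = agent$rho %||% NA_real_, m = agent$m %||% NA_integer_,
        seed = pseed)
    }
  }
  log <- data.table::rbindlist(logs)
  data.table::setcolorder(log, c("participant_id", "condition", "block",
                                 "round", "trial", "matrix", "key_id",
                                 "first_press", "raw_outcome", "scheme_delta",
                                 "cost_charged", "net_points"))
  log <- label_log(log, config)
  data.table::setattr(log, "participants", data.table::rbindlist(parts))
  log
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-block bonus-round sampling
#'
#' Utility mirroring the payment rule of sampling one round per block and
#' averaging the accumulated points; it plays no role in generation or in the
#' analysis pipeline.
#'
#' @param log A trial log.
#' @param seed Seed for the round sampling.
#' @return data.table per participant: sampled rounds and the mean of the
#'   three sampled rounds' accumulated points.
#' @export
sample_bonus_rounds <- function(log, seed) {
  dt <- data.table::as.data.table(log)
  set.seed(seed)
  totals <- dt[, .(round_points = sum(net_points)),
               by = .(participant_id, block, round)]
  picks <- totals[, .SD[sample(.N, 1L)], by = .(participant_id, block)]
  picks[, .(bonus_points = mean(round_points),
            rounds = paste(round, collapse = ",")), by = participant_id]
}
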