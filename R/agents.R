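META_STRATEGIES <- c("giveup_search", "trylow_settle", "try_search")

#' Specify a round-playing agent
#'
#' Available kinds:
#' \describe{
#'   \item{giveup_searcher}{explores fresh Give-Up keys until a high one is
#'     found, then exploits it — the first local maximum of suboptimal play.}
#'   \item{trylow_settler}{explores one Try key and exploits whatever it
#'     finds — the under-exploration local maximum.}
#'   \item{threshold_try}{the `S_m` family member (see
#'     [benchmark_strategy_comparison()]); requires `m`.}
#'   \item{dp_optimal}{plays the backward-induction policy for the scheme it
#'     is run under (full-information benchmark).}
#'   \item{adaptive_learner}{chooses one meta-strategy per round (Give-Up
#'     search, Try-low settling, Try search) by softmax over payoff
#'     propensities; requires `alpha` (learning rate), `tau` (softmax
#'     temperature), `rho` (decay toward initial propensities when the scheme
#'     changes) and optionally `init_propensities`.}
#' }
#' Parameters that a kind does not use are rejected.
#'
#' @param kind Agent kind.
#' @param m Threshold for `threshold_try`.
#' @param alpha Learning rate in (0, 1] (`adaptive_learner`).
#' @param tau Softmax temperature >= 0; 0 means deterministic argmax
#'   (`adaptive_learner`).
#' @param rho Retention decay in \[0, 1\] applied at scheme changes
#'   (`adaptive_learner`).
#' @param init_propensities Named numeric over
#'   `giveup_search`, `trylow_settle`, `try_search` (`adaptive_learner`).
#' @return An `agent_spec` object.
#' @export
agent_spec <- function(kind = c("giveup_searcher", "trylow_settler",
                                "threshold_try", "dp_optimal",
                                "adaptive_learner"),
                       m = NULL, alpha = NULL, tau = NULL, rho = NULL,
                       init_propensities = NULL) {
  kind <- match.arg(kind)
  supplied <- list(m = m, alpha = alpha, tau = tau, rho = rho,
                   init_propensities = init_propensities)
  used <- switch(kind,
    threshold_try = "m",
    adaptive_learner = c("alpha", "tau", "rho", "init_propensities"),
    character(0))
  extra <- setdiff(names(Filter(Negate(is.null), supplied)), used)
  if (length(extra))
    stop("parameters not used by kind '", kind, "': ",
         paste(extra, collapse = ", "))
  if (kind == "threshold_try") {
    if (is.null(m) || m < 0) stop("threshold_try requires m >= 0")
    m <- as.integer(m)
  }
  if (kind == "adaptive_learner") {
    if (is.null(alpha) || alpha <= 0 || alpha > 1)
      stop("adaptive_learner requires alpha in (0, 1]")
    if (is.null(tau) || tau < 0)
      stop("adaptive_learner requires tau >= 0")
    if (is.null(rho) || rho < 0 || rho > 1)
      stop("adaptive_learner requires rho in [0, 1]")
    if (is.null(init_propensities))
      init_propensities <- c(giveup_search = 14, trylow_settle = 10,
                             try_search = 6)
    if (!setequal(names(init_propensities), META_STRATEGIES))
      stop("init_propensities must be named over: ",
           paste(META_STRATEGIES, collapse = ", "))
    init_propensities <- init_propensities[META_STRATEGIES]
  }
  structure(list(kind = kind, m = m, alpha = alpha, tau = tau, rho = rho,
                 init_propensities = init_propensities),
            class = "agent_spec")
}

# --- concrete within-round policies (1-based keys; obs holds revealed maps) --

policy_giveup_search <- function(config) {
  hv <- config$giveup_spec$high_value
  function(obs) {
    high <- which(obs$rev_gu == hv)
    if (length(high)) return(c(2L, high[1L]))
    fresh <- which(is.na(obs$rev_gu))
    if (length(fresh)) return(c(2L, fresh[1L]))
    c(2L, which.max(obs$rev_gu))
  }
}

policy_trylow_settle <- function(config) {
  function(obs) {
    seen <- which(!is.na(obs$rev_try))
    if (length(seen)) return(c(1L, seen[1L]))
    c(1L, which(is.na(obs$rev_try))[1L])
  }
}

policy_try_search <- function(config) {
  hv <- config$try_spec$high_value
  function(obs) {
    high <- which(obs$rev_try == hv)
    if (length(high)) return(c(1L, high[1L]))
    fresh <- which(is.na(obs$rev_try))
    if (length(fresh)) return(c(1L, fresh[1L]))
    c(1L, which.max(obs$rev_try))
  }
}

policy_threshold_try <- function(config, m) {
  hv_t <- config$try_spec$high_value
  low_t <- config$try_spec$low_value
  gu <- policy_giveup_search(config)
  function(obs) {
    high <- which(obs$rev_try == hv_t)
    if (length(high)) return(c(1L, high[1L]))
    failures <- sum(!is.na(obs$rev_try))
    fresh <- which(is.na(obs$rev_try))
    if (failures < m && length(fresh)) return(c(1L, fresh[1L]))
    gu(obs)
  }
}

policy_dp <- function(config, sch, policy = NULL) {
  if (is.null(policy)) policy <- solve_dp(config, sch)
  hv_t <- config$try_spec$high_value
  hv_g <- config$giveup_spec$high_value
  act <- policy$action
  function(obs) {
    rt <- obs$rev_try; rg <- obs$rev_gu
    ut <- sum(is.na(rt)); ug <- sum(is.na(rg))
    bt <- if (ut == length(rt)) 1L else if (any(rt == hv_t, na.rm = TRUE)) 3L else 2L
    bg <- if (ug == length(rg)) 1L else if (any(rg == hv_g, na.rm = TRUE)) 3L else 2L
    a <- act[obs$trials_remaining + 1L, bt, bg, ut + 1L, ug + 1L]
    switch(a,
      c(1L, which(rt == hv_t)[1L]),                      # EXPLOIT_TRY_HIGH
      c(1L, which(is.na(rt))[1L]),                       # EXPLORE_TRY
      c(2L, which(rg == hv_g)[1L]),                      # EXPLOIT_GIVEUP_HIGH
      c(2L, which(is.na(rg))[1L]),                       # EXPLORE_GIVEUP
      c(2L, which(!is.na(rg) & rg != hv_g)[1L]),         # EXPLOIT_GIVEUP_LOW
      c(1L, which(!is.na(rt) & rt != hv_t)[1L])          # EXPLOIT_TRY_LOW
    )
  }
}

meta_policy <- function(strategy, config) {
  switch(strategy,
    giveup_search = policy_giveup_search(config),
    trylow_settle = policy_trylow_settle(config),
    try_search = policy_try_search(config),
    stop("unknown meta-strategy: ", strategy))
}

#' Softmax choice over meta-strategy propensities
#'
#' With temperature `tau = 0` the choice is the deterministic argmax (first
#' of the fixed strategy order on exact ties).
#'
#' @param propensities Named numeric over the meta-strategies.
#' @param tau Temperature >= 0.
#' @return The chosen strategy name (consumes one RNG draw when `tau > 0`).
#' @export
softmax_choice <- function(propensities, tau) {
  if (any(!is.finite(propensities))) stop("non-finite propensities")
  if (tau <= 0) return(names(propensities)[which.max(propensities)])
  w <- exp((propensities - max(propensities)) / tau)
  p <- w / sum(w)
  names(propensities)[findInterval(stats::runif(1), cumsum(p)) + 1L]
}

#' Update learner propensities after a round
#'
#' Moves the chosen meta-strategy's propensity toward the realised round
#' payoff by step `alpha`; other propensities are unchanged.
#'
#' @param propensities Named numeric over the meta-strategies.
#' @param strategy The meta-strategy played this round.
#' @param payoff Realised round net payoff.
#' @param alpha Learning rate in (0, 1].
#' @return Updated propensities.
#' @export
update_learner <- function(propensities, strategy, payoff, alpha) {
  if (!is.finite(payoff) || any(!is.finite(propensities)))
    stop("non-finite propensities or payoff")
  propensities[strategy] <- propensities[strategy] +
    alpha * (payoff - propensities[strategy])
  if (any(!is.finite(propensities))) stop("non-finite propensities after update")
  propensities
}

#' Decay propensities toward their initial values
#'
#' Applied when the incentive scheme changes between blocks: a retention
#' knob. `rho = 0` keeps the learned propensities; `rho = 1` resets them.
#'
#' @param propensities Current propensities.
#' @param init Initial propensities.
#' @param rho Decay in \[0, 1\].
#' @return Partially reset propensities.
#' @export
decay_propensities <- function(propensities, init, rho) {
  (1 - rho) * propensities + rho * init[names(propensities)]
}

#' Play one round
#'
#' The agent observes only revealed outcomes, never the latent values of
#' unexplored keys. Deterministic given `seed`.
#'
#' @param agent An [agent_spec()].
#' @param config A [task_config()].
#' @param sch A scheme or scheme name.
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @param propensities For `adaptive_learner`, the current propensities
#'   (defaults to the agent's initial ones).
#' @param policy For `dp_optimal`, a pre-solved [solve_dp()] table to avoid
#'   re-solving on every round (it must match `config` and `sch`).
#' @return A `data.table` with one row per trial (`trial`, `matrix`,
#'   `key_id`, `first_press`, `raw_outcome`, `scheme_delta`, `cost_charged`,
#'   `net_points`). For learners the chosen meta-strategy is attached as
#'   attribute `"strategy"`.
#' @export
play_round <- function(agent, config, sch, seed = NULL, propensities = NULL,
                       policy = NULL) {
  sch <- as_scheme(sch)
  if (!is.null(seed)) set.seed(seed)
  strategy <- NULL
  pol <- switch(agent$kind,
    giveup_searcher = policy_giveup_search(config),
    trylow_settler = policy_trylow_settle(config),
    threshold_try = policy_threshold_try(config, agent$m),
    dp_optimal = policy_dp(config, sch, policy),
    adaptive_learner = {
      if (is.null(propensities)) propensities <- agent$init_propensities
      strategy <- softmax_choice(propensities, agent$tau)
      meta_policy(strategy, config)
    })
  out <- data.table::as.data.table(play_round_impl(pol, config, sch, seed = NULL))
  if (!is.null(strategy)) data.table::setattr(out, "strategy", strategy)
  out
}

#' Play a block of rounds
#'
#' For fixed agents each round is independent; for the `adaptive_learner`
#' propensities carry over between rounds (softmax choice before the round,
#' payoff-driven update after). Round seeds are derived from `seed` and the
#' round index so any round is independently reproducible.
#'
#' @param agent An [agent_spec()].
#' @param config A [task_config()].
#' @param sch A scheme or scheme name.
#' @param n_rounds Number of rounds.
#' @param seed Integer block seed.
#' @param propensities Starting propensities for a learner (defaults to the
#'   agent's initial ones).
#' @param policy Optional pre-solved policy for `dp_optimal` agents.
#' @return List: `log` (data.table with a `round` column), `propensities`
#'   (final learner state or `NULL`), `strategies` and `payoffs` per round.
#' @export
play_block <- function(agent, config, sch, n_rounds, seed,
                       propensities = NULL, policy = NULL) {
  sch <- as_scheme(sch)
  if (agent$kind == "adaptive_learner" && is.null(propensities))
    propensities <- agent$init_propensities
  if (agent$kind == "dp_optimal" && is.null(policy))
    policy <- solve_dp(config, sch)
  logs <- vector("list", n_rounds)
  strategies <- character(n_rounds)
  payoffs <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    rl <- play_round(agent, config, sch, seed = derive_seed(seed, r),
                     propensities = propensities, policy = policy)
    rl[, round := r]
    payoffs[r] <- sum(rl$net_points)
    st <- attr(rl, "strategy")
    if (!is.null(st)) {
      strategies[r] <- st
      propensities <- update_learner(propensities, st, payoffs[r], agent$alpha)
    } else strategies[r] <- agent$kind
    logs[[r]] <- rl
  }
  log <- data.table::rbindlist(logs)
  data.table::setcolorder(log, c("round", "trial"))
  list(log = log,
       propensities = if (agent$kind == "adaptive_learner") propensities,
       strategies = strategies, payoffs = payoffs)
}
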