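DP_ACTIONS <- c("EXPLOIT_TRY_HIGH", "EXPLORE_TRY", "EXPLOIT_GIVEUP_HIGH",
                "EXPLORE_GIVEUP", "EXPLOIT_GIVEUP_LOW", "EXPLOIT_TRY_LOW")

# probability that a freshly revealed key is *classified* high. Levels are
# classified by outcome value, so when high_value == low_value every revealed
# key reads as high regardless of its latent type.
class_p_high <- function(sp) {
  if (sp$high_value == sp$low_value) 1 else sp$p_high
}

# effective (scheme-adjusted) outcome values per matrix
eff_values <- function(config, sch) {
  list(try = c(low = config$try_spec$low_value + sch$delta$try[["low"]],
               high = config$try_spec$high_value + sch$delta$try[["high"]]),
       giveup = c(low = config$giveup_spec$low_value + sch$delta$giveup[["low"]],
                  high = config$giveup_spec$high_value + sch$delta$giveup[["high"]]))
}

#' Solve the task by belief-state backward induction
#'
#' Because keys are i.i.d. within a matrix, the decision-relevant state is
#' `(trials remaining, best revealed level per matrix, unexplored count per
#' matrix)`: exploration yields a high key with the matrix's `p_high` and no
#' posterior updating is needed, only key-availability bookkeeping. The value
#' of a state is the maximum over available actions of expected immediate net
#' payoff (exploration cost included) plus the successor value. Exploit
#' actions target the best revealed level of a matrix; exactness therefore
#' requires schemes that preserve the low <= high ordering of effective
#' outcomes, which all five named schemes do.
#'
#' Ties are broken by the fixed action order `EXPLOIT_TRY_HIGH`,
#' `EXPLORE_TRY`, `EXPLOIT_GIVEUP_HIGH`, `EXPLORE_GIVEUP`,
#' `EXPLOIT_GIVEUP_LOW`, `EXPLOIT_TRY_LOW`, so solved policies are
#' deterministic and reproducible.
#'
#' @param config A [task_config()].
#' @param sch A scheme or scheme name.
#' @return A `policy_table`: 5-dimensional `value` and `action` arrays indexed
#'   by (trials remaining, best try, best giveup, unexplored try, unexplored
#'   giveup), plus the config and scheme.
#' @export
solve_dp <- function(config, sch) {
  sch <- as_scheme(sch)
  v <- eff_values(config, sch)
  pt <- class_p_high(config$try_spec); pg <- class_p_high(config$giveup_spec)
  ct <- unname(sch$cost["try"]); cg <- unname(sch$cost["giveup"])
  Tn <- config$trials_per_round
  Kt <- config$try_spec$n_keys; Kg <- config$giveup_spec$n_keys
  dims <- c(Tn + 1L, 3L, 3L, Kt + 1L, Kg + 1L)
  V <- array(0, dim = dims)
  A <- array(NA_integer_, dim = dims)
  imm_t <- pt * v$try[["high"]] + (1 - pt) * v$try[["low"]] - ct
  imm_g <- pg * v$giveup[["high"]] + (1 - pg) * v$giveup[["low"]] - cg
  for (t in seq_len(Tn)) {
    it <- t + 1L
    for (bt in 1:3) for (bg in 1:3) for (ut in 0:Kt) for (ug in 0:Kg) {
      iu <- ut + 1L; ig <- ug + 1L
      best <- -Inf; besta <- NA_integer_
      # actions evaluated in tie-break priority order; strict > keeps first
      if (bt == 3L) {
        val <- v$try[["high"]] + V[t, bt, bg, iu, ig]
        if (val > best) { best <- val; besta <- 1L }
      }
      if (ut > 0L) {
        val <- imm_t + pt * V[t, 3L, bg, iu - 1L, ig] +
          (1 - pt) * V[t, max(bt, 2L), bg, iu - 1L, ig]
        if (val > best) { best <- val; besta <- 2L }
      }
      if (bg == 3L) {
        val <- v$giveup[["high"]] + V[t, bt, bg, iu, ig]
        if (val > best) { best <- val; besta <- 3L }
      }
      if (ug > 0L) {
        val <- imm_g + pg * V[t, bt, 3L, iu, ig - 1L] +
          (1 - pg) * V[t, bt, max(bg, 2L), iu, ig - 1L]
        if (val > best) { best <- val; besta <- 4L }
      }
      if (bg == 2L) {
        val <- v$giveup[["low"]] + V[t, bt, bg, iu, ig]
        if (val > best) { best <- val; besta <- 5L }
      }
      if (bt == 2L) {
        val <- v$try[["low"]] + V[t, bt, bg, iu, ig]
        if (val > best) { best <- val; besta <- 6L }
      }
      if (is.finite(best)) {
        V[it, bt, bg, iu, ig] <- best
        A[it, bt, bg, iu, ig] <- besta
      } # states with no action (no keys anywhere) keep value 0
    }
  }
  structure(list(value = V, action = A, config = config, scheme = sch),
            class = "policy_table")
}

best_code <- function(x) match(x, c("none", "low", "high"))

#' Query a solved policy
#'
#' @param policy A `policy_table` from [solve_dp()].
#' @param trials_remaining Trials left in the round (>= 1).
#' @param best_try,best_giveup `"none"`, `"low"` or `"high"`.
#' @param unexplored_try,unexplored_giveup Unexplored key counts.
#' @return List with `action` (one of the six action names) and `value`
#'   (expected remaining net points under optimal play).
#' @export
policy_action <- function(policy, trials_remaining, best_try, best_giveup,
                          unexplored_try, unexplored_giveup) {
  it <- trials_remaining + 1L
  bt <- best_code(best_try); bg <- best_code(best_giveup)
  iu <- unexplored_try + 1L; ig <- unexplored_giveup + 1L
  list(action = DP_ACTIONS[policy$action[it, bt, bg, iu, ig]],
       value = policy$value[it, bt, bg, iu, ig])
}

#' Root value of a solved policy
#'
#' Expected net points of a full round played optimally from the initial
#' state (nothing revealed, all keys unexplored).
#'
#' @param policy A `policy_table`.
#' @return Numeric scalar.
#' @export
root_value <- function(policy) {
  cf <- policy$config
  policy$value[cf$trials_per_round + 1L, 1L, 1L,
               cf$try_spec$n_keys + 1L, cf$giveup_spec$n_keys + 1L]
}

#' @export
print.policy_table <- function(x, ...) {
  cf <- x$config
  cat("<policy_table>", x$scheme$name, "scheme;",
      cf$trials_per_round, "trials;",
      cf$try_spec$n_keys, "+", cf$giveup_spec$n_keys, "keys\n")
  rs <- policy_action(x, cf$trials_per_round, "none", "none",
                      cf$try_spec$n_keys, cf$giveup_spec$n_keys)
  cat("  root action:", rs$action, " root value:", format(rs$value), "\n")
  invisible(x)
}

#' Exact optimal value by exhaustive recursion (oracle)
#'
#' Independent check on [solve_dp()]: enumerates every concrete action
#' sequence and outcome realisation over full information sets (per-key
#' revealed values, no belief abstraction). Exponential, so refuses instances
#' beyond 4 trials or 3 keys per matrix.
#'
#' @param config Small [task_config()].
#' @param sch A scheme or scheme name.
#' @return Exact optimal expected net points for the round.
#' @export
brute_force_value <- function(config, sch) {
  sch <- as_scheme(sch)
  if (config$trials_per_round > 4L)
    stop("brute_force_value refuses instances with > 4 trials")
  if (config$try_spec$n_keys > 3L || config$giveup_spec$n_keys > 3L)
    stop("brute_force_value refuses instances with > 3 keys per matrix")
  v <- eff_values(config, sch)
  tsp <- config$try_spec; gsp <- config$giveup_spec
  pct <- class_p_high(tsp); pcg <- class_p_high(gsp)
  ct <- unname(sch$cost["try"]); cg <- unname(sch$cost["giveup"])
  rec <- function(t, rt, rg) {
    if (t == 0L) return(0)
    best <- -Inf
    for (k in seq_len(tsp$n_keys)) {
      if (is.na(rt[k])) {
        hi <- v$try[["high"]] + { r2 <- rt; r2[k] <- tsp$high_value; rec(t - 1L, r2, rg) }
        lo <- v$try[["low"]] + { r2 <- rt; r2[k] <- tsp$low_value; rec(t - 1L, r2, rg) }
        val <- pct * hi + (1 - pct) * lo - ct
      } else {
        lev <- if (rt[k] == tsp$high_value) "high" else "low"
        val <- v$try[[lev]] + rec(t - 1L, rt, rg)
      }
      if (val > best) best <- val
    }
    for (k in seq_len(gsp$n_keys)) {
      if (is.na(rg[k])) {
        hi <- v$giveup[["high"]] + { r2 <- rg; r2[k] <- gsp$high_value; rec(t - 1L, rt, r2) }
        lo <- v$giveup[["low"]] + { r2 <- rg; r2[k] <- gsp$low_value; rec(t - 1L, rt, r2) }
        val <- pcg * hi + (1 - pcg) * lo - cg
      } else {
        lev <- if (rg[k] == gsp$high_value) "high" else "low"
        val <- v$giveup[[lev]] + rec(t - 1L, rt, rg)
      }
      if (val > best) best <- val
    }
    best
  }
  rec(config$trials_per_round,
      rep(NA_real_, tsp$n_keys), rep(NA_real_, gsp$n_keys))
}

#' Export a solved policy as JSON
#'
#' One entry per reachable state, keyed
#' `"<trials>|<best_try>|<best_giveup>|<unexplored_try>|<unexplored_giveup>"`,
#' each listing the optimal action and state value. Round-trips through
#' [read_policy_json()].
#'
#' @param policy A `policy_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_policy_json <- function(policy, path) {
  cf <- policy$config
  Kt <- cf$try_spec$n_keys; Kg <- cf$giveup_spec$n_keys
  lv <- c("none", "low", "high")
  out <- list()
  for (t in seq_len(cf$trials_per_round)) for (bt in 1:3) for (bg in 1:3)
    for (ut in 0:Kt) for (ug in 0:Kg) {
      # reachable iff best is none exactly when nothing explored
      if ((bt == 1L) != (ut == Kt) || (bg == 1L) != (ug == Kg)) next
      a <- policy$action[t + 1L, bt, bg, ut + 1L, ug + 1L]
      if (is.na(a)) next
      key <- paste(t, lv[bt], lv[bg], ut, ug, sep = "|")
      out[[key]] <- list(action = DP_ACTIONS[a],
                         value = policy$value[t + 1L, bt, bg, ut + 1L, ug + 1L])
    }
  jsonlite::write_json(list(scheme = policy$scheme$name,
                            trials_per_round = cf$trials_per_round,
                            n_keys = c(try = Kt, giveup = Kg),
                            states = out),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a policy JSON export
#'
#' @param path File written by [write_policy_json()].
#' @return List with `scheme`, `trials_per_round`, `n_keys` and a `states`
#'   list keyed by the 5-tuple state string.
#' @export
read_policy_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
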