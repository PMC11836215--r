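#' Treatment scheme names
#'
#' The baseline payoff structure plus the four incentive interventions applied
#' in the middle experimental block: punishing Give-Up choices, punishing both
#' Give-Up and low-Try choices, rewarding any Try choice, and rewarding Try
#' exploration by waiving its exploration cost.
#'
#' @return Character vector of the five recognised scheme names.
#' @export
list_schemes <- function() {
  c("baseline", "minus_giveup", "minus_giveup_minus_trylow",
    "plus_try", "plus_try_explore")
}

#' Construct a treatment scheme
#'
#' A scheme is an additive transformation of the baseline incentive structure:
#' per-matrix, per-level outcome deltas plus a per-matrix exploration cost
#' charged on the first press of a key within a round.
#'
#' The five named schemes encode the study design:
#' \describe{
#'   \item{baseline}{no deltas, exploration cost 2 on both matrices.}
#'   \item{minus_giveup}{-2 on every Give-Up outcome.}
#'   \item{minus_giveup_minus_trylow}{-2 on every Give-Up outcome and on every
#'     low Try outcome (high Try outcomes untouched).}
#'   \item{plus_try}{+2 on every Try outcome.}
#'   \item{plus_try_explore}{outcomes unchanged; the Try matrix's exploration
#'     cost is waived (0) while Give-Up keys keep cost 2.}
#' }
#'
#' @param name One of [list_schemes()].
#' @return An object of class `scheme`: list with `name`, `delta` (list of
#'   named numeric vectors `try`, `giveup`, each with elements `low`, `high`)
#'   and `cost` (named numeric vector over matrices).
#' @export
scheme <- function(name) {
  name <- match.arg(name, list_schemes())
  delta <- list(try = c(low = 0, high = 0), giveup = c(low = 0, high = 0))
  cost <- c(try = 2, giveup = 2)
  switch(name,
    baseline = NULL,
    minus_giveup = {
      delta$giveup[] <- -2
    },
    minus_giveup_minus_trylow = {
      delta$giveup[] <- -2
      delta$try["low"] <- -2
    },
    plus_try = {
      delta$try[] <- 2
    },
    plus_try_explore = {
      cost["try"] <- 0
    }
  )
  structure(list(name = name, delta = delta, cost = cost), class = "scheme")
}

#' Construct a custom scheme
#'
#' Mainly for experimentation and randomised testing; the named study schemes
#' come from [scheme()].
#'
#' @param delta_try,delta_giveup Numeric length-2 vectors `c(low =, high =)`.
#' @param cost_try,cost_giveup Nonnegative exploration costs.
#' @param name Label.
#' @return A `scheme` object.
#' @export
custom_scheme <- function(delta_try = c(low = 0, high = 0),
                          delta_giveup = c(low = 0, high = 0),
                          cost_try = 2, cost_giveup = 2,
                          name = "custom") {
  stopifnot(length(delta_try) == 2, length(delta_giveup) == 2,
            cost_try >= 0, cost_giveup >= 0)
  delta_try <- stats::setNames(as.numeric(delta_try), c("low", "high"))
  delta_giveup <- stats::setNames(as.numeric(delta_giveup), c("low", "high"))
  structure(list(name = name,
                 delta = list(try = delta_try, giveup = delta_giveup),
                 cost = c(try = as.numeric(cost_try),
                          giveup = as.numeric(cost_giveup))),
            class = "scheme")
}

as_scheme <- function(x) {
  if (inherits(x, "scheme")) return(x)
  if (is.character(x) && length(x) == 1) return(scheme(x))
  stop("not a scheme: supply a scheme object or one of ",
       paste(list_schemes(), collapse = ", "))
}

#' Apply a scheme to a single choice
#'
#' Pure function giving the additive outcome adjustment and the exploration
#' cost actually charged for a press of a `matrix` key at outcome `level`.
#'
#' @param sch A `scheme` object or scheme name.
#' @param matrix `"try"` or `"giveup"`.
#' @param level `"low"` or `"high"`.
#' @param first_press Logical; is this the key's first press this round?
#' @return List with numeric `delta` and `cost` (cost is 0 unless
#'   `first_press`).
#' @export
apply_scheme <- function(sch, matrix, level, first_press) {
  sch <- as_scheme(sch)
  matrix <- match.arg(matrix, c("try", "giveup"))
  level <- match.arg(level, c("low", "high"))
  list(delta = unname(sch$delta[[matrix]][level]),
       cost = if (isTRUE(first_press)) unname(sch$cost[matrix]) else 0)
}

#' @export
print.scheme <- function(x, ...) {
  cat("<scheme>", x$name, "\n")
  cat("  delta try   : low", x$delta$try["low"], " high", x$delta$try["high"], "\n")
  cat("  delta giveup: low", x$delta$giveup["low"], " high", x$delta$giveup["high"], "\n")
  cat("  exploration cost: try", x$cost["try"], " giveup", x$cost["giveup"], "\n")
  invisible(x)
}
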