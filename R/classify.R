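CHOICE_CATEGORIES <- c("GIVEUP", "TRY_EXPLORE", "TRY_LOW_EXPLOIT",
                       "TRY_HIGH_EXPLOIT")

#' Classify one choice against the optimal-strategy benchmark
#'
#' Categories partition all choices: any Give-Up press is `GIVEUP`; a fresh
#' Try press is `TRY_EXPLORE`; re-pressing a revealed Try key is
#' `TRY_LOW_EXPLOIT` or `TRY_HIGH_EXPLOIT` by its revealed level. A choice is
#' benchmark-consistent (`optimal_consistent`) iff no high Try key is known
#' and the choice explores a fresh Try key, or a high Try key is known and
#' the choice exploits such a key.
#'
#' @param history List with `rev_try` and `rev_gu`: numeric vectors of
#'   revealed values before the trial, `NA` for unexplored keys.
#' @param matrix `"try"` or `"giveup"`.
#' @param key_id 0-based key index.
#' @param config A [task_config()] (supplies the high-outcome values).
#' @return List with `category` and logical `optimal_consistent`.
#' @export
classify_choice <- function(history, matrix, key_id, config = task_config()) {
  matrix <- match.arg(matrix, c("try", "giveup"))
  k <- as.integer(key_id) + 1L
  hv <- config$try_spec$high_value
  high_known <- any(history$rev_try == hv, na.rm = TRUE)
  if (matrix == "giveup") {
    return(list(category = "GIVEUP", optimal_consistent = FALSE))
  }
  val <- history$rev_try[k]
  if (is.na(val)) {
    list(category = "TRY_EXPLORE", optimal_consistent = !high_known)
  } else if (val == hv) {
    list(category = "TRY_HIGH_EXPLOIT", optimal_consistent = TRUE)
  } else {
    list(category = "TRY_LOW_EXPLOIT", optimal_consistent = FALSE)
  }
}

#' Label every trial of a log
#'
#' Vectorised replay of [classify_choice()] over a trial log: within each
#' round (grouped by participant, block and round, ordered by trial) it
#' tracks whether a high Try key was revealed before each trial and assigns
#' the category and benchmark-consistency flag.
#'
#' @param log A trial log (`data.frame`/`data.table`) with at least `matrix`,
#'   `first_press`, `raw_outcome`, `trial` and, if present, grouping columns
#'   `participant_id`, `condition`, `block`, `round`.
#' @param config A [task_config()].
#' @return A `data.table` copy of `log` with `label` and `optimal_consistent`
#'   columns (flags as 0/1).
#' @export
label_log <- function(log, config = task_config()) {
  dt <- data.table::as.data.table(log)
  hv <- config$try_spec$high_value
  grp <- intersect(c("participant_id", "condition", "block", "round"), names(dt))
  data.table::setorderv(dt, c(grp, "trial"))
  is_try <- dt$matrix == "try"
  reveal_high <- as.integer(is_try & dt$first_press == 1L & dt$raw_outcome == hv)
  dt[, `:=`(.tmp_rh = reveal_high)]
  if (length(grp)) {
    dt[, `:=`(.tmp_hk = {
      cs <- cumsum(.tmp_rh)
      data.table::shift(cs, fill = 0L) > 0L
    }), by = grp]
  } else {
    cs <- cumsum(dt$.tmp_rh)
    dt[, `:=`(.tmp_hk = data.table::shift(cs, fill = 0L) > 0L)]
  }
  high_known <- dt$.tmp_hk
  label <- data.table::fifelse(!is_try, "GIVEUP",
    data.table::fifelse(dt$first_press == 1L, "TRY_EXPLORE",
      data.table::fifelse(dt$raw_outcome == hv, "TRY_HIGH_EXPLOIT",
                          "TRY_LOW_EXPLOIT")))
  optimal <- (is_try & dt$first_press == 1L & !high_known) |
    (is_try & dt$first_press == 0L & dt$raw_outcome == hv)
  dt[, `:=`(label = label, optimal_consistent = as.integer(optimal))]
  dt[, c(".tmp_rh", ".tmp_hk") := NULL]
  dt[]
}
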