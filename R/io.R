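TRIAL_LOG_COLUMNS <- c("participant_id", "condition", "block", "round",
                       "trial", "matrix", "key_id", "first_press",
                       "raw_outcome", "scheme_delta", "cost_charged",
                       "net_points", "label", "optimal_consistent")

read_structured <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

check_fields <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown field(s) in ", where, ": ", paste(unknown, collapse = ", "))
}

build_spec <- function(lst, default, where) {
  if (is.null(lst)) return(default)
  check_fields(lst, c("low_value", "high_value", "p_high", "n_keys"), where)
  matrix_spec(lst$low_value %||% default$low_value,
              lst$high_value %||% default$high_value,
              lst$p_high %||% default$p_high,
              lst$n_keys %||% default$n_keys)
}

#' Load a task configuration file
#'
#' YAML (or JSON) with optional fields `try`, `giveup` (each `low_value`,
#' `high_value`, `p_high`, `n_keys`), `trials_per_round`, `rounds_per_block`,
#' `block_schemes`, `analysis_window`. Unknown fields are rejected with a
#' message naming them; an empty file yields the full default structure
#' (Try +1/.9 and +14/.1, Give-Up +1/.5 and +2/.5, cost 2, 12 trials,
#' 15 rounds, 9-trial window).
#'
#' @param path Path to the config file, or `NULL` for the packaged default.
#' @return A [task_config()].
#' @export
load_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_task.yaml", package = "trygiveup")
  raw <- read_structured(path)
  if (is.null(raw)) raw <- list()
  check_fields(raw, c("try", "giveup", "trials_per_round", "rounds_per_block",
                      "block_schemes", "analysis_window"), path)
  d <- task_config()
  task_config(try_spec = build_spec(raw$try, d$try_spec, "try"),
              giveup_spec = build_spec(raw$giveup, d$giveup_spec, "giveup"),
              trials_per_round = raw$trials_per_round %||% d$trials_per_round,
              rounds_per_block = raw$rounds_per_block %||% d$rounds_per_block,
              block_schemes = raw$block_schemes %||% d$block_schemes,
              analysis_window = raw$analysis_window %||% d$analysis_window)
}

#' Load a cohort design file
#'
#' YAML (or JSON) with optional fields `n_per_condition` (named by treatment
#' scheme), `task` (as in [load_config()]) and `population` (`mixture`,
#' `alpha`, `tau`, `rho`, `init_propensities`). Unknown fields are rejected.
#'
#' @param path Path to the design file, or `NULL` for the packaged default.
#' @return A [cohort_design()].
#' @export
load_design <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_cohort.yaml", package = "trygiveup")
  raw <- read_structured(path)
  if (is.null(raw)) raw <- list()
  check_fields(raw, c("n_per_condition", "task", "population"), path)
  config <- if (is.null(raw$task)) task_config() else {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(raw$task, tmp)
    load_config(tmp)
  }
  pop <- default_population()
  if (!is.null(raw$population)) {
    check_fields(raw$population, names(pop), "population")
    for (nm in names(raw$population)) pop[[nm]] <- unlist(raw$population[[nm]])
  }
  n <- if (is.null(raw$n_per_condition)) {
    formals(cohort_design)$n_per_condition
    c(minus_giveup = 53, minus_giveup_minus_trylow = 55,
      plus_try = 54, plus_try_explore = 54)
  } else unlist(raw$n_per_condition)
  cohort_design(n_per_condition = n, config = config, agent_population = pop)
}

#' Write a trial log CSV
#'
#' Fixed column order (header mandatory), `matrix` in `try`/`giveup`, flags
#' as 0/1, points as decimals; byte-stable for identical inputs.
#'
#' @param log A trial log.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  dt <- data.table::as.data.table(log)
  cols <- intersect(TRIAL_LOG_COLUMNS, names(dt))
  data.table::fwrite(dt[, ..cols], path, eol = "\n")
  invisible(path)
}

#' Read and validate a trial log CSV
#'
#' @param path CSV written by [write_trial_log()] (or produced externally in
#'   the same schema).
#' @return A `data.table` trial log.
#' @export
read_trial_log <- function(path) {
  dt <- data.table::fread(path)
  req <- setdiff(TRIAL_LOG_COLUMNS, c("label", "optimal_consistent"))
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("trial log is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!dt$matrix %in% c("try", "giveup"))
  if (length(bad))
    stop("invalid matrix value at row ", bad[1])
  bad <- which(!dt$first_press %in% c(0L, 1L))
  if (length(bad))
    stop("invalid first_press flag at row ", bad[1])
  bad <- which(abs(dt$net_points -
                     (dt$raw_outcome + dt$scheme_delta - dt$cost_charged)) > 1e-9)
  if (length(bad))
    stop("net-points decomposition violated at row ", bad[1])
  dt
}

#' Write a run manifest
#'
#' Records command, configuration hash, master seed, package version, output
#' paths and timestamp alongside any artifact-producing run.
#'
#' @param path Manifest path (JSON).
#' @param command Name of the command/driver.
#' @param config Any serialisable configuration object.
#' @param seed Master seed of the run.
#' @param outputs Character vector of output paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config, seed, outputs) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(
    command = command,
    config_hash = unname(tools::md5sum(tmp)),
    seed = seed,
    package_version = as.character(utils::packageVersion("trygiveup")),
    outputs = outputs,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write the realised-participant sidecar
#'
#' @param log A cohort log from [generate_cohort()].
#' @param path Sidecar path (JSON).
#' @return `path`, invisibly.
#' @export
write_participant_sidecar <- function(log, path) {
  parts <- attr(log, "participants")
  if (is.null(parts)) stop("log carries no participant attribute")
  jsonlite::write_json(parts, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
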