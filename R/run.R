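# end-to-end pipeline driver: one structured config, one global seed,
# artifacts on disk with the producing config's hash embedded

run_config_schema <- list(
  seed = c("seed"),
  synthetic = c("j_wrist", "j_grip", "snr_db", "grip_spillover",
                "loading_jitter", "n_trials", "n_reps", "diagonal_bias",
                "amplitude_deg"),
  preprocess = c("cutoff", "order", "zero_phase", "rate"),
  hals = c("max_sweeps", "tol", "n_restarts"),
  model = c("strategy", "j_wrist", "j_grip", "select_j",
            "include_grip_regressor"),
  cv = c("train_condition", "grip_condition", "a")
)

#' Default pipeline configuration
#'
#' @return Nested list understood by [run_all()].
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    synthetic = list(j_wrist = 4L, j_grip = 1L, snr_db = 20,
                     grip_spillover = 0.05, loading_jitter = 0.1,
                     n_trials = 3L, n_reps = 3L, diagonal_bias = 0.3,
                     amplitude_deg = 45),
    preprocess = list(cutoff = 5, order = 2L, zero_phase = TRUE, rate = 74),
    hals = list(max_sweeps = 500L, tol = 1e-8, n_restarts = 10L),
    model = list(strategy = "separate", j_wrist = 4L, j_grip = 1L,
                 select_j = FALSE, include_grip_regressor = TRUE),
    cv = list(train_condition = "comfortable_max",
              grip_condition = "grip_only", a = 90)
  )
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys at the top level and within each section, and checks
#' the few values whose invalidity would only surface deep in the pipeline.
#'
#' @param config Nested configuration list.
#' @return The config, invisibly, or an error.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), names(run_config_schema))
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  for (sec in setdiff(names(config), "seed")) {
    bad <- setdiff(names(config[[sec]]), run_config_schema[[sec]])
    if (length(bad)) {
      stopf("unknown key(s) in config section '%s': %s", sec,
            paste(bad, collapse = ", "))
    }
  }
  jw <- config$model$j_wrist
  if (!is.null(jw) && (!is.numeric(jw) || jw < 1)) {
    stopf("config validation: model$j_wrist must be >= 1")
  }
  jw <- config$synthetic$j_wrist
  if (!is.null(jw) && (!is.numeric(jw) || jw < 1)) {
    stopf("config validation: synthetic$j_wrist must be >= 1")
  }
  st <- config$model$strategy
  if (!is.null(st) && !st %in% c("separate", "joint")) {
    stopf("config validation: model$strategy must be 'separate' or 'joint'")
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; missing keys fall back to [default_run_config()].
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  validate_run_config(user)
  config <- default_run_config()
  for (sec in names(user)) {
    if (sec == "seed") config$seed <- user$seed
    else for (k in names(user[[sec]])) config[[sec]][[k]] <- user[[sec]][[k]]
  }
  validate_run_config(config)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

write_report_table <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_md5: %s", hash), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline: simulate, preprocess, extract, fit, evaluate
#'
#' Executes every stage from one validated configuration under a single
#' global seed, logging each stage's parameters and timing, and writes the
#' session streams, the VAF selection table (when enabled), per-fold and
#' summary performance tables to `out_dir`. Every table embeds the MD5 hash
#' of the producing configuration.
#'
#' @param config Configuration list (see [default_run_config()]), already
#'   merged/validated or straight from [read_run_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress stage log lines (default FALSE).
#' @return The `performance_report`, invisibly, with the selection table (if
#'   any) attached as attribute `selection`.
#' @export
run_all <- function(config = default_run_config(), out_dir, quiet = FALSE) {
  validate_run_config(config)
  hash <- config_hash(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  stage <- function(name, params, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    line <- sprintf("[%s] %s (%.2fs) %s", format(Sys.time(), "%H:%M:%S"),
                    name, proc.time()[["elapsed"]] - t0, params)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
    res
  }
  syn <- config$synthetic
  gt <- stage("ground_truth",
              sprintf("j_wrist=%d j_grip=%d snr=%s", syn$j_wrist, syn$j_grip,
                      format(syn$snr_db)),
              make_ground_truth(j_wrist = syn$j_wrist, j_grip = syn$j_grip,
                                seed = config$seed,
                                grip_spillover = syn$grip_spillover,
                                loading_jitter = syn$loading_jitter,
                                snr_db = syn$snr_db))
  protocol <- default_protocol(n_trials = syn$n_trials, n_reps = syn$n_reps,
                               diagonal_bias = syn$diagonal_bias,
                               amplitude_deg = syn$amplitude_deg)
  session <- stage("simulate", sprintf("%d trials", length(protocol)),
                   generate_session(gt, protocol, seed = config$seed,
                                    keep_truth = FALSE))
  stage("write_session", out_dir,
        write_session(session, file.path(out_dir, "session")))
  pp <- config$preprocess
  prep <- stage("preprocess",
                sprintf("cutoff=%g order=%d zero_phase=%s rate=%g",
                        pp$cutoff, pp$order, pp$zero_phase, pp$rate),
                preprocess_session(session, cutoff = pp$cutoff,
                                   order = pp$order,
                                   zero_phase = pp$zero_phase,
                                   rate = pp$rate))
  hc <- hals_config(max_sweeps = config$hals$max_sweeps,
                    tol = config$hals$tol,
                    n_restarts = config$hals$n_restarts,
                    seed = config$seed)
  selection <- NULL
  j_wrist <- config$model$j_wrist
  if (isTRUE(config$model$select_j)) {
    conds <- vapply(prep$trials, `[[`, "", "condition")
    wtr <- prep$trials[conds == config$cv$train_condition]
    selection <- stage("select_synergy_count", "j in 1..6",
                       select_synergy_count(lapply(wtr, `[[`, "E"),
                                            config = hc))
    j_wrist <- selection$j
    write_report_table(selection$table,
                       file.path(out_dir, "vaf_by_synergy_count.tsv"), hash)
  }
  report <- stage("exhaustive_cv",
                  sprintf("strategy=%s j_wrist=%d", config$model$strategy,
                          j_wrist),
                  exhaustive_cv(prep, strategy = config$model$strategy,
                                j_wrist = j_wrist,
                                j_grip = config$model$j_grip,
                                config = hc,
                                train_condition = config$cv$train_condition,
                                grip_condition = config$cv$grip_condition,
                                include_grip_regressor =
                                  config$model$include_grip_regressor,
                                a = config$cv$a))
  write_report_table(report$trials, file.path(out_dir, "per_trial.tsv"), hash)
  write_report_table(report$folds, file.path(out_dir, "per_fold.tsv"), hash)
  write_report_table(report$summary, file.path(out_dir, "summary.tsv"), hash)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  writeLines(c(sprintf("# config_md5: %s", hash), log_lines), log_path)
  attr(report, "selection") <- selection
  invisible(report)
}
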