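# CSV readers/writers for trial logs and test-retest tables, plus YAML
# experiment configs.  Numeric columns are written with 17 significant
# digits so every table round-trips through its own reader without loss.

write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Write / read a per-letter trial log
#'
#' One row per presented letter with the running AULCSF estimate of its
#' trial: columns `trial_index`, `freq_cpd`, `contrast`, `letter_index`,
#' `correct`, `aulcsf_est`, `ci_lo`, `ci_hi`.
#'
#' @param session a [run_session()] result.
#' @param path CSV file path.
#' @return `write_trial_log` returns the path invisibly;
#'   `read_trial_log` the data.frame.
#' @export
write_trial_log <- function(session, path) {
  log <- merge(session$letters, session$estimates, by = "trial_index",
               sort = FALSE)
  log <- log[order(log$trial_index, log$letter_index), ]
  rownames(log) <- NULL
  write_csv_exact(log, path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("trial_index", "freq_cpd", "contrast", "letter_index",
            "correct", "aulcsf_est", "ci_lo", "ci_hi")
  if (!all(need %in% names(df)))
    stop("trial log is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$correct <- as.logical(df$correct)
  df
}

#' Write / read a test--retest table
#'
#' Long format as produced by [simulate_test_retest()]; missing feature
#' values stay empty fields and read back as `NA`.
#'
#' @param table the long-format data.frame.
#' @param path CSV file path.
#' @return `write_test_retest` returns the path invisibly;
#'   `read_test_retest` the data.frame.
#' @export
write_test_retest <- function(table, path) {
  write_csv_exact(table, path)
}

#' @rdname write_test_retest
#' @export
read_test_retest <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8",
                        colClasses = c(test = "numeric", retest = "numeric"))
  need <- c("subject_id", "eye", "group", "feature", "test", "retest")
  if (!all(need %in% names(df)))
    stop("test-retest table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Load an experiment configuration file
#'
#' YAML (JSON, being a YAML subset, is accepted too) with optional
#' sections `engine:`, `cohort:` (or `cohort_ms:`/`cohort_hc:`),
#' `chart:`, and `experiment:`; missing entries fall back to package
#' defaults inside the `run_*_experiment()` functions.
#'
#' @param path config file path.
#' @return A named list.
#' @examples
#' cfg <- load_experiment_config(
#'   system.file("extdata", "example_config.yaml", package = "qcsfsim"))
#' str(cfg$experiment)
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

# build helper objects out of a parsed config list
engine_from_config <- function(cfg) {
  if (is.null(cfg)) return(qcsf_engine())
  grid <- do.call(build_grid, cfg$grid %||% list())
  stimuli <- do.call(stimulus_grid, cfg$stimuli %||% list())
  psy <- do.call(psychometric_config, cfg$psy %||% list())
  qcsf_engine(grid = grid, stimuli = stimuli, psy = psy)
}

cohort_from_config <- function(cfg, default) {
  if (is.null(cfg)) return(default)
  do.call(cohort_spec, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# provenance dump written into every experiment output directory
dump_config <- function(out_dir, cfg) {
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
}

write_run_log <- function(out_dir, lines) {
  writeLines(lines, file.path(out_dir, "run.log"))
}
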