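#' Read forager line-crossing times from a CSV file
#'
#' The field-style crossing file is a CSV with header `time_s,direction`:
#' one row per forager crossing the reference line, time in seconds since
#' the start of the recording and direction `in` or `out`. Rows may be
#' unsorted (they are sorted on load with a warning); unknown direction
#' tokens and negative times are schema errors naming the offending line.
#'
#' @param path Path to the CSV file.
#' @return A list with elements `in_events` and `out_events`, both
#'   [event_sequence()]s.
#' @export
read_crossing_times <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "direction") %in% names(df))) {
    abort("crossing-times file must have columns `time_s,direction`")
  }
  df$time_s <- suppressWarnings(as.numeric(df$time_s))
  bad_time <- which(is.na(df$time_s) | df$time_s < 0)
  if (length(bad_time)) {
    abort(sprintf("invalid or negative time on data line %d", bad_time[1]))
  }
  bad_dir <- which(!df$direction %in% c("in", "out"))
  if (length(bad_dir)) {
    abort(sprintf("unknown direction '%s' on data line %d",
                  df$direction[bad_dir[1]], bad_dir[1]))
  }
  mk <- function(lbl) {
    t <- df$time_s[df$direction == lbl]
    if (is.unsorted(t)) {
      warn(sprintf("'%s' crossing times were unsorted; sorting", lbl))
      t <- sort(t)
    }
    ev <- event_sequence(numeric(), label = lbl)
    if (length(t)) ev <- event_sequence(t, label = lbl)
    ev
  }
  list(in_events = mk("in"), out_events = mk("out"))
}

#' Write crossing times to a CSV file
#'
#' @param in_events,out_events Incoming and outgoing [event_sequence()]s.
#' @param path Output file path.
#' @return The path, invisibly. Times are written with microsecond
#'   precision (sub-step spike interpolation produces sub-millisecond
#'   times).
#' @export
write_crossing_times <- function(in_events, out_events, path) {
  t_in <- event_times(in_events)
  t_out <- event_times(out_events)
  df <- rbind(
    data.frame(time_s = t_in, direction = rep("in", length(t_in))),
    data.frame(time_s = t_out, direction = rep("out", length(t_out))))
  df <- df[order(df$time_s), , drop = FALSE]
  df$time_s <- sprintf("%.6f", df$time_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulation record to a directory
#'
#' Emits three files: `crossings.csv` (merged incoming/outgoing event
#' times), `rates.csv` (per-second `time_s,r_in,r_out,q,x_i` with the
#' standard 300-second rate window) and `summary.txt` (configuration echo
#' including the seed, so a run can be reproduced bit-for-bit, plus the
#' QSS estimates).
#'
#' @param record A `sim_record` from [run_closed_loop()].
#' @param out_dir Output directory, created if needed.
#' @param window Rate window in seconds for `rates.csv`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_record <- function(record, out_dir, window = 300) {
  stopifnot(inherits(record, "sim_record"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(crossings = file.path(out_dir, "crossings.csv"),
             rates = file.path(out_dir, "rates.csv"),
             summary = file.path(out_dir, "summary.txt"))
  write_crossing_times(tibble(time_s = record$lambda_in$time_s),
                       tibble(time_s = record$lambda_out$time_s),
                       paths[["crossings"]])
  rates <- tidy(record, window = window)
  out <- data.frame(time_s = rates$time_s,
                    r_in = sprintf("%.9g", rates$r_in),
                    r_out = sprintf("%.9g", rates$r_out),
                    q = rates$q, x_i = sprintf("%.9g", rates$x_i))
  utils::write.csv(out, paths[["rates"]], row.names = FALSE, quote = FALSE)
  cfg <- record$config
  # fit the summary window to short records
  qss_window <- min(window, cfg$duration / 3)
  qss <- qss_estimate(record, window = qss_window)
  lines <- c(
    "closed-loop colony simulation summary",
    sprintf("c_u: %g", cfg$c_u), sprintf("c_i: %g", cfg$c_i),
    sprintf("N: %d", cfg$N), sprintf("D_minutes: %g", cfg$D),
    sprintf("k: %g", cfg$stim$k), sprintf("tau_s: %g", cfg$stim$tau),
    sprintf("a: %g", cfg$fn$a), sprintf("eps1: %g", cfg$fn$eps1),
    sprintf("eps2: %g", cfg$fn$eps2),
    sprintf("spike_threshold: %g", cfg$fn$spike_threshold),
    sprintf("duration_s: %g", cfg$duration),
    sprintf("dt_s: %g", cfg$dt),
    "integrator: fixed-step RK4, event times forced as mesh points",
    sprintf("seed: %s", if (is.null(cfg$seed)) "NA" else cfg$seed),
    sprintf("rate_window_s: %g", window),
    sprintf("n_out: %d", nrow(record$lambda_out)),
    sprintf("n_in: %d", nrow(record$lambda_in)),
    sprintf("dropped_uninformed: %d", record$dropped[["uninformed"]]),
    sprintf("dropped_informed: %d", record$dropped[["informed"]]),
    sprintf("r_qss_ants_per_s: %.6g", qss$r_qss),
    sprintf("q_qss_ants: %.6g", qss$q_qss),
    sprintf("rate_gap_rel: %.6g", qss$rate_gap_rel))
  writeLines(lines, paths[["summary"]])
  invisible(paths)
}

#' Read a flat key-value run configuration file
#'
#' The configuration format is a flat, human-editable `key = value` file
#' (lines starting with `#` are comments). Units are explicit in key
#' names to guard against the seconds/minutes mix of the model. Recognised
#' keys: `c_u`, `c_i`, `N`, `D_minutes`, `duration_s`, `seed`, `k`,
#' `tau_s`, `a`, `eps1`, `eps2`, `spike_threshold`, `initial_rate`;
#' unknown keys are rejected.
#'
#' @param path Path to the configuration file.
#' @return A [colony_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2)
  if (length(bad)) abort(sprintf("malformed config line: '%s'", lines[bad[1]]))
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[[`, character(1), 2)))
  known <- c("c_u", "c_i", "N", "D_minutes", "duration_s", "seed", "k",
             "tau_s", "a", "eps1", "eps2", "spike_threshold",
             "initial_rate")
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    abort(sprintf("unknown config key: '%s'", unknown[1]))
  }
  if (anyNA(vals)) {
    abort(sprintf("non-numeric value for key '%s'", keys[which(is.na(vals))[1]]))
  }
  v <- as.list(vals)
  names(v) <- keys
  need <- c("c_u", "c_i", "N", "D_minutes")
  missing_keys <- setdiff(need, keys)
  if (length(missing_keys)) {
    abort(sprintf("config is missing required key '%s'", missing_keys[1]))
  }
  get_or <- function(key, default) if (!is.null(v[[key]])) v[[key]] else default
  colony_config(
    c_u = v$c_u, c_i = v$c_i, N = v$N, D = v$D_minutes,
    stim = stimulus_params(k = get_or("k", 0.3), tau = get_or("tau_s", 0.41)),
    fn = fn_params(c = 1, a = get_or("a", 0.35),
                   eps1 = get_or("eps1", 0.2), eps2 = get_or("eps2", 0.05),
                   spike_threshold = get_or("spike_threshold", 0.75)),
    duration = get_or("duration_s", 3 * 3600),
    seed = if (!is.null(v$seed)) as.integer(v$seed) else NULL,
    initial_rate = get_or("initial_rate", 0.01))
}
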