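# Configuration files, event-log serialization, run manifests, and the
# programmatic entry points behind the command-line tool
# (inst/cli/rulechoice).

config_canonical_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null",
                   digits = NA)
}

#' MD5 hash of a session configuration
#' @param config A [session_config()].
#' @return Character MD5 digest of the canonical JSON form.
#' @export
config_md5 <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(config_canonical_json(config)), tf)
  unname(tools::md5sum(tf))
}

#' Write an event log to CSV
#'
#' The file starts with a `#key=value` header block (seed, participant,
#' configuration echo as JSON, configuration hash) followed by one row
#' per event.  Timestamps are written in seconds with 3 decimal places,
#' which is exact on the engine's 10-ms grid, so a read-back reproduces
#' the in-memory log.
#'
#' @param x A `session_result`, or an event-log data frame.
#' @param path Output file path.
#' @param config The session configuration (taken from `x` when `x` is a
#'   `session_result`).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(x, path, config = NULL) {
  if (inherits(x, "session_result")) {
    config <- x$config
    log <- x$log
  } else log <- x
  stopifnot(is.data.frame(log))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#rulechoice_log_version=1",
               paste0("#package_version=",
                      as.character(utils::packageVersion("rulechoice")))),
             con)
  if (!is.null(config)) {
    writeLines(c(paste0("#seed=", config$seed),
                 paste0("#participant=", config$participant_id),
                 paste0("#experiment=", config$experiment),
                 paste0("#config_md5=", config_md5(config)),
                 paste0("#config_json=", config_canonical_json(config))),
               con)
  }
  out <- log
  out$t_s <- sprintf("%.3f", out$t_s)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event log written by [write_event_log()]
#'
#' @param path Path to the CSV file.
#' @return A list with `log` (event data frame), `header` (named
#'   character vector of the `#` lines) and `config` (a reconstructed
#'   `session_config`, or `NULL` if the file carries none).
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr_lines <- sub("^#", "", lines[is_hdr])
  eq <- regexpr("=", hdr_lines, fixed = TRUE)
  header <- stats::setNames(substring(hdr_lines, eq + 1L),
                            substring(hdr_lines, 1L, eq - 1L))
  log <- utils::read.csv(text = paste(lines[!is_hdr], collapse = "\n"),
                         stringsAsFactors = FALSE,
                         colClasses = c(t_s = "numeric", phase = "character",
                                        block = "integer", cycle = "integer",
                                        component_index = "integer",
                                        component_label = "character",
                                        event = "character",
                                        payload = "character"))
  log$payload[is.na(log$payload)] <- ""
  log$component_label[is.na(log$component_label)] <- ""
  config <- NULL
  if ("config_json" %in% names(header)) {
    lst <- jsonlite::fromJSON(header[["config_json"]],
                              simplifyVector = TRUE)
    lst$condition <- as.list(lst$condition)
    config <- do.call(session_config, lst)
  }
  list(log = log, header = header, config = config)
}

#' Write / read a session configuration file
#'
#' Configurations are stored as YAML mirroring the [session_config()]
#' fields (including the condition row and an optional declarative agent
#' spec).  A commented example ships in `inst/extdata/`.
#'
#' @param config A [session_config()].
#' @param path File path.
#' @return `write_config()`: `path` invisibly; `read_config()`: a
#'   `session_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::yaml.load_file(path)
  if (!is.list(lst) || is.null(lst$participant_id))
    stop("not a rulechoice session configuration: ", path, call. = FALSE)
  known <- names(formals(session_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(session_config, lst)
}

# ---- manifests ---------------------------------------------------------

#' Write a run manifest
#'
#' Records what a run produced: configuration hash, seed, phase
#' outcomes, and the MD5 of every file written, so a run can be audited
#' later with [verify_manifest()].
#'
#' @param result A `session_result`.
#' @param files Character vector of file paths produced by the run.
#' @param path Manifest output path (JSON).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(result, files, path) {
  stopifnot(inherits(result, "session_result"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("rulechoice")),
    participant = result$config$participant_id,
    experiment = result$config$experiment,
    seed = result$config$seed,
    config_md5 = config_md5(result$config),
    phase_outcomes = list(
      training_passed = result$training_passed,
      rule_test_passed = if (is.null(result$rule_test)) NA
                         else result$rule_test$passed,
      choice_test_run = result$choice_test_run,
      terminated_phase = result$terminated_phase),
    n_reinforcers = result$n_reinforcers,
    earnings = result$earnings,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) list(path = f,
                                    md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Verify a run manifest
#'
#' Checks that every file listed in a manifest still exists with an
#' unchanged MD5.
#'
#' @param path Path to a manifest JSON.
#' @return A list with `ok` (logical) and `problems` (character vector).
#' @export
verify_manifest <- function(path) {
  manifest <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  problems <- character(0)
  for (f in manifest$files) {
    if (!file.exists(f$path))
      problems <- c(problems, paste0("missing: ", f$path))
    else if (!identical(unname(tools::md5sum(f$path)), f$md5))
      problems <- c(problems, paste0("modified: ", f$path))
  }
  list(ok = length(problems) == 0L, problems = problems)
}

# ---- entry points ------------------------------------------------------

write_analysis_files <- function(result, out_dir, stem) {
  files <- character(0)
  counts <- observation_period_counts(result$log, "training")
  f <- file.path(out_dir, paste0(stem, "_training_periods.csv"))
  utils::write.csv(counts, f, row.names = FALSE)
  files <- c(files, f)
  ser <- data.frame(
    period = seq_len(sum(counts$component_label == "Rich")),
    pct_instructed_rich = as.numeric(
      percent_instructed_series(result$log, "Rich")),
    pct_instructed_lean = as.numeric(
      percent_instructed_series(result$log, "Lean")))
  f <- file.path(out_dir, paste0(stem, "_training_percent.csv"))
  utils::write.csv(ser, f, row.names = FALSE)
  files <- c(files, f)
  if (result$choice_test_run) {
    rows <- lapply(c("Rich", "Lean", "BS", "NS"), function(lab) {
      p <- pool_choice_test(result$log, lab)
      data.frame(component = lab, alternative = names(p),
                 percent = as.numeric(p),
                 responses_left = attr(p, "counts")[["left"]],
                 responses_right = attr(p, "counts")[["right"]],
                 stringsAsFactors = FALSE)
    })
    f <- file.path(out_dir, paste0(stem, "_choice_test.csv"))
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    files <- c(files, f)
  }
  files
}

#' Run one configured session and write all outputs
#'
#' Loads the configuration, builds the agent from its declarative spec,
#' runs the session, and writes the event log, the analysis CSVs and a
#' manifest into `out_dir`.
#'
#' @param config_path Path to a YAML session configuration (must include
#'   an `agent_spec`).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding the configuration's.
#' @return The run manifest, invisibly.
#' @export
cli_run <- function(config_path, out_dir, seed = NULL) {
  config <- read_config(config_path)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$agent_spec))
    stop("configuration has no agent_spec", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  result <- run_session(config)
  stem <- config$participant_id
  log_file <- file.path(out_dir, paste0(stem, "_events.csv"))
  write_event_log(result, log_file)
  files <- c(log_file, write_analysis_files(result, out_dir, stem))
  manifest_path <- file.path(out_dir, paste0(stem, "_manifest.json"))
  manifest <- write_manifest(result, files, manifest_path)
  manifest$manifest_path <- manifest_path
  manifest$result <- result
  invisible(manifest)
}

#' Re-run the analysis on an existing event log
#'
#' @param log_path Path to an event-log CSV written by
#'   [write_event_log()].
#' @param out_dir Output directory for the analysis CSVs.
#' @return Character vector of files written, invisibly.
#' @export
cli_analyze <- function(log_path, out_dir) {
  rd <- read_event_log(log_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- if (!is.null(rd$config)) rd$config$participant_id
          else sub("\\.csv$", "", basename(log_path))
  fake <- list(log = rd$log,
               choice_test_run = any(rd$log$phase == "choice_test"))
  invisible(write_analysis_files(fake, out_dir, stem))
}

#' Calibrate obtained reinforcer rates on a single schedule
#'
#' Runs the always-respond probe against one schedule for `duration_s`
#' of simulated time and reports the obtained reinforcer rate per minute
#' with a Poisson-based 95% confidence interval.  A VI with mean
#' `vi_mean_s` programs about `60 / vi_mean_s` reinforcers per minute.
#'
#' @param vi_mean_s Programmed VI mean, seconds.
#' @param duration_s Simulated time, seconds.
#' @param seed RNG seed.
#' @param response_rate_hz Probe emission rate.
#' @param kind `"VI"` or `"EXT"`.
#' @param n_intervals Intervals per VI list.
#' @return A list with `rate_per_min`, `ci` (length-2 vector),
#'   `n_reinforcers`, `n_responses`, `duration_s`.
#' @export
cli_calibrate <- function(vi_mean_s, duration_s = 10000, seed = 1L,
                          response_rate_hz = 5, kind = c("VI", "EXT"),
                          n_intervals = 20L) {
  kind <- match.arg(kind)
  stopifnot(duration_s > 0, response_rate_hz > 0)
  if (kind == "VI" && (missing(vi_mean_s) || vi_mean_s <= 0))
    stop("`vi_mean_s` must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  sch <- if (kind == "VI") new_schedule("VI", vi_mean_s, n_intervals)
         else new_schedule("EXT")
  pair <- new_concurrent_pair(sch, new_schedule("EXT"))
  probe <- always_respond_probe("left", response_rate_hz)
  end <- s_to_ticks(duration_s)
  t <- 0L
  n_reinf <- 0L
  n_resp <- 0L
  repeat {
    irt <- agent_irt(probe)
    if (t + irt >= end) break
    pair <- advance_pair_ticks(pair, irt)
    t <- t + irt
    res <- register_response(pair, "left")
    pair <- res$pair
    n_resp <- n_resp + 1L
    if (res$reinforced) n_reinf <- n_reinf + 1L
  }
  minutes <- duration_s / 60
  rate <- n_reinf / minutes
  ci <- (n_reinf + c(-1, 1) * 1.96 * sqrt(max(n_reinf, 1))) / minutes
  list(kind = kind,
       vi_mean_s = if (kind == "VI") vi_mean_s else NA_real_,
       duration_s = duration_s, response_rate_hz = response_rate_hz,
       n_responses = n_resp, n_reinforcers = n_reinf,
       rate_per_min = rate, ci = pmax(ci, 0))
}

#' Run every condition of an experiment with one agent specification
#'
#' Convenience group runner: one session per [condition_table()] row,
#' seeded deterministically from `seed`, followed by the group-level
#' choice-test comparisons of [choice_test_group_table()].
#'
#' @param experiment 1 or 2.
#' @param agent_spec Declarative agent specification (see
#'   [agent_from_spec()]).
#' @param seed Base seed; session `i` uses `seed + i`.
#' @param config_args Named list of extra [session_config()] arguments
#'   applied to every session.
#' @return A list with `results` (session results) and `table` (group
#'   comparison data frame over the sessions that reached the choice
#'   test).
#' @export
run_group <- function(experiment = 1, agent_spec, seed = 1L,
                      config_args = list()) {
  tab <- condition_table(experiment)
  results <- lapply(seq_len(nrow(tab)), function(i) {
    cond <- as.list(tab[i, ])
    args <- c(list(participant_id = cond$participant,
                   experiment = experiment,
                   seed = as.integer(seed) + i, condition = cond,
                   agent_spec = agent_spec),
              config_args)
    run_session(do.call(session_config, args))
  })
  names(results) <- tab$participant
  complete <- Filter(function(r) r$choice_test_run, results)
  table <- if (length(complete) >= 2L) choice_test_group_table(complete)
           else NULL
  list(results = results, table = table)
}

#' Batch-run a directory of session configurations
#'
#' Runs every `.yaml` configuration in `config_dir`, `n_replicates`
#' times each, writes per-session outputs, and aggregates the group
#' choice-test comparisons per replicate.
#'
#' @param config_dir Directory containing session configuration files.
#' @param n_replicates Replicates per configuration.
#' @param seeds Integer vector of length `n_replicates`; replicate `r`
#'   of configuration `i` is seeded with `seeds[r] + 7919 * (i - 1)`.
#' @param out_dir Output directory.
#' @return A list with `aggregate` (data frame of group tests per
#'   replicate) and `results` (nested list of session results),
#'   invisibly.
#' @export
cli_batch <- function(config_dir, n_replicates = 1L, seeds = seq_len(n_replicates),
                      out_dir = file.path(config_dir, "batch_out")) {
  paths <- list.files(config_dir, pattern = "\\.ya?ml$", full.names = TRUE)
  if (length(paths) == 0L)
    stop("no configuration files in ", config_dir, call. = FALSE)
  stopifnot(length(seeds) == n_replicates)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_results <- list()
  agg <- list()
  for (r in seq_len(n_replicates)) {
    results <- lapply(seq_along(paths), function(i) {
      config <- read_config(paths[i])
      config$seed <- as.integer(seeds[r]) + 7919L * (i - 1L)
      res <- run_session(config)
      write_event_log(res, file.path(
        out_dir, sprintf("%s_rep%d_events.csv", config$participant_id, r)))
      res
    })
    all_results[[r]] <- results
    complete <- Filter(function(x) x$choice_test_run, results)
    if (length(complete) >= 2L) {
      tab <- choice_test_group_table(complete)
      tab$replicate <- r
      agg[[length(agg) + 1L]] <- tab
    }
  }
  aggregate <- if (length(agg)) do.call(rbind, agg) else NULL
  if (!is.null(aggregate))
    utils::write.csv(aggregate, file.path(out_dir, "group_tests.csv"),
                     row.names = FALSE)
  invisible(list(aggregate = aggregate, results = all_results))
}
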