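# Session orchestration: the three experimental phases (training,
# rule test, choice test), advancement criteria, and the event log.

# ---- event recorder ----------------------------------------------------

LOG_FIELDS <- c("t_s", "phase", "block", "cycle", "component_index",
                "component_label", "event", "payload")

new_recorder <- function(n0 = 2048L) {
  rec <- new.env(parent = emptyenv())
  rec$n <- 0L
  rec$ticks <- integer(n0)
  rec$phase <- character(n0)
  rec$block <- integer(n0)
  rec$cycle <- integer(n0)
  rec$component_index <- integer(n0)
  rec$component_label <- character(n0)
  rec$event <- character(n0)
  rec$payload <- character(n0)
  rec
}

rec_add <- function(rec, ticks, phase, block, cycle, comp_index, label,
                    event, payload = "") {
  i <- rec$n + 1L
  if (i > length(rec$ticks)) {
    for (f in c("ticks", "phase", "block", "cycle", "component_index",
                "component_label", "event", "payload"))
      length(rec[[f]]) <- 2L * length(rec[[f]])
  }
  rec$ticks[i] <- ticks
  rec$phase[i] <- phase
  rec$block[i] <- block
  rec$cycle[i] <- cycle
  rec$component_index[i] <- comp_index
  rec$component_label[i] <- label
  rec$event[i] <- event
  rec$payload[i] <- payload
  rec$n <- i
  invisible(rec)
}

rec_df <- function(rec) {
  idx <- seq_len(rec$n)
  data.frame(
    t_s = rec$ticks[idx] / 100,
    phase = rec$phase[idx],
    block = rec$block[idx],
    cycle = rec$cycle[idx],
    component_index = rec$component_index[idx],
    component_label = rec$component_label[idx],
    event = rec$event[idx],
    payload = rec$payload[idx],
    stringsAsFactors = FALSE)
}

# ---- counterbalancing --------------------------------------------------

#' Counterbalanced schedule assignments
#'
#' Returns the eight counterbalanced combinations of (color of the
#' VI 10-s component) x (side of its VI), each combination appearing
#' twice.  The component whose concurrent pair carries the VI 10-s
#' schedule is the Rich component; the VI 60-s component is Lean, and its
#' VI always sits on the opposite side.
#'
#' @param experiment 1 (rule-instructed participants, GP ids) or 2
#'   (no rules, CP ids).
#' @return A data frame with one row per simulated participant: columns
#'   `participant`, `experiment`, `rich_color`, `rich_side`, `lean_color`,
#'   `lean_side`, `rule_red`, `rule_blue` (the instructed side for each
#'   stimulus color).
#' @export
condition_table <- function(experiment = 1) {
  stopifnot(experiment %in% c(1, 2))
  combo <- data.frame(
    rich_color = c("red", "blue", "red", "blue"),
    rich_side  = c("left", "left", "right", "right"),
    stringsAsFactors = FALSE)
  combo$lean_color <- ifelse(combo$rich_color == "red", "blue", "red")
  combo$lean_side  <- ifelse(combo$rich_side == "left", "right", "left")
  ids <- if (experiment == 1)
    c("GP101", "GP201", "GP301", "GP401", "GP102", "GP202", "GP302", "GP402")
  else
    c("CP111", "CP211", "CP311", "CP411", "CP112", "CP212", "CP312", "CP412")
  tab <- combo[rep(1:4, 2), ]
  tab <- data.frame(participant = ids, experiment = experiment, tab,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$rule_red <- ifelse(tab$rich_color == "red", tab$rich_side, tab$lean_side)
  tab$rule_blue <- ifelse(tab$rich_color == "blue", tab$rich_side,
                          tab$lean_side)
  tab
}

#' Rule map implied by a condition row
#'
#' @param condition One row of [condition_table()] (data frame or list).
#' @return Named list mapping `"red"` and `"blue"` to instructed sides.
#' @export
rule_map_from_condition <- function(condition) {
  condition <- as.list(condition)
  list(red = condition$rule_red, blue = condition$rule_blue)
}

# ---- configuration -----------------------------------------------------

#' Build a session configuration
#'
#' Bundles every programmable parameter of one experimental session.
#' Defaults reproduce the published procedure: three blocks of six cycles
#' of a two-component multiple schedule in training (each component 60 s,
#' 10-s inter-component intervals, so a cycle spans 140 s; 30-s rests
#' between blocks), a 3-s changeover delay, VI lists of 20
#' Fleshler-Hoffman intervals (VI 10 s Rich, VI 60 s Lean), exactly 6 of
#' the 18 Lean components run as concurrent EXT-EXT, a 95% advancement
#' criterion over the last six observation periods of each component
#' (80% when no rules are given, experiment 2), and a two-cycle
#' four-component choice test.
#'
#' @param participant_id Identifier; used to pick the condition row.
#' @param experiment 1 (rules given; rule-test phase runs) or 2 (no
#'   rules; no rule test).
#' @param seed Integer seed for the single session RNG stream.
#' @param condition A condition row (defaults to the [condition_table()]
#'   row matching `participant_id`).
#' @param n_blocks,cycles_per_block Training structure.
#' @param component_s Component (observation period) duration, seconds.
#' @param ici_s Inter-component interval, seconds.
#' @param rest_s Rest between training blocks, seconds.
#' @param cod_s Changeover delay, seconds.
#' @param criterion_pct Advancement criterion (percent of responses on the
#'   instructed/VI alternative, pooled over the last six observation
#'   periods of each component).
#' @param n_forced_ext_lean Number of training Lean components run as
#'   EXT-EXT.
#' @param choice_test_cycles Cycles of the four-component choice test.
#' @param rich_vi_mean_s,lean_vi_mean_s Programmed VI means, seconds.
#' @param n_intervals Intervals per VI list.
#' @param flash_ms Stimulus flash period (logged as metadata; nothing is
#'   rendered).
#' @param bs_alternation_ms Color alternation period in the both-stimuli
#'   component, milliseconds.
#' @param point_value Currency units credited per reinforcer.
#' @param post_cod_unconditional Engine flag: reinforce the first
#'   post-changeover response unconditionally (off by default; see
#'   [new_concurrent_pair()]).
#' @param agent_spec Optional declarative agent specification (see
#'   [agent_from_spec()]); used by the file-driven interfaces.
#' @return An object of class `session_config`.
#' @export
session_config <- function(participant_id = "GP101",
                           experiment = 1,
                           seed = 1L,
                           condition = NULL,
                           n_blocks = 3L,
                           cycles_per_block = 6L,
                           component_s = 60,
                           ici_s = 10,
                           rest_s = 30,
                           cod_s = 3,
                           criterion_pct = if (experiment == 1) 95 else 80,
                           n_forced_ext_lean = 6L,
                           choice_test_cycles = 2L,
                           rich_vi_mean_s = 10,
                           lean_vi_mean_s = 60,
                           n_intervals = 20L,
                           flash_ms = 235,
                           bs_alternation_ms = 400,
                           point_value = 0.7,
                           post_cod_unconditional = FALSE,
                           agent_spec = NULL) {
  stopifnot(experiment %in% c(1, 2), n_blocks >= 1, cycles_per_block >= 1,
            component_s > 0, ici_s >= 0, rest_s >= 0, cod_s >= 0,
            criterion_pct >= 0, criterion_pct <= 100,
            rich_vi_mean_s > 0, lean_vi_mean_s > 0, n_intervals >= 1,
            choice_test_cycles >= 1)
  total_lean <- n_blocks * cycles_per_block
  if (n_forced_ext_lean > total_lean)
    stop("`n_forced_ext_lean` cannot exceed the number of Lean components (",
         total_lean, ")", call. = FALSE)
  if (is.null(condition)) {
    tab <- condition_table(experiment)
    hit <- tab[tab$participant == participant_id, ]
    if (nrow(hit) != 1L)
      stop("unknown participant_id ", participant_id,
           "; supply `condition` explicitly", call. = FALSE)
    condition <- as.list(hit)
  } else condition <- as.list(condition)
  structure(
    list(participant_id = participant_id, experiment = experiment,
         seed = as.integer(seed), condition = condition,
         n_blocks = as.integer(n_blocks),
         cycles_per_block = as.integer(cycles_per_block),
         component_s = component_s, ici_s = ici_s, rest_s = rest_s,
         cod_s = cod_s, criterion_pct = criterion_pct,
         n_forced_ext_lean = as.integer(n_forced_ext_lean),
         choice_test_cycles = as.integer(choice_test_cycles),
         rich_vi_mean_s = rich_vi_mean_s, lean_vi_mean_s = lean_vi_mean_s,
         n_intervals = as.integer(n_intervals), flash_ms = flash_ms,
         bs_alternation_ms = bs_alternation_ms, point_value = point_value,
         post_cod_unconditional = isTRUE(post_cod_unconditional),
         agent_spec = agent_spec),
    class = "session_config")
}

# ---- components --------------------------------------------------------

#' Color of the alternating both-stimuli display at a time offset
#'
#' @param t_rel_s Seconds since component onset.
#' @param initial_color `"red"` or `"blue"` at onset.
#' @param period_ms Display period per color, milliseconds (default 400).
#' @return The displayed color at `t_rel_s` (vectorized).
#' @export
bs_stimulus_at <- function(t_rel_s, initial_color = "red", period_ms = 400) {
  stopifnot(initial_color %in% c("red", "blue"), period_ms > 0)
  idx <- floor(t_rel_s / (period_ms / 1000))
  flip <- idx %% 2 == 1
  out <- rep(initial_color, length(t_rel_s))
  out[flip] <- if (initial_color == "red") "blue" else "red"
  out
}

component_setup <- function(cfg, label, forced_ext = FALSE) {
  cond <- cfg$condition
  make_pair <- function(vi_side, vi_mean) {
    vi <- new_schedule("VI", vi_mean, cfg$n_intervals)
    ext <- new_schedule("EXT")
    new_concurrent_pair(
      left = if (identical(vi_side, "left")) vi else ext,
      right = if (identical(vi_side, "right")) vi else ext,
      cod_s = cfg$cod_s,
      post_cod_unconditional = cfg$post_cod_unconditional)
  }
  ext_pair <- function() new_concurrent_pair(
    new_schedule("EXT"), new_schedule("EXT"), cod_s = cfg$cod_s,
    post_cod_unconditional = cfg$post_cod_unconditional)
  if (label == "Rich") {
    pair <- make_pair(cond$rich_side, cfg$rich_vi_mean_s)
    stimulus <- cond$rich_color
    instructed <- cond$rich_side
    sched <- list(side = cond$rich_side, mean = cfg$rich_vi_mean_s)
  } else if (label == "Lean") {
    pair <- if (forced_ext) ext_pair()
            else make_pair(cond$lean_side, cfg$lean_vi_mean_s)
    stimulus <- cond$lean_color
    instructed <- cond$lean_side
    sched <- list(side = cond$lean_side, mean = cfg$lean_vi_mean_s)
  } else if (label == "BS") {
    pair <- ext_pair()
    stimulus <- "alternating"
    instructed <- ""
    sched <- NULL
  } else if (label == "NS") {
    pair <- ext_pair()
    stimulus <- "none"
    instructed <- ""
    sched <- NULL
  } else stop("unknown component label: ", label, call. = FALSE)
  initial_color <- if (label == "BS") sample(c("red", "blue"), 1L) else ""
  side_desc <- function(s) {
    if (is.null(sched) || forced_ext || sched$side != s) "EXT"
    else sprintf("VI:%g", sched$mean)
  }
  payload <- sprintf(
    paste0("stimulus=%s;left=%s;right=%s;instructed=%s;rich_side=%s;",
           "lean_side=%s;forced_ext=%d;initial_color=%s;flash_ms=%g;",
           "alternation_ms=%g"),
    stimulus, side_desc("left"), side_desc("right"), instructed,
    cond$rich_side, cond$lean_side, as.integer(forced_ext), initial_color,
    cfg$flash_ms, cfg$bs_alternation_ms)
  list(pair = pair, stimulus = stimulus, instructed = instructed,
       initial_color = initial_color, payload = payload)
}

run_component_ticks <- function(rec, cfg, agent, t0, phase, block, cycle,
                                comp_index, label, forced_ext = FALSE) {
  setup <- component_setup(cfg, label, forced_ext)
  pair <- setup$pair
  dur <- s_to_ticks(cfg$component_s)
  alt_ticks <- max(1L, s_to_ticks(cfg$bs_alternation_ms / 1000))
  rec_add(rec, t0, phase, block, cycle, comp_index, label,
          "component_on", setup$payload)
  ctx <- list(label = label, stimulus = setup$stimulus,
              stimulus_now = setup$stimulus,
              instructed_side = setup$instructed,
              rich_side = cfg$condition$rich_side,
              lean_side = cfg$condition$lean_side)
  t_end <- t0 + dur
  t_cur <- t0
  t_next <- t0 + agent_irt(agent)
  while (t_next < t_end) {
    pair <- advance_pair_ticks(pair, t_next - t_cur)
    t_cur <- t_next
    if (label == "BS") {
      idx <- (t_cur - t0) %/% alt_ticks
      ctx$stimulus_now <- if (idx %% 2L == 0L) setup$initial_color
        else if (setup$initial_color == "red") "blue" else "red"
    }
    ch <- agent_choose(agent, ctx)
    agent <- ch$agent
    res <- register_response(pair, ch$side)
    pair <- res$pair
    if (res$outcome == "cod_triggered") {
      rec_add(rec, t_cur, phase, block, cycle, comp_index, label,
              "cod_on", paste0("to=", ch$side))
      rec_add(rec, min(t_cur + pair$cod_duration_ticks, t_end),
              phase, block, cycle, comp_index, label, "cod_off", "")
    } else if (res$outcome %in% c("recorded", "reinforced")) {
      rec_add(rec, t_cur, phase, block, cycle, comp_index, label,
              paste0("response_", ch$side), "")
      agent <- agent_learn(agent, ctx, ch$side, res$reinforced)
      if (res$reinforced)
        rec_add(rec, t_cur, phase, block, cycle, comp_index, label,
                paste0("reinforcer_", ch$side), "")
    }
    t_next <- t_cur + agent_irt(agent)
  }
  rec_add(rec, t_end, phase, block, cycle, comp_index, label,
          "component_off", "")
  list(agent = agent, t_end = t_end)
}

# ---- phases ------------------------------------------------------------

eng_training <- function(rec, cfg, agent, t0 = 0L) {
  total_lean <- cfg$n_blocks * cfg$cycles_per_block
  forced <- sort(sample.int(total_lean, cfg$n_forced_ext_lean))
  t <- t0
  comp_index <- 0L
  lean_ordinal <- 0L
  ici <- s_to_ticks(cfg$ici_s)
  for (b in seq_len(cfg$n_blocks)) {
    if (b > 1L) {
      rec_add(rec, t, "training", b, 0L, 0L, "", "rest_on", "")
      t <- t + s_to_ticks(cfg$rest_s)
      rec_add(rec, t, "training", b, 0L, 0L, "", "rest_off", "")
    }
    for (cy in seq_len(cfg$cycles_per_block)) {
      order <- sample(c("Rich", "Lean"))
      for (label in order) {
        comp_index <- comp_index + 1L
        fe <- FALSE
        if (label == "Lean") {
          lean_ordinal <- lean_ordinal + 1L
          fe <- lean_ordinal %in% forced
        }
        out <- run_component_ticks(rec, cfg, agent, t, "training", b, cy,
                                   comp_index, label, forced_ext = fe)
        agent <- out$agent
        t <- out$t_end + ici
      }
    }
  }
  list(agent = agent, t_end = t)
}

rule_test_sentences <- function(condition) {
  rm <- rule_map_from_condition(condition)
  colors <- c("red", "blue")
  sides <- c("left", "right")
  side_sent <- lapply(colors, function(cc)
    list(type = "side", given = cc, expected = rm[[cc]]))
  color_sent <- lapply(sides, function(ss) {
    hit <- colors[vapply(colors, function(cc) rm[[cc]] == ss, logical(1))]
    list(type = "color", given = ss, expected = hit)
  })
  c(side_sent, color_sent)
}

eng_rule_test <- function(rec, cfg, agent, t0) {
  sentences <- rule_test_sentences(cfg$condition)
  order <- sample.int(4L)
  t <- t0
  answers <- vector("list", 4L)
  for (i in seq_along(order)) {
    s <- sentences[[order[i]]]
    rec_add(rec, t, "rule_test", 0L, 1L, i, "", "sentence_shown",
            sprintf("type=%s;given=%s", s$type, s$given))
    ans <- agent_rule_answer(agent, s)
    # exact-match validation: lowercase, space-free token required
    correct <- identical(ans, s$expected)
    t <- t + s_to_ticks(3)
    rec_add(rec, t, "rule_test", 0L, 1L, i, "", "sentence_answered",
            sprintf("type=%s;given=%s;answer=%s;expected=%s;correct=%d",
                    s$type, s$given, ans, s$expected, as.integer(correct)))
    answers[[i]] <- data.frame(order = i, type = s$type, given = s$given,
                               answer = ans, expected = s$expected,
                               correct = correct, stringsAsFactors = FALSE)
    t <- t + s_to_ticks(1)
  }
  answers <- do.call(rbind, answers)
  list(agent = agent, t_end = t, answers = answers,
       passed = all(answers$correct))
}

eng_choice_test <- function(rec, cfg, agent, t0) {
  t <- t0
  comp_index <- 0L
  ici <- s_to_ticks(cfg$ici_s)
  for (cy in seq_len(cfg$choice_test_cycles)) {
    order <- sample(c("Rich", "Lean", "BS", "NS"))
    for (label in order) {
      comp_index <- comp_index + 1L
      out <- run_component_ticks(rec, cfg, agent, t, "choice_test", 1L, cy,
                                 comp_index, label)
      agent <- out$agent
      t <- out$t_end + ici
    }
  }
  list(agent = agent, t_end = t)
}

# ---- public phase runners ----------------------------------------------

#' Run the training phase
#'
#' Presents `n_blocks` blocks of `cycles_per_block` cycles of the
#' two-component multiple schedule (components in random order within
#' each cycle, separated by the inter-component interval, blocks
#' separated by rests).  Exactly `n_forced_ext_lean` Lean components,
#' chosen uniformly without replacement, run as concurrent EXT-EXT.
#' The phase is passed when at least `criterion_pct` percent of the
#' agent's responses, pooled over the last six observation periods of
#' each component, fall on the instructed/VI alternative.
#'
#' Seeds the session RNG from `config$seed`.  Use [run_session()] to run
#' all phases with one seeding.
#'
#' @param config A [session_config()].
#' @param agent An agent object.
#' @return A list with `log` (event data frame), `passed` (logical) and
#'   `agent` (final agent state).
#' @export
run_training <- function(config, agent) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  rec <- new_recorder()
  out <- eng_training(rec, config, agent)
  log <- rec_df(rec)
  list(log = log, passed = training_passed(log, config$criterion_pct),
       agent = out$agent)
}

#' Run the rule-test phase
#'
#' Presents the two color sentences and the two side sentences in random
#' order.  An answer is correct only if it exactly matches the expected
#' lowercase, space-free token for the participant's rules; answers are
#' recorded once and cannot be changed.  The phase is passed only with
#' 4/4 correct on this first cycle.
#'
#' @inheritParams run_training
#' @return A list with `answers` (four-row data frame), `passed`, `log`,
#'   `agent`.
#' @export
run_rule_test <- function(config, agent) {
  stopifnot(inherits(config, "session_config"))
  if (config$experiment != 1)
    stop("the rule-test phase is not applicable in experiment 2",
         call. = FALSE)
  set.seed(config$seed)
  rec <- new_recorder()
  out <- eng_rule_test(rec, config, agent, 0L)
  list(answers = out$answers, passed = out$passed, log = rec_df(rec),
       agent = out$agent)
}

#' Run the choice-test phase
#'
#' Two cycles of the four-component multiple schedule \{Rich, Lean, BS,
#' NS\}, order uniform over the 24 permutations independently per cycle.
#' Rich and Lean keep their trained schedules; BS presents the two colors
#' alternating every `bs_alternation_ms` (initial color random at onset)
#' with extinction on both alternatives; NS presents no stimulus, also
#' with extinction on both alternatives.
#'
#' @inheritParams run_training
#' @return A list with `log` and `agent`.
#' @export
run_choice_test <- function(config, agent) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  rec <- new_recorder()
  out <- eng_choice_test(rec, config, agent, 0L)
  list(log = rec_df(rec), agent = out$agent)
}

#' Run a full session
#'
#' Runs training, then (experiment 1 only) the rule test, then the choice
#' test, terminating at the first failed advancement criterion.  A single
#' RNG stream seeded from `config$seed` drives every random element, so a
#' rerun with the same configuration and agent reproduces the event log
#' bit for bit.
#'
#' @param config A [session_config()].
#' @param agent An agent object; if missing, built from
#'   `config$agent_spec`.
#' @return An object of class `session_result`: a list with `config`,
#'   `log`, `training_passed`, `rule_test` (answers + passed, or `NULL`),
#'   `choice_test_run`, `terminated_phase` (`NA` if the session
#'   completed), `n_reinforcers`, `earnings`, and `agent` (final state).
#' @export
run_session <- function(config, agent = NULL) {
  stopifnot(inherits(config, "session_config"))
  if (is.null(agent)) {
    if (is.null(config$agent_spec))
      stop("no agent given and no agent_spec in the configuration",
           call. = FALSE)
    agent <- agent_from_spec(config$agent_spec, config$condition)
  }
  set.seed(config$seed)
  rec <- new_recorder()
  tr <- eng_training(rec, config, agent)
  agent <- tr$agent
  log <- rec_df(rec)
  tr_passed <- training_passed(log, config$criterion_pct)
  rule_res <- NULL
  ct_run <- FALSE
  terminated <- NA_character_
  if (!tr_passed) {
    terminated <- "training"
  } else {
    t <- tr$t_end
    if (config$experiment == 1) {
      rt <- eng_rule_test(rec, config, agent, t)
      agent <- rt$agent
      t <- rt$t_end
      rule_res <- list(answers = rt$answers, passed = rt$passed)
      if (!rt$passed) terminated <- "rule_test"
    }
    if (is.na(terminated)) {
      ct <- eng_choice_test(rec, config, agent, t)
      agent <- ct$agent
      ct_run <- TRUE
    }
    log <- rec_df(rec)
  }
  n_reinf <- sum(log$event %in% c("reinforcer_left", "reinforcer_right"))
  structure(
    list(config = config, log = log, training_passed = tr_passed,
         rule_test = rule_res, choice_test_run = ct_run,
         terminated_phase = terminated, n_reinforcers = n_reinf,
         earnings = n_reinf * config$point_value, agent = agent),
    class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cfg <- x$config
  cat("Simulated session:", cfg$participant_id,
      sprintf("(experiment %d, seed %d)\n", cfg$experiment, cfg$seed))
  cat("  training criterion (", cfg$criterion_pct, "%): ",
      if (x$training_passed) "passed" else "FAILED", "\n", sep = "")
  if (!is.null(x$rule_test))
    cat("  rule test: ", sum(x$rule_test$answers$correct), "/4 correct (",
        if (x$rule_test$passed) "passed" else "FAILED", ")\n", sep = "")
  cat("  choice test run:", x$choice_test_run, "\n")
  if (!is.na(x$terminated_phase))
    cat("  session terminated during:", x$terminated_phase, "\n")
  cat(sprintf("  %d reinforcers, %.1f currency units earned\n",
              x$n_reinforcers, x$earnings))
  cat(sprintf("  %d logged events over %.1f s simulated time\n",
              nrow(x$log), max(x$log$t_s)))
  invisible(x)
}
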