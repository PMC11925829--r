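# Shared fixtures, all built in code at test time.

# A fast session configuration: 2 blocks x 3 cycles of 20-s components,
# still giving the six observation periods per component that the
# stability criterion needs.
small_config <- function(seed = 1L, experiment = 1, participant = "GP101",
                         n_forced_ext_lean = 2L, ...) {
  session_config(participant_id = participant, experiment = experiment,
                 seed = seed, n_blocks = 2L, cycles_per_block = 3L,
                 component_s = 20, ici_s = 2, rest_s = 5,
                 n_forced_ext_lean = n_forced_ext_lean,
                 choice_test_cycles = 1L, ...)
}

perfect_rule_agent <- function(cfg, ...)
  rule_following_agent(rule_map_from_condition(cfg$condition), ...)

# One full-size rule-instructed session, computed once per test run.
full_exp1_session <- local({
  res <- NULL
  function() {
    if (is.null(res)) {
      cfg <- session_config("GP101", seed = 101L)
      res <<- run_session(cfg, perfect_rule_agent(cfg))
    }
    res
  }
})

# Hand-built event log with given per-period response counts; used to
# test the analysis layer against known arithmetic.
fake_log <- function(periods, phase = "training", component_s = 60) {
  rows <- list()
  t <- 0
  for (i in seq_along(periods)) {
    p <- periods[[i]]
    payload <- sprintf(
      paste0("stimulus=%s;left=VI:10;right=EXT;instructed=%s;",
             "rich_side=left;lean_side=right;forced_ext=%d;",
             "initial_color=;flash_ms=235;alternation_ms=400"),
      p$stimulus %||% "red", p$instructed %||% "left",
      as.integer(p$forced_ext %||% FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      t_s = t, phase = phase, block = 1L, cycle = i, component_index = i,
      component_label = p$label, event = "component_on", payload = payload)
    tt <- t
    for (side in c("left", "right")) {
      n <- p[[side]] %||% 0L
      if (n > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          t_s = tt + seq_len(n) * 0.1, phase = phase, block = 1L,
          cycle = i, component_index = i, component_label = p$label,
          event = paste0("response_", side), payload = "")
    }
    t <- t + component_s
    rows[[length(rows) + 1L]] <- data.frame(
      t_s = t, phase = phase, block = 1L, cycle = i, component_index = i,
      component_label = p$label, event = "component_off", payload = "")
    t <- t + 10
  }
  out <- do.call(rbind, rows)
  out[order(out$t_s), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Audit: no reinforcer may be delivered within cod_s of the preceding
# changeover in the same component.
check_cod_safety <- function(log, cod_s = 3) {
  for (phase in c("training", "choice_test")) {
    lg <- log[log$phase == phase, , drop = FALSE]
    for (ci in unique(lg$component_index[lg$event == "cod_on"])) {
      ev <- lg[lg$component_index == ci, , drop = FALSE]
      cod_t <- ev$t_s[ev$event == "cod_on"]
      reinf_t <- ev$t_s[ev$event %in% c("reinforcer_left",
                                        "reinforcer_right")]
      for (rt in reinf_t) {
        prior <- cod_t[cod_t <= rt]
        if (length(prior) && rt - max(prior) < cod_s - 1e-9) return(FALSE)
      }
    }
  }
  TRUE
}
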