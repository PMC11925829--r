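# Phase orchestration, counterbalancing, and the event log.

test_that("the condition table reproduces the counterbalanced assignments", {
  tab <- condition_table(1)
  expect_equal(nrow(tab), 8)
  gp101 <- tab[tab$participant == "GP101", ]
  expect_equal(gp101$rich_color, "red")
  expect_equal(gp101$rich_side, "left")    # Red VI-10 on the left
  expect_equal(gp101$lean_side, "right")   # Blue VI-60 on the right
  expect_equal(gp101$rule_red, "left")
  expect_equal(gp101$rule_blue, "right")
  gp301 <- tab[tab$participant == "GP301", ]
  expect_equal(gp301$rich_side, "right")   # Red EXT - VI-10
  expect_equal(gp301$lean_side, "left")
  # counterbalancing symmetry: exactly 4 of 8 rows put the VI-10 left
  expect_equal(sum(tab$rich_side == "left"), 4)
  expect_equal(sum(tab$rich_color == "red"), 4)
  # Lean VI always sits opposite the Rich VI
  expect_true(all(tab$rich_side != tab$lean_side))
  tab2 <- condition_table(2)
  expect_equal(nrow(tab2), 8)
  expect_true(all(startsWith(tab2$participant, "CP")))
})

test_that("a training cycle spans 140 s: two 60-s components plus two 10-s ICIs", {
  res <- full_exp1_session()
  tr <- res$log[res$log$phase == "training", ]
  ons <- tr[tr$event == "component_on", ]
  offs <- tr[tr$event == "component_off", ]
  expect_equal(nrow(ons), 36)   # 3 blocks x 6 cycles x 2 components
  expect_equal(offs$t_s - ons$t_s, rep(60, 36))
  # consecutive cycle onsets within a block are 140 s apart
  first_per_cycle <- tapply(ons$t_s, list(ons$block, ons$cycle), min)
  for (b in 1:3) expect_equal(diff(first_per_cycle[b, ]), rep(140, 5),
                              ignore_attr = TRUE)
  # each cycle presents both components exactly once
  per_cycle <- table(ons$block, ons$cycle, ons$component_label)
  expect_true(all(per_cycle == 1))
  # 18 observation periods per component
  expect_equal(as.vector(table(ons$component_label)), c(18, 18))
})

test_that("exactly the configured number of Lean components run as EXT-EXT", {
  res <- full_exp1_session()
  counts <- observation_period_counts(res$log, "training")
  lean <- counts[counts$component_label == "Lean", ]
  expect_equal(nrow(lean), 18)
  expect_equal(sum(lean$forced_ext), 6)
  # no programmed reinforcement there, for any agent
  expect_true(all(lean$reinforcers[lean$forced_ext] == 0))
  # Rich components are never forced to extinction
  expect_true(!any(counts$forced_ext[counts$component_label == "Rich"]))
})

test_that("timestamps are non-decreasing and rests separate the blocks", {
  res <- full_exp1_session()
  expect_true(all(diff(res$log$t_s) >= 0))
  expect_equal(sum(res$log$event == "rest_on"), 2)
  rests <- res$log[res$log$event %in% c("rest_on", "rest_off"), ]
  expect_equal(rests$t_s[rests$event == "rest_off"] -
                 rests$t_s[rests$event == "rest_on"], rep(30, 2))
})

test_that("a compliant rule follower passes training at the 95% criterion", {
  res <- full_exp1_session()
  expect_true(res$training_passed)
  rich <- percent_instructed_series(res$log, "Rich")
  expect_equal(as.numeric(rich), rep(100, 18))
})

test_that("training fails for non-compliant and for silent agents", {
  cfg <- small_config(seed = 5)
  anti <- perfect_rule_agent(cfg, compliance = 0)
  out <- run_training(cfg, anti)
  expect_false(out$passed)
  # an agent that never responds fails the criterion without an error
  mute <- perfect_rule_agent(cfg, response_rate_hz = 1e-4)
  out <- run_training(cfg, mute)
  expect_false(out$passed)
})

test_that("the rule test validates exact lowercase tokens and gates the session", {
  cfg <- small_config(seed = 9)
  rt <- run_rule_test(cfg, perfect_rule_agent(cfg))
  expect_true(rt$passed)
  expect_equal(nrow(rt$answers), 4)
  expect_setequal(rt$answers$type, c("side", "color"))
  # an uppercase variant of the correct token is scored incorrect
  rt <- run_rule_test(cfg, perfect_rule_agent(cfg, rule_miscase = TRUE))
  expect_false(rt$passed)
  expect_true(all(!rt$answers$correct))
  # one wrong answer of four fails the phase and ends the session early
  set.seed(42)
  res <- run_session(small_config(seed = 7),
                     perfect_rule_agent(cfg, rule_error_prob = 1))
  expect_true(res$training_passed)
  expect_equal(res$terminated_phase, "rule_test")
  expect_false(res$choice_test_run)
  expect_false(any(res$log$phase == "choice_test"))
  # the phase does not exist in experiment 2
  cfg2 <- small_config(seed = 9, experiment = 2, participant = "CP111")
  expect_error(run_rule_test(cfg2, perfect_rule_agent(cfg2)),
               "not applicable")
})

test_that("the choice test presents two cycles of all four components under the right contingencies", {
  res <- full_exp1_session()
  ct <- res$log[res$log$phase == "choice_test", ]
  ons <- ct[ct$event == "component_on", ]
  expect_equal(nrow(ons), 8)
  expect_equal(as.vector(table(ons$component_label)), rep(2, 4))
  counts <- observation_period_counts(res$log, "choice_test")
  # BS and NS never deliver reinforcers (extinction on both sides)
  expect_true(all(counts$reinforcers[counts$component_label %in%
                                       c("BS", "NS")] == 0))
  # BS carries an alternating stimulus with a random initial color
  bs_meta <- ons[ons$component_label == "BS", "payload"]
  expect_true(all(grepl("stimulus=alternating", bs_meta)))
  expect_true(all(grepl("initial_color=(red|blue)", bs_meta)))
  # NS shows no stimulus
  expect_true(all(grepl("stimulus=none",
                        ons[ons$component_label == "NS", "payload"])))
})

test_that("the alternating both-stimuli display switches color every 400 ms", {
  expect_equal(bs_stimulus_at(c(0, 0.399, 0.4, 0.799, 0.8), "red"),
               c("red", "red", "blue", "blue", "red"))
  expect_equal(bs_stimulus_at(c(0, 0.4), "blue"), c("blue", "red"))
  # 150 switches over a 60-s component
  trace <- bs_stimulus_at(seq(0, 59.99, by = 0.01), "red")
  expect_equal(sum(trace[-1] != trace[-length(trace)]), 149)
})

test_that("phase order is training -> rule test -> choice test, gated by criteria", {
  cfg <- small_config(seed = 21)
  res <- run_session(cfg, perfect_rule_agent(cfg))
  expect_true(res$training_passed)
  expect_true(res$rule_test$passed)
  expect_true(res$choice_test_run)
  expect_true(is.na(res$terminated_phase))
  phases <- unique(res$log$phase)
  expect_equal(phases, c("training", "rule_test", "choice_test"))
  # a failed training criterion stops everything downstream
  res <- run_session(cfg, perfect_rule_agent(cfg, compliance = 0.3))
  expect_false(res$training_passed)
  expect_equal(res$terminated_phase, "training")
  expect_false(any(res$log$phase %in% c("rule_test", "choice_test")))
  # experiment 2 has no rule-test phase
  cfg2 <- small_config(seed = 22, experiment = 2, participant = "CP111",
                       criterion_pct = 80)
  res2 <- run_session(cfg2, rate_learning_agent())
  expect_false(any(res2$log$phase == "rule_test"))
  expect_null(res2$rule_test)
})

test_that("a session replays bit-for-bit from its seed", {
  cfg <- small_config(seed = 77)
  a <- run_session(cfg, perfect_rule_agent(cfg, compliance = 0.9))
  b <- run_session(cfg, perfect_rule_agent(cfg, compliance = 0.9))
  expect_identical(a$log, b$log)
  la <- run_session(cfg, rate_learning_agent())
  lb <- run_session(cfg, rate_learning_agent())
  expect_identical(la$log, lb$log)
  # a different seed gives a different log
  cfg2 <- small_config(seed = 78)
  c <- run_session(cfg2, perfect_rule_agent(cfg, compliance = 0.9))
  expect_false(identical(a$log, c$log))
})

test_that("earnings accumulate at the configured value per reinforcer", {
  res <- full_exp1_session()
  n <- sum(res$log$event %in% c("reinforcer_left", "reinforcer_right"))
  expect_equal(res$n_reinforcers, n)
  expect_equal(res$earnings, n * 0.7)
})
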