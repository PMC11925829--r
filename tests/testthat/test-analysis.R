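# Response-allocation measures and the paired exact permutation test.

test_that("per-period percentages follow the response counts", {
  log <- fake_log(list(
    list(label = "Rich", left = 40, right = 0),
    list(label = "Rich", left = 20, right = 20),
    list(label = "Rich", left = 0, right = 0),
    list(label = "Rich", left = 0, right = 40)))
  pct <- percent_instructed_series(log, "Rich")
  expect_equal(as.numeric(pct), c(100, 50, NA, 0))
  # a zero-response period is undefined, not 0, and is flagged
  expect_equal(attr(pct, "flagged"), 3L)
  expect_error(percent_instructed_series(log, "BS"), "instructed")
  expect_error(percent_instructed_series(log, "Banana"), "instructed")
})

test_that("period counts carry metadata and respect basic identities", {
  res <- full_exp1_session()
  counts <- observation_period_counts(res$log, "training")
  expect_equal(nrow(counts), 36)
  expect_true(all(counts$responses_instructed <=
                    counts$responses_left + counts$responses_right))
  expect_true(all(counts$responses_left >= 0 & counts$responses_right >= 0))
  expect_equal(sort(unique(counts$period_index)), 1:18)
  # counts match a direct tally of the raw log rows
  one <- counts[counts$component_index == 1, ]
  raw <- res$log[res$log$component_index == 1 &
                   res$log$phase == "training", ]
  expect_equal(one$responses_left, sum(raw$event == "response_left"))
  expect_equal(one$responses_right, sum(raw$event == "response_right"))
})

test_that("the stability check pools counts over the last six periods with a strict >=", {
  # six perfect periods pass at 95
  expect_true(stability_check(rep(40, 6), rep(40, 6), threshold_pct = 95))
  # pooled 94.9% fails at 95; pooled exactly 95.0% passes
  expect_false(stability_check(c(949), c(1000), last_k = 1,
                               threshold_pct = 95))
  expect_true(stability_check(c(950), c(1000), last_k = 1,
                              threshold_pct = 95))
  ins <- c(rep(0, 4), 155, 156, 160, 170, 160, 148)  # pooled 949/1000
  tot <- c(rep(0, 4), 160, 165, 170, 180, 170, 155)
  expect_false(stability_check(ins, tot, threshold_pct = 95))
  # the experiment-2 criterion is the same check at 80
  expect_true(stability_check(rep(8, 6), rep(10, 6), threshold_pct = 80))
  expect_false(stability_check(rep(7, 6), rep(10, 6), threshold_pct = 80))
  # windows with no responses fail rather than erroring
  expect_false(stability_check(rep(0, 6), rep(0, 6), threshold_pct = 95))
  expect_error(stability_check(1:3, 1:3, last_k = 6), "at least 6")
})

test_that("choice-test pooling sums counts across presentations before percentaging", {
  log <- fake_log(list(
    list(label = "Rich", left = 10, right = 0),
    list(label = "Rich", left = 5, right = 5)), phase = "choice_test")
  p <- pool_choice_test(log, "Rich")
  expect_equal(unname(p[["instructed"]]), 75)
  expect_equal(unname(p[["uninstructed"]]), 25)
  expect_equal(attr(p, "counts"), c(left = 15, right = 5))
  # two exclusive presentations pool to 100/0
  log2 <- fake_log(list(
    list(label = "Rich", left = 30, right = 0),
    list(label = "Rich", left = 12, right = 0)), phase = "choice_test")
  expect_equal(as.numeric(pool_choice_test(log2, "Rich")), c(100, 0))
  # BS/NS report by the sides the Rich and Lean rules instruct
  log3 <- fake_log(list(
    list(label = "NS", left = 6, right = 18, instructed = "")),
    phase = "choice_test")
  p3 <- pool_choice_test(log3, "NS")
  expect_equal(unname(p3[["rich"]]), 25)   # rich_side=left in the fixture
  expect_equal(unname(p3[["lean"]]), 75)
  # a response-free component yields undefined percentages, not zeros
  log4 <- fake_log(list(list(label = "NS", instructed = "")),
                   phase = "choice_test")
  expect_true(all(is.na(pool_choice_test(log4, "NS"))))
  expect_error(pool_choice_test(log, "Banana"), "unknown component")
})

test_that("the paired permutation test reproduces hand-enumerated exact p-values", {
  # eight pairs of (100, 0): T = 800, M_dif = 100, p = 2/256
  r <- fisher_pitman_paired(rep(100, 8), rep(0, 8))
  expect_equal(r$T, 800)
  expect_equal(r$M_dif, 100)
  expect_equal(r$p, 2 / 256)
  expect_equal(r$method, "exact")
  expect_equal(r$n_permutations, 256)
  expect_equal(r$T, r$M_dif * r$n_pairs)
  # d = (1, 2, 3): of the 8 sign patterns only +++ and --- reach |6|
  r <- fisher_pitman_paired(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$p, 0.25)
  # d = (2, -1, 3, 5): hand enumeration over 16 patterns gives 4/16
  r <- fisher_pitman_paired(c(2, -1, 3, 5), c(0, 0, 0, 0))
  expect_equal(r$p, 0.25)
  # a zero difference contributes to both tails: d = (0, 1, 1) -> 4/8
  r <- fisher_pitman_paired(c(0, 1, 1), c(0, 0, 0))
  expect_equal(r$p, 0.5)
  # identical samples: degenerate, not an error
  r <- fisher_pitman_paired(c(3, 1, 4, 1), c(3, 1, 4, 1))
  expect_equal(r$T, 0)
  expect_equal(r$p, 1)
})

test_that("the permutation test is antisymmetric and scale invariant", {
  set.seed(99)
  for (i in 1:20) {
    x <- stats::rnorm(8, 1)
    y <- stats::rnorm(8)
    a <- fisher_pitman_paired(x, y)
    b <- fisher_pitman_paired(y, x)
    expect_equal(a$T, -b$T)
    expect_equal(a$p, b$p)
    s <- fisher_pitman_paired(10 * x, 10 * y)
    expect_equal(s$p, a$p)
  }
})

test_that("undefined pairs are dropped with a warning, reducing n", {
  x <- c(100, 90, NA, 80)
  y <- c(0, 10, 5, NA)
  expect_warning(r <- fisher_pitman_paired(x, y), "dropped")
  expect_equal(r$n_pairs, 2)
  expect_error(suppressWarnings(fisher_pitman_paired(c(1, NA), c(NA, 1))),
               "at least 2")
  expect_error(fisher_pitman_paired(1:3, 1:2), "equal length")
})

test_that("exact enumeration and Monte Carlo agree", {
  set.seed(123)
  d <- stats::rnorm(12, 0.4)
  exact <- fisher_pitman_paired(d, rep(0, 12))
  mc <- fisher_pitman_paired(d, rep(0, 12), max_exact_n = 1L, n_mc = 1e5L)
  expect_equal(mc$method, "monte_carlo")
  se <- sqrt(exact$p * (1 - exact$p) / 1e5)
  expect_lt(abs(mc$p - exact$p), 3 * se + 2e-5)
})

test_that("the exact test is valid and conservative under the null", {
  set.seed(2024)
  rejections <- replicate(2000, {
    d <- stats::rnorm(8)
    fisher_pitman_paired(d, rep(0, 8))$p <= 0.05
  })
  rate <- mean(rejections)
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
  expect_gte(rate, 0.01)
})

test_that("group choice-test tables mirror the per-participant pooling", {
  grp <- run_group(1, list(type = "rule_following", compliance = 1),
                   seed = 500,
                   config_args = list(n_blocks = 2L, cycles_per_block = 3L,
                                      component_s = 20, ici_s = 2,
                                      rest_s = 5, n_forced_ext_lean = 2L,
                                      choice_test_cycles = 1L))
  tab <- grp$table
  expect_equal(nrow(tab), 4)
  rich <- tab[tab$component == "Rich", ]
  expect_equal(rich$T, 800)
  expect_equal(rich$M_dif, 100)
  expect_lt(rich$p, 0.01)
  expect_equal(rich$n_pairs, 8)
})
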