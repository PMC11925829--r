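# Dependent variables and statistics: per-observation-period response
# allocation, stability (advancement) criteria, choice-test pooling, and
# the Fisher-Pitman paired exact permutation test.

parse_payload <- function(s) {
  if (!nzchar(s)) return(character(0))
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) if (length(x) > 1L) x[2] else "",
                         character(1)),
                  vapply(kv, `[`, character(1), 1))
}

#' Per-observation-period response and reinforcer counts
#'
#' Each component presentation is one observation period.  Counts
#' responses and reinforcers per period and carries the component
#' metadata (stimulus, schedule sides, instructed side, forced-extinction
#' flag) parsed from the `component_on` event.
#'
#' @param log An event-log data frame (from [run_session()] or
#'   [read_event_log()]).
#' @param phase `"training"` or `"choice_test"`.
#' @return A data frame with one row per observation period: columns
#'   `phase`, `period_index` (ordinal within component label),
#'   `component_index`, `component_label`, `stimulus`, `instructed_side`,
#'   `forced_ext`, `rich_side`, `lean_side`, `responses_left`,
#'   `responses_right`, `responses_instructed`, `reinforcers`.
#' @export
observation_period_counts <- function(log,
                                      phase = c("training", "choice_test")) {
  phase <- match.arg(phase)
  lg <- log[log$phase == phase, , drop = FALSE]
  ons <- lg[lg$event == "component_on", , drop = FALSE]
  if (nrow(ons) == 0L)
    stop("no ", phase, " components in this log", call. = FALSE)
  ons <- ons[order(ons$t_s), , drop = FALSE]
  rows <- lapply(seq_len(nrow(ons)), function(i) {
    on <- ons[i, ]
    meta <- parse_payload(on$payload)
    ev <- lg[lg$component_index == on$component_index, , drop = FALSE]
    rl <- sum(ev$event == "response_left")
    rr <- sum(ev$event == "response_right")
    instructed <- meta[["instructed"]]
    ri <- if (identical(instructed, "left")) rl
          else if (identical(instructed, "right")) rr
          else NA_integer_
    data.frame(
      phase = phase, component_index = on$component_index,
      component_label = on$component_label,
      stimulus = meta[["stimulus"]],
      instructed_side = instructed,
      forced_ext = identical(meta[["forced_ext"]], "1"),
      rich_side = meta[["rich_side"]], lean_side = meta[["lean_side"]],
      responses_left = rl, responses_right = rr,
      responses_instructed = ri,
      reinforcers = sum(ev$event %in% c("reinforcer_left",
                                        "reinforcer_right")),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$period_index <- stats::ave(seq_len(nrow(out)), out$component_label,
                                 FUN = seq_along)
  out[, c("phase", "period_index", "component_index", "component_label",
          "stimulus", "instructed_side", "forced_ext", "rich_side",
          "lean_side", "responses_left", "responses_right",
          "responses_instructed", "reinforcers")]
}

#' Percentage of responses on the instructed alternative, per period
#'
#' For each observation period of the given component, 100 x (responses
#' on the instructed alternative) / (total responses).  100 indicates
#' exclusive preference for the instructed alternative, 50 indifference,
#' 0 exclusive preference for the uninstructed alternative.  A period
#' with zero responses yields `NA` (undefined, not 0); the indices of
#' such periods are attached as attribute `"flagged"`.
#'
#' @param log An event-log data frame.
#' @param component_label `"Rich"` or `"Lean"` (the only components with
#'   an instructed alternative).
#' @param phase `"training"` or `"choice_test"`.
#' @return Numeric vector of percentages, one per observation period, in
#'   presentation order, with attribute `"flagged"`.
#' @export
percent_instructed_series <- function(log, component_label,
                                      phase = "training") {
  if (!component_label %in% c("Rich", "Lean"))
    stop("no instructed alternative is defined for component ",
         component_label, call. = FALSE)
  counts <- observation_period_counts(log, phase)
  counts <- counts[counts$component_label == component_label, , drop = FALSE]
  if (nrow(counts) == 0L)
    stop("component ", component_label, " not present in the ", phase,
         " log", call. = FALSE)
  total <- counts$responses_left + counts$responses_right
  pct <- ifelse(total > 0, 100 * counts$responses_instructed / total,
                NA_real_)
  structure(pct, flagged = which(total == 0))
}

#' Stability / advancement check over the last k observation periods
#'
#' True when the pooled percentage of responses on the instructed
#' alternative over the last `last_k` periods is at or above
#' `threshold_pct` (the comparison is `>=`: a pooled 94.9% fails a 95%
#' criterion).  A window with zero responses fails the check.
#'
#' @param instructed Per-period counts of responses on the instructed/VI
#'   alternative.
#' @param total Per-period total response counts (same length).
#' @param last_k Window length (default 6).
#' @param threshold_pct Criterion percentage (95 with rules, 80 without).
#' @return Logical scalar.
#' @export
stability_check <- function(instructed, total, last_k = 6L,
                            threshold_pct = 95) {
  stopifnot(length(instructed) == length(total))
  if (length(total) < last_k)
    stop("need at least ", last_k, " observation periods", call. = FALSE)
  ins <- sum(utils::tail(instructed, last_k))
  tot <- sum(utils::tail(total, last_k))
  if (tot == 0) return(FALSE)
  100 * ins / tot >= threshold_pct
}

#' Did a training log meet the advancement criterion?
#'
#' Applies [stability_check()] to the last six observation periods of
#' each component; both must pass.
#'
#' @param log An event-log data frame containing a training phase.
#' @param criterion_pct Criterion percentage.
#' @param last_k Window length (default 6).
#' @return Logical scalar.
#' @export
training_passed <- function(log, criterion_pct = 95, last_k = 6L) {
  counts <- observation_period_counts(log, "training")
  all(vapply(c("Rich", "Lean"), function(lab) {
    cc <- counts[counts$component_label == lab, , drop = FALSE]
    stability_check(cc$responses_instructed,
                    cc$responses_left + cc$responses_right,
                    last_k, criterion_pct)
  }, logical(1)))
}

#' Pooled choice-test response percentages for one component
#'
#' Sums the response counts over the component's presentations in the
#' choice test, then converts to percentages.  For Rich and Lean the
#' alternatives are labeled by the instructed side; for BS and NS they
#' are labeled by the sides instructed by the Rich and Lean rules under
#' the participant's condition.
#'
#' @param log An event-log data frame containing a choice-test phase.
#' @param component_label `"Rich"`, `"Lean"`, `"BS"` or `"NS"`.
#' @return Named numeric percentages (`instructed`/`uninstructed`, or
#'   `rich`/`lean`), `NA` when no responses occurred, with attributes
#'   `"counts"` (summed left/right counts) and `"n_presentations"`.
#' @export
pool_choice_test <- function(log, component_label) {
  if (!component_label %in% c("Rich", "Lean", "BS", "NS"))
    stop("unknown component label: ", component_label, call. = FALSE)
  counts <- observation_period_counts(log, "choice_test")
  cc <- counts[counts$component_label == component_label, , drop = FALSE]
  if (nrow(cc) == 0L)
    stop("component ", component_label, " not present in the choice test",
         call. = FALSE)
  left <- sum(cc$responses_left)
  right <- sum(cc$responses_right)
  tot <- left + right
  pick <- function(side) if (identical(side, "left")) left else right
  if (component_label %in% c("Rich", "Lean")) {
    ins <- pick(cc$instructed_side[1])
    out <- c(instructed = ins, uninstructed = tot - ins)
  } else {
    out <- c(rich = pick(cc$rich_side[1]), lean = pick(cc$lean_side[1]))
  }
  pct <- if (tot > 0) 100 * out / tot
         else stats::setNames(rep(NA_real_, 2L), names(out))
  structure(pct, counts = c(left = left, right = right),
            n_presentations = nrow(cc))
}

#' Fisher-Pitman paired exact permutation test
#'
#' Tests the null hypothesis of zero mean difference for paired data via
#' the sign-flip permutation distribution of the paired differences
#' \eqn{d_i = x_i - y_i}.  The statistic is \eqn{T = \sum_i d_i}
#' (so \eqn{T = n \times M_{dif}}); the two-tailed exact p-value is the
#' proportion of the \eqn{2^n} sign assignments \eqn{s} with
#' \eqn{|\sum_i s_i d_i| \ge |T|} (ties inclusive, keeping the test exact
#' and conservative).  Full enumeration is used up to `max_exact_n`
#' pairs; beyond that a Monte-Carlo approximation with the observed
#' assignment included in the count.
#'
#' Pairs in which either value is missing are dropped (with a warning),
#' reducing `n_pairs` -- undefined response percentages from
#' zero-response observation periods propagate this way.
#'
#' @param x,y Numeric vectors of equal length (at least 2 complete
#'   pairs).
#' @param n_mc Monte-Carlo sample size used when `n_pairs > max_exact_n`.
#' @param max_exact_n Largest `n_pairs` for full enumeration (default
#'   20).
#' @return An object of class `paired_permutation`: a list with `T`,
#'   `M_dif`, `p`, `n_pairs`, `method` (`"exact"` or `"monte_carlo"`)
#'   and `n_permutations`.
#' @examples
#' fisher_pitman_paired(rep(100, 8), rep(0, 8))  # T = 800, p = 2/256
#' @export
fisher_pitman_paired <- function(x, y, n_mc = 1e5L, max_exact_n = 20L) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  if (any(!keep)) {
    warning(sum(!keep), " pair(s) with undefined values dropped")
    x <- x[keep]
    y <- y[keep]
  }
  n <- length(x)
  if (n < 2L)
    stop("need at least 2 complete pairs", call. = FALSE)
  d <- x - y
  T_obs <- sum(d)
  tol <- 1e-9 * max(1, abs(T_obs))
  if (n <= max_exact_n) {
    # subset-sum enumeration: flipping the signs of subset S gives
    # T_s = T - 2 * sum(d[S])
    sums <- 0
    for (di in d) sums <- c(sums, sums + di)
    p <- mean(abs(T_obs - 2 * sums) >= abs(T_obs) - tol)
    method <- "exact"
    n_perm <- 2^n
  } else {
    signs <- matrix(sample(c(-1, 1), n * n_mc, replace = TRUE),
                    nrow = n_mc, ncol = n)
    T_mc <- as.numeric(signs %*% d)
    p <- (1 + sum(abs(T_mc) >= abs(T_obs) - tol)) / (n_mc + 1)
    method <- "monte_carlo"
    n_perm <- n_mc
  }
  structure(
    list(T = T_obs, M_dif = T_obs / n, p = p, n_pairs = n,
         method = method, n_permutations = n_perm),
    class = "paired_permutation")
}

#' @export
print.paired_permutation <- function(x, ...) {
  cat(sprintf(
    "Fisher-Pitman paired permutation test (%s, %d permutations)\n",
    x$method, x$n_permutations))
  cat(sprintf("  n = %d pairs, T = %g, M_dif = %g, two-tailed p = %g\n",
              x$n_pairs, x$T, x$M_dif, x$p))
  invisible(x)
}

#' Group-level choice-test comparisons across sessions
#'
#' For a set of simulated participants, pairs the pooled choice-test
#' percentages within each component (instructed vs uninstructed for
#' Rich and Lean; Rich-rule vs Lean-rule alternative for BS and NS) and
#' runs [fisher_pitman_paired()] on each, mirroring the group analyses
#' reported for the human experiments.
#'
#' @param results A list of `session_result` objects (with choice tests).
#' @return A data frame with one row per component: `component`,
#'   `n_pairs`, `T`, `M_dif`, `p`, `method`.
#' @export
choice_test_group_table <- function(results) {
  stopifnot(length(results) >= 2L)
  comp <- c("Rich", "Lean", "BS", "NS")
  rows <- lapply(comp, function(lab) {
    mat <- vapply(results, function(r) {
      unname(pool_choice_test(r$log, lab)[1:2])
    }, numeric(2))
    tst <- fisher_pitman_paired(mat[1, ], mat[2, ])
    data.frame(component = lab, n_pairs = tst$n_pairs, T = tst$T,
               M_dif = tst$M_dif, p = tst$p, method = tst$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot per-period preference for the instructed alternative
#'
#' Base-graphics acquisition plot: percentage of responses on the
#' instructed alternative across successive training observation
#' periods, open circles for the Rich component, filled for Lean,
#' gray-ringed points marking non-reinforced (EXT-EXT) Lean periods.
#'
#' @param log An event-log data frame with a training phase.
#' @param main Plot title.
#' @return Invisibly, the plotted data frame.
#' @export
plot_percent_instructed <- function(log, main = "Training acquisition") {
  counts <- observation_period_counts(log, "training")
  rich <- percent_instructed_series(log, "Rich")
  lean <- percent_instructed_series(log, "Lean")
  graphics::plot(seq_along(rich), rich, ylim = c(0, 100), pch = 1,
                 xlab = "Observation period",
                 ylab = "% responses on instructed alternative",
                 main = main)
  graphics::points(seq_along(lean), lean, pch = 16)
  fe <- counts$forced_ext[counts$component_label == "Lean"]
  graphics::points(which(fe), lean[fe], pch = 21, bg = "black",
                   col = "gray50", cex = 1.6)
  graphics::abline(h = 50, lty = 3)
  graphics::legend("bottomright", pch = c(1, 16), bty = "n",
                   legend = c("Rich", "Lean"))
  invisible(data.frame(period = seq_along(rich), rich = rich, lean = lean))
}
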