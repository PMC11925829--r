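# Reinforcement-schedule primitives: constant-probability VI interval
# generation, VI/EXT schedule state machines, and the concurrent pair
# with a changeover delay (COD).
#
# All engine time is kept on a 10-ms grid (1 tick = 0.01 s) so that every
# programmed duration (60 s components, 10 s inter-component intervals,
# 3 s COD, 30 s rests, 400 ms stimulus alternation, 235 ms flash) is an
# integer number of ticks and sessions replay bit-for-bit.

TICK_S <- 0.01

s_to_ticks <- function(s) as.integer(round(s / TICK_S))

ticks_to_s <- function(ticks) ticks / 100

#' Fleshler-Hoffman constant-probability VI intervals
#'
#' Generates the `n` intervals of a variable-interval schedule with
#' programmed mean `mean_s` using the Fleshler-Hoffman progression
#' \deqn{t_k = T\,[\,1 + \ln n + (n-k)\ln(n-k) - (n-k+1)\ln(n-k+1)\,],
#'   \quad k = 1,\dots,n,}
#' with the convention \eqn{0\ln 0 = 0}.  Sampling these intervals without
#' replacement yields an approximately constant probability of reinforcer
#' setup per unit time (inter-reinforcer times close to exponential).
#' The terms telescope, so the arithmetic mean of the list equals `mean_s`
#' up to floating-point rounding.
#'
#' @param mean_s Programmed VI mean, in seconds. Must be positive.
#' @param n Number of intervals in the list (default 20).
#' @return Numeric vector of `n` strictly positive intervals (seconds),
#'   in increasing order.
#' @examples
#' ivs <- fleshler_hoffman_intervals(60, 20)
#' mean(ivs)  # 60
#' @export
fleshler_hoffman_intervals <- function(mean_s, n = 20L) {
  if (!is.numeric(mean_s) || length(mean_s) != 1L || !is.finite(mean_s) ||
      mean_s <= 0)
    stop("`mean_s` must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 ||
      n != round(n))
    stop("`n` must be a single positive integer", call. = FALSE)
  n <- as.integer(n)
  k <- seq_len(n)
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  mean_s * (1 + log(n) + xlx(n - k) - xlx(n - k + 1))
}

#' Create a VI interval list
#'
#' An `interval_list` holds the full Fleshler-Hoffman set for one VI
#' schedule plus the subset not yet consumed.  Draws are without
#' replacement; when the list is exhausted a fresh one is generated.
#'
#' @param mean_s Programmed VI mean in seconds.
#' @param n Number of intervals (default 20).
#' @return An object of class `interval_list` with fields `mean_s`,
#'   `n_intervals`, `intervals_s`, `remaining`.
#' @export
new_interval_list <- function(mean_s, n = 20L) {
  ivs <- fleshler_hoffman_intervals(mean_s, n)
  structure(
    list(mean_s = mean_s, n_intervals = as.integer(n),
         intervals_s = ivs, remaining = ivs),
    class = "interval_list")
}

#' Draw one interval without replacement
#'
#' Returns one interval chosen uniformly at random from the remaining
#' subset and removes it.  If the subset is empty a fresh list is
#' generated first.  Uses the session RNG stream.
#'
#' @param ilist An `interval_list`.
#' @return A list with `interval_s` (the drawn interval, seconds) and
#'   `list` (the updated `interval_list`).
#' @export
draw_interval <- function(ilist) {
  stopifnot(inherits(ilist, "interval_list"))
  if (length(ilist$remaining) == 0L)
    ilist$remaining <- fleshler_hoffman_intervals(ilist$mean_s,
                                                  ilist$n_intervals)
  i <- sample.int(length(ilist$remaining), 1L)
  val <- ilist$remaining[i]
  ilist$remaining <- ilist$remaining[-i]
  list(interval_s = val, list = ilist)
}

#' Create a schedule state machine (VI or EXT)
#'
#' A VI schedule arms (sets up a reinforcer) when its current interval
#' elapses and stays armed until a response collects it, at which point a
#' new interval is drawn without replacement.  EXT never arms.
#'
#' @param kind `"VI"` or `"EXT"`.
#' @param mean_s Programmed VI mean in seconds (VI only).
#' @param n_intervals Intervals per list (VI only, default 20).
#' @return An object of class `schedule_state`.
#' @export
new_schedule <- function(kind = c("VI", "EXT"), mean_s = NULL,
                         n_intervals = 20L) {
  kind <- match.arg(kind)
  sch <- list(kind = kind, armed = FALSE, arm_ticks = NA_integer_,
              interval_list = NULL)
  if (kind == "VI") {
    if (is.null(mean_s)) stop("a VI schedule needs `mean_s`", call. = FALSE)
    sch$interval_list <- new_interval_list(mean_s, n_intervals)
    d <- draw_interval(sch$interval_list)
    sch$interval_list <- d$list
    sch$arm_ticks <- max(1L, s_to_ticks(d$interval_s))
  }
  structure(sch, class = "schedule_state")
}

#' Time remaining until a VI arms, in seconds
#' @param sch A `schedule_state`.
#' @return Seconds until arming (0 if armed; `NA` for EXT).
#' @export
time_to_arm <- function(sch) {
  stopifnot(inherits(sch, "schedule_state"))
  if (sch$kind == "EXT") return(NA_real_)
  if (sch$armed) 0 else ticks_to_s(sch$arm_ticks)
}

#' Create a concurrent schedule pair with changeover delay
#'
#' Two response alternatives (left/right), each governed by its own
#' schedule, available simultaneously.  Switching alternatives triggers a
#' changeover delay during which the operanda are unavailable: responses
#' are dropped, and no reinforcer can be delivered within `cod_s` of a
#' changeover.
#'
#' @param left,right `schedule_state` objects.
#' @param cod_s Changeover delay in seconds (default 3).
#' @param active Whether a component is running (responses outside an
#'   active component are a protocol error).
#' @param post_cod_unconditional If `TRUE`, the first response to the
#'   switched-to alternative after a COD is reinforced even if that VI is
#'   not armed.  Off by default: unconditional delivery would distort the
#'   programmed VI rates.
#' @return An object of class `concurrent_pair`.
#' @export
new_concurrent_pair <- function(left, right, cod_s = 3, active = TRUE,
                                post_cod_unconditional = FALSE) {
  stopifnot(inherits(left, "schedule_state"), inherits(right, "schedule_state"))
  structure(
    list(left = left, right = right, last_alternative = "none",
         cod_ticks = 0L, cod_duration_ticks = s_to_ticks(cod_s),
         just_changed = FALSE, active = active,
         post_cod_unconditional = isTRUE(post_cod_unconditional)),
    class = "concurrent_pair")
}

advance_pair_ticks <- function(pair, dticks) {
  for (s in c("left", "right")) {
    sch <- pair[[s]]
    if (sch$kind == "VI" && !sch$armed) {
      sch$arm_ticks <- sch$arm_ticks - dticks
      if (sch$arm_ticks <= 0L) {
        sch$armed <- TRUE
        sch$arm_ticks <- 0L
      }
      pair[[s]] <- sch
    }
  }
  if (pair$cod_ticks > 0L)
    pair$cod_ticks <- max(0L, pair$cod_ticks - dticks)
  pair
}

#' Advance a concurrent pair in time
#'
#' Decrements the arming timer on each unarmed VI (arming exactly when the
#' interval elapses) and the remaining changeover delay.  No other state
#' changes.
#'
#' @param pair A `concurrent_pair`.
#' @param dt Time step in seconds; must be positive.  Rounded to the
#'   10-ms engine grid.
#' @return The updated `concurrent_pair`.
#' @export
advance_time <- function(pair, dt) {
  stopifnot(inherits(pair, "concurrent_pair"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  advance_pair_ticks(pair, max(1L, s_to_ticks(dt)))
}

#' Register a response on a concurrent pair
#'
#' Applies the changeover-delay contract:
#' \itemize{
#'   \item During an active COD the operanda are unavailable: the response
#'     is dropped (`"blocked"`) and counts toward nothing.
#'   \item A response to the alternative other than the last one responded
#'     to triggers a COD (`"cod_triggered"`); it is not recorded as a
#'     count toward that side's schedule.  The first response after
#'     component onset never triggers a COD.
#'   \item Otherwise the response is `"recorded"`, and additionally
#'     `"reinforced"` if that side's schedule is armed, which disarms it
#'     and draws the next interval.
#' }
#'
#' @param pair A `concurrent_pair` (must be active).
#' @param side `"left"` or `"right"`.
#' @return A list with `pair` (updated), `outcome` (one of `"blocked"`,
#'   `"cod_triggered"`, `"recorded"`, `"reinforced"`) and `reinforced`
#'   (logical).
#' @export
register_response <- function(pair, side = c("left", "right")) {
  stopifnot(inherits(pair, "concurrent_pair"))
  side <- match.arg(side)
  if (!isTRUE(pair$active))
    stop("protocol error: response outside an active component",
         call. = FALSE)
  if (pair$cod_ticks > 0L)
    return(list(pair = pair, outcome = "blocked", reinforced = FALSE))
  if (pair$last_alternative != "none" && side != pair$last_alternative) {
    pair$cod_ticks <- pair$cod_duration_ticks
    pair$last_alternative <- side
    pair$just_changed <- TRUE
    return(list(pair = pair, outcome = "cod_triggered", reinforced = FALSE))
  }
  pair$last_alternative <- side
  sch <- pair[[side]]
  reinforced <- isTRUE(sch$armed) ||
    (pair$post_cod_unconditional && pair$just_changed && sch$kind == "VI")
  pair$just_changed <- FALSE
  if (isTRUE(sch$armed)) {
    sch$armed <- FALSE
    d <- draw_interval(sch$interval_list)
    sch$interval_list <- d$list
    sch$arm_ticks <- max(1L, s_to_ticks(d$interval_s))
    pair[[side]] <- sch
  }
  list(pair = pair,
       outcome = if (reinforced) "reinforced" else "recorded",
       reinforced = reinforced)
}
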