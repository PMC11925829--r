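---
title: "Simulating rule-governed choice on concurrent VI-EXT schedules"
author: "rulechoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating rule-governed choice on concurrent VI-EXT schedules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rulechoice)
```

## The procedure

`rulechoice` implements an operant-conditioning task for studying choice
between two incompatible performance rules, each correlated with a
different rate of reinforcement, together with simulated agents that
stand in for human participants and the full analysis stack.

The task is a multiple schedule with two response alternatives (left and
right). During **training**, a red or a blue discriminative stimulus
signals which of two components is in effect. Each component runs a
concurrent variable-interval-extinction (VI-EXT) pair: one alternative
is reinforced on a VI schedule, the other never. One component carries a
VI 10 s (the *Rich* component, about six programmed reinforcers per
minute), the other a VI 60 s (*Lean*, about one per minute), and the VI
side differs between components, so the behavior the two stimuli call
for is incompatible. Which color carries the rich schedule, and on which
side its VI sits, is counterbalanced over eight conditions
(`condition_table()`). In the rule-instructed variant (experiment 1) the
simulated participant also "knows" two rules of the form *when the
circle is red, press the left button*; in the contingency-only variant
(experiment 2) it does not.

Training presents three blocks of six cycles. A cycle shows both
components, 60 s each, in random order, each followed by a 10-s
inter-component interval, so a cycle spans 140 s; 30-s rests separate
blocks. Each 60-s component presentation is one *observation period*.
To advance, at least 95% (80% without rules) of responses pooled over
the last six observation periods of *each* component must fall on the
instructed/VI alternative.

A **rule test** (experiment 1 only) then presents four fill-in
sentences -- two asking for the color given a side, two for the side
given a color. Answers must exactly match the lowercase, space-free
token; one error ends the session.

The **choice test** finally runs two cycles of a four-component
multiple schedule. Rich and Lean keep their trained contingencies. Two
probe components put the two contexts in conflict: *BS* (both stimuli)
shows the two colors alternating every 400 ms, and *NS* (no stimulus)
shows nothing; both run extinction on both alternatives, so whatever
preference appears there is carried in from training.

## Schedule primitives

VI interval lists are generated with the Fleshler-Hoffman progression

$$ t_k = T\left[1 + \ln n + (n-k)\ln(n-k) - (n-k+1)\ln(n-k+1)\right],
\qquad k = 1,\dots,n, $$

with $0 \ln 0 = 0$, $T$ the programmed mean and $n = 20$ intervals per
list. The terms telescope, so the list mean is exactly $T$, and
sampling the list uniformly *without replacement* gives an
approximately constant probability of reinforcer setup per unit time:
the empirical distribution of drawn intervals stays within
Kolmogorov-Smirnov distance ~0.032 of the exponential with mean $T$
(the residual is the $n = 20$ discretization). A fresh list is
generated at every component onset; draws within a component are
without replacement; an armed but uncollected reinforcer is discarded
at component end, and nothing carries over.

A VI *arms* when its current interval elapses and stays armed until a
response on that side collects the reinforcer, which draws the next
interval. Extinction never arms.

The 3-s changeover delay (COD) follows the standard free-operant
contract. Switching alternatives triggers the COD; in the original
preparation the operanda leave the screen, so responses during the COD
are dropped entirely (not queued, not counted). The changeover response
itself is not recorded as a count toward either schedule, and no
reinforcer can be delivered within 3 s of a changeover. The first
response after component onset never triggers a COD; it merely fixes
the reference alternative. One reading of the procedure's description
is that the first response after a COD is reinforced *unconditionally*;
that reading would contradict the programmed VI rates (rapid switchers
would collect far more than $60/T$ per minute), so the engine defaults
to standard armed-only semantics and exposes the literal reading behind
`post_cod_unconditional = TRUE` for sensitivity analyses.

## Time model

The engine runs on a fixed 10-ms grid: every programmed duration (60 s,
10 s, 30 s, 3 s, 400 ms, 235 ms) is an integer number of ticks, the
session clock is integer, and logged timestamps (seconds, 3 decimals)
are exact, which is what makes logs replay bit-for-bit from a single
session seed. Interval lists keep their exact closed-form values (so
list means are exact); an interval is rounded to the grid only when it
is consumed as an arming timer, a perturbation of at most 5 ms per
reinforcer. Agent decision opportunities arrive at exponential
inter-response times rounded up to the grid, and the engine advances
event-to-event rather than tick-by-tick.

One structural choice deserves a note: the procedure fixes the total
cycle at 140 s, which implies two 10-s intervals per cycle; the engine
places one inter-component interval after each component. It also
describes the non-reinforced Lean components as emergent (a sampled
interval exceeding the 60-s component) while fixing their count at six
of the 18; the engine enforces the printed count deterministically by
drawing six of the 18 Lean indices uniformly without replacement, which
keeps every session structurally identical rather than leaving the
count to sampling noise.

## Agents

The agents reproduce target *patterns*, not mechanisms; nothing here is
a model of a human participant.

`rule_following_agent()` emulates instructed performance: it responds
to the rule-mapped side with probability `compliance` (default 1,
matching the immediate, exclusive rule following observed with
instructions). Under BS it mixes the two instructed sides with weight
`bs_rich_weight` on the richer rule's side; the default 0.7 encodes the
"richer rule wins" outcome, while 0.5 encodes the indifference
hypothesis -- which of the two should hold is exactly the open
theoretical question, so both are one parameter away. Under NS it falls
back on a side `bias` (default 0.5).

`rate_learning_agent()` emulates acquisition without rules. It keeps an
exponentially weighted estimate $v$ of obtained reinforcement per
response for every (stimulus, side) pair,
$v \leftarrow v + \alpha(r - v)$ with $r \in \{0,1\}$ per recorded
response, and chooses by a two-option softmax with temperature $\tau$
conditioned on the current stimulus. Under BS the per-side estimates
are summed over the two colors (both contexts are present); under NS it
conditions on a separate, never-trained context, so NS choice stays at
chance -- matching the unsystematic NS preferences observed. Defaults
($\alpha = 0.01$, $\tau = 0.005$ on the reinforcers-per-response scale)
were fixed by a seed-ensemble study before release: across ten seeds of
the full no-rules training, the agent met the 80% criterion on both
components in 10/10 runs while still starting at chance and acquiring
gradually (the Lean component, with roughly one reinforcer per period,
is the binding constraint; larger $\alpha$ makes its estimate collapse
during the forced-extinction periods, larger $\tau$ leaves asymptotic
allocation short of criterion).

Emission rates default to 1 Hz, the order of magnitude implied by
median per-component response counts in this kind of task (a few dozen
per 60-s component). The calibration probe `always_respond_probe()`
instead defaults to 5 Hz: its job is to measure programmed rates, and
the obtained inter-reinforcer time is the programmed interval plus the
wait for the next response, so a higher probe rate brings obtained
rates within ~2% of $60/T$ per minute.

## Analysis

The primary dependent variable is the percentage of responses on the
instructed (or VI) alternative per observation period: 100 is exclusive
instructed responding, 50 indifference, 0 exclusive uninstructed
responding. A period with zero recorded responses is *undefined* -- it
yields `NA`, flagged, never 0, because 0 would assert exclusive
preference for the other side on no evidence. Undefined values
propagate to the paired test as dropped pairs, reducing $n$ with a
warning. The advancement check pools *counts* over the last six
periods of a component rather than averaging the six percentages, so
sparse periods cannot dominate; the comparison is `>=` (a pooled 94.9%
fails a 95% criterion). Choice-test percentages pool the counts over a
component's two presentations; for BS and NS the two alternatives are
relabeled as the sides the Rich and the Lean rule instruct under that
participant's condition.

Group comparisons use the two-tailed Fisher-Pitman exact permutation
test for paired data, on the statistic $T = \sum_i d_i$ with
$d_i = x_i - y_i$ (reported alongside $M_{dif} = T/n$, so
$T = n \times M_{dif}$). The exact two-tailed p is the fraction of the
$2^n$ sign assignments $s$ with $|\sum_i s_i d_i| \ge |T|$, ties
counted (inclusive), which keeps the test exact and conservative;
equality is tested with a $10^{-9}$ relative slack so floating-point
ties are not silently dropped. For eight pairs of (100, 0) this gives
$T = 800$, $M_{dif} = 100$, $p = 2/256 \approx 0.0078$. Above $n = 20$
pairs the test falls back to Monte Carlo with the observed assignment
included in the count, $p = (1 + k)/(B + 1)$. All differences zero is
degenerate, not an error: $T = 0$, $p = 1$. No multiple-testing
correction is applied; raw p-values are reported per comparison.

One anomaly the undefined-value contract resolves: a probe component in
which a participant emits no responses at all cannot meaningfully be
scored 0% on both alternatives; here it is `NA` on both and drops out
of the group test.

## Problem sizes used by the test suite

The suite exercises full-size sessions (3 x 6 cycles, 60-s components)
where structure is at stake, and scaled sessions (2 x 3 cycles, 20-s
components) where only contingency logic is: the engine is
parameterized in all durations, so the state machines traversed are
identical. Calibration runs use 10,000 s of simulated time per
schedule; the changeover-safety audit sweeps 1,000 randomized short
sessions across agent types, COD durations and component lengths;
learning-agent checks use ten-seed ensembles of the full-size no-rules
training.

## Limitations

The agents are stand-ins: passing tests show the *engine and analysis*
behave as specified under agents that reproduce the published response
patterns, not that any mechanism explains the human data. The rule
agents' BS behavior is an assumption exposed as a parameter, not a
prediction. Stimulus presentation (flash at 235 ms, the "Wait"
rectangle) is carried as configuration and logged metadata only;
nothing is rendered. Obtained reinforcer rates at participant-scale
response rates (~1 Hz) sit a few percent below programmed rates, as in
any finite-rate free-operant preparation; the calibration probe
quantifies exactly this gap.
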