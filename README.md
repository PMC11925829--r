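# rulechoice

A programmable operant-conditioning task engine for studying
**rule-governed versus contingency-shaped choice**, with simulated
agents in place of human participants.

The experimental question: when two incompatible performance rules
(*"when the circle is red, press the left button"* / *"when it is blue,
press the right button"*) are each correlated with a different rate of
reinforcement, which one controls behavior when both can be followed at
once? The package implements the full preparation needed to ask this at
the desk:

* **Schedule primitives** — constant-probability variable-interval (VI)
  schedules built from the Fleshler–Hoffman progression
  `t_k = T·[1 + ln n + (n−k)·ln(n−k) − (n−k+1)·ln(n−k+1)]`
  (20 intervals per list, sampled without replacement, fresh list per
  component), concurrent VI–EXT pairs, and a 3-s changeover delay
  (COD) under which responses are dropped and no reinforcer can follow
  a switch within 3 s.
* **Session engine** — a multiple schedule with training (3 blocks × 6
  cycles; two 60-s components per cycle, separated by 10-s intervals,
  so each cycle spans 140 s; 6 of the 18 Lean components run as
  EXT–EXT), an exact-match rule test, and a four-component choice test
  adding a both-stimuli (BS, colors alternating every 400 ms) and a
  no-stimulus (NS) probe, both under extinction. Advancement requires
  ≥ 95% (80% without rules) of responses on the instructed/VI
  alternative pooled over the last six observation periods of each
  component. Everything is seeded and replays bit-for-bit; sessions
  emit timestamped CSV event logs.
* **Agents** — a rule-following agent (immediate, near-exclusive
  instructed responding), a reinforcement-rate learning agent
  (exponentially weighted value estimates + softmax; develops VI
  preference gradually), and an always-respond calibration probe.
* **Analysis** — per-period response-allocation percentages, stability
  criteria, choice-test pooling, and the two-tailed **Fisher–Pitman
  paired exact permutation test**: statistic `T = Σ dᵢ` (so
  `T = n × M_dif`), exact p by full enumeration of the `2^n` sign
  assignments up to n = 20, Monte-Carlo fallback above.

## Worked example

```r
library(rulechoice)

cfg   <- session_config("GP101", experiment = 1, seed = 20260901)
agent <- rule_following_agent(rule_map_from_condition(cfg$condition))
res   <- run_session(cfg, agent)
res
#> Simulated session: GP101 (experiment 1, seed 20260901)
#>   training criterion (95%): passed
#>   rule test: 4/4 correct (passed)
#>   choice test run: TRUE
#>   119 reinforcers, 83.3 currency units earned
#>   2812 logged events over 3146.0 s simulated time
```

The compliant rule follower passes training with exclusive instructed
responding (`percent_instructed_series(res$log, "Lean")` is 100 in every
observation period), answers the four rule-test sentences, and in the
BS probe allocates most responses to the side instructed by the richer
rule:

```r
pool_choice_test(res$log, "BS")
#>      rich      lean
#> 94.871795  5.128205
```

Running all eight counterbalanced conditions and testing instructed vs
uninstructed allocation (Rich/Lean) and rich-rule vs lean-rule
allocation (BS/NS) across the eight simulated participants:

```r
grp <- run_group(1, list(type = "rule_following", compliance = 1),
                 seed = 20260901)
grp$table
#>   component n_pairs         T      M_dif         p method
#> 1      Rich       8 800.00000 100.000000 0.0078125  exact
#> 2      Lean       8 800.00000 100.000000 0.0078125  exact
#> 3        BS       8 529.25045  66.156307 0.0078125  exact
#> 4        NS       8 -59.20023  -7.400029 0.4687500  exact
```

Rich and Lean show the ceiling result `T = 800`, `M_dif = 100`,
`p = 2/256 ≈ 0.0078` (eight pairs of 100% vs 0%); the NS probe, where
no stimulus controls choice, stays far from significance. Programmed
reinforcer rates verify by simulation:

```r
cli_calibrate(10, duration_s = 10000, seed = 1)$rate_per_min  # 5.87
cli_calibrate(60, duration_s = 10000, seed = 1)$rate_per_min  # 0.99
```

about six and one reinforcers per minute — the 6:1 Rich:Lean contrast
the schedules program.

## Learn more

The methods vignette (`vignettes/rulechoice-methods.Rmd`) documents the
schedule semantics, the 10-ms time model, the agents and how their
defaults were fixed, the analysis conventions (undefined-percentage
handling, pooled stability checks, permutation-test tie handling), and
the package's limitations.
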