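# Example session configuration: participant GP101 of the
# rule-instructed experiment (experiment 1), driven by a fully
# compliant rule-following agent.
#
# Schema: every key mirrors an argument of rulechoice::session_config().
#   participant_id        condition-table row to use (GP*/CP* ids)
#   experiment            1 = rules given (rule-test phase runs), 2 = no rules
#   seed                  single RNG seed; the whole session replays from it
#   condition             schedule assignment; omit to use the built-in
#                         counterbalancing table row for participant_id
#   n_blocks, cycles_per_block   training structure (3 x 6)
#   component_s           observation-period duration, seconds
#   ici_s, rest_s         inter-component interval / inter-block rest, s
#   cod_s                 changeover delay, seconds
#   criterion_pct         advancement criterion over the last six
#                         observation periods of each component
#   n_forced_ext_lean     Lean components run as EXT-EXT during training
#   choice_test_cycles    cycles of the four-component choice test
#   rich_vi_mean_s, lean_vi_mean_s   programmed VI means, seconds
#   n_intervals           Fleshler-Hoffman list length
#   flash_ms              stimulus flash period (metadata only)
#   bs_alternation_ms     color alternation period in the BS component
#   point_value           currency units per reinforcer
#   post_cod_unconditional  reinforce the first post-changeover response
#                         even when the VI is not armed (default false)
#   agent_spec            agent type + parameters (see agent_from_spec())

participant_id: GP101
experiment: 1
seed: 20260901
n_blocks: 3
cycles_per_block: 6
component_s: 60.0
ici_s: 10.0
rest_s: 30.0
cod_s: 3.0
criterion_pct: 95.0
n_forced_ext_lean: 6
choice_test_cycles: 2
rich_vi_mean_s: 10.0
lean_vi_mean_s: 60.0
n_intervals: 20
flash_ms: 235.0
bs_alternation_ms: 400.0
point_value: 0.7
post_cod_unconditional: false
agent_spec:
  type: rule_following
  response_rate_hz: 1.0
  compliance: 1.0
  bs_rich_weight: 0.7
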