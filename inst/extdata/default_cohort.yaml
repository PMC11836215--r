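# Default synthetic-experiment design: four between-subject treatment
# conditions, three blocks (baseline / treatment / baseline) of 15 rounds.
# The population is all propensity-learning agents with heterogeneous
# parameters drawn from truncated normals.
n_per_condition:
  minus_giveup: 53
  minus_giveup_minus_trylow: 55
  plus_try: 54
  plus_try_explore: 54
population:
  mixture:
    adaptive_learner: 1.0
  alpha: {mean: 0.35, sd: 0.15, min: 0.05, max: 0.90}
  tau: {mean: 5.0, sd: 2.0, min: 1.0, max: 12.0}
  rho: {mean: 0.40, sd: 0.20, min: 0.00, max: 0.95}
  init_propensities:
    giveup_search: 14.0
    trylow_settle: 10.0
    try_search: 6.0
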