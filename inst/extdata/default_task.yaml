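# Default task structure: two 12-key matrices, 12 trials x 15 rounds,
# exploration cost 2 on first press, 9-trial analysis window.
try:
  low_value: 1
  high_value: 14
  p_high: 0.1
  n_keys: 12
giveup:
  low_value: 1
  high_value: 2
  p_high: 0.5
  n_keys: 12
trials_per_round: 12
rounds_per_block: 15
block_schemes: [baseline, "<treatment>", baseline]
analysis_window: 9
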