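# Example experiment configuration (all keys are experiment_config arguments)
style: center_biased
n_steps: 1000
seed: 1
L: 100
n_landmarks: 40
alpha: 0.1
n_cells: 2000
place_input: true
field_mode: emergent
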