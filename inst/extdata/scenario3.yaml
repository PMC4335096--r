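# Message-fatigue scenario at the study defaults
scenario: 3
n_runs: 100
master_seed: 1
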