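# example run configuration
seed = 1
sim.n_app = 104
sim.n_usual = 105
sim.horizon_days = 180
sim.engine_detail = false
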