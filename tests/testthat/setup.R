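# One shared synthetic study, generated once per test run.
SIM_DIR <- file.path(tempdir(), "earlinc-shared-sim")
SIM_CFG <- sim_config(seed = 42)
SIM <- simulate_inputs(SIM_CFG, SIM_DIR)
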