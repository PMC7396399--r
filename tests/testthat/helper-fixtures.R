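# Shared fixtures, built in code. The noiseless arterial input and the
# default frame schedule are reused across kinetic tests.

noiseless_blood <- function(seed = 11) {
  gen_input(input_spec(noise_cv = 0), seed = seed)
}

noiseless_input <- function(seed = 11) {
  b <- noiseless_blood(seed)
  build_input(b$plasma, b$pf_model)
}

default_sched <- function() frame_schedule()

# reference two-tissue parameter set used throughout the kinetics tests
ref_params <- function() kinetic_params(0.2, 0.4, 0.3, 0.1)
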