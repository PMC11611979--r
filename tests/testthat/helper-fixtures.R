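# Shared fixtures, built once per test run.

fix_config <- design_config()
fix_schedules <- build_subject_schedule(fix_config, seed = 7)
fix_schedule <- fix_schedules[[1]]
fix_inputs <- dcm_inputs(fix_schedules)
fix_inputs_run1 <- dcm_inputs(fix_schedules[[1]])

# fast inversion settings for tests (iteration cap only; tolerances default)
st_fast <- invert_settings(max_iter = 24)

# a small generating model + parameters used across inversion tests
gen_spec <- model_spec(c("SMA->SM1", "SM1->SMA", "self-SMA", "self-SM1"),
                       c("PMd", "SMA"))
gen_params <- function(b_self = -0.4) {
  B <- matrix(0, 3, 3)
  B[1, 1] <- b_self; B[1, 3] <- 0.3; B[3, 1] <- 0.2; B[3, 3] <- 0.1
  dcm_parameters(B = B, C = c(0, 0.4, 0.4))
}

# one-run single-subject data from the generating model
gen_series <- function(snr = 1, seed = 42, params = gen_params()) {
  simulate_bold(params, fix_inputs_run1, snr = snr, seed = seed)
}
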