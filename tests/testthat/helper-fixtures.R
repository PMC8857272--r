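# shared fixtures: everything is generated in code, nothing is stored

ref_patient <- function(id = "P1", age = 77, va = 52, pre = "naive",
                        delay = 0, obs_end = 730.5) {
  patient_baseline(id, age = age, baseline_va = va, pretreatment = pre,
                   delay_days = delay, obs_end_days = obs_end)
}

# random but valid parameter sets for property-style tests
random_params <- function() {
  va_params(g_ss = runif(1, 20, 80),
            k_out = runif(1, 0.001, 0.05),
            ec50 = runif(1, 0.001, 0.05),
            emax0_ss = runif(1, 0.1, 1),
            d_emax0 = runif(1, 0, 2),
            k_emax = runif(1, 0, 0.05),
            beta = runif(1, -2, 1),
            alpha_pretreated = runif(1, 0, 1))
}

small_cohort <- function(n = 40, seed = 1, params = NULL, noise_sd = 5) {
  generate_cohort(n = n, seed = seed, params = params, noise_sd = noise_sd)
}
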