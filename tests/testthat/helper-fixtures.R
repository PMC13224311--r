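# Shared fixtures, all built in code.

default_grid <- function() seq(2, 45, 0.5)

# identifiable recovery configuration: time constants, the three loop gains
# that are separable once their partners are frozen, and the delay
recovery_params <- function() {
  nmm_params(free_mask = c(Te = TRUE, Ti = TRUE, G1 = TRUE, G4 = TRUE,
                           G5 = TRUE, Di = TRUE, He = FALSE, Hi = FALSE,
                           G2 = FALSE, G3 = FALSE, R1 = FALSE, R2 = FALSE,
                           input_gain = FALSE))
}

recovery_truth <- function() c(Te = 0.15, Ti = -0.1, G1 = 0.2, G4 = -0.2,
                               G5 = 0.1, Di = 0.2)

# a handful of stable, well-separated parameter sets (log scale shifts)
stable_theta_sets <- function() list(
  c(Te = 0, Ti = 0),
  c(Te = 0.15, Ti = -0.1, G1 = 0.2, G4 = -0.2, G5 = 0.1, Di = 0.2),
  c(Te = -0.2, Ti = 0.15, G3 = 0.2, R1 = -0.3)
)

# small synthetic observation for quick VL/GA runs
quick_data <- function(theta = c(Te = 0.15, G1 = 0.2), noise_sd = 0.05,
                       seed = 3) {
  generate_spectrum(synthetic_spec(set_theta(nmm_params(), theta),
                                   noise_sd = noise_sd, seed = seed))
}

study1_bands <- function() study_preset("study1")$bands

expect_no_failure <- function(x) expect_true(all(is.finite(x)))
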