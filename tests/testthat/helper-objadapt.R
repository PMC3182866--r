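# Published best-fit parameter sets used as generative truth throughout.
SRM_EXP1 <- srm_params(alpha = 0.9513, beta = 0.2150)
DRM_EXP1 <- drm_params(0.9808, 0.0139, 0.9453, 0.2053)
MCSRM4_EXP2 <- mcsrm_params(0.9811, 0.0451, sigma_deg = 26.3, offset = 0.09)

main_exp1 <- function(seed = 1) {
  s <- build_schedule("exp1", seed = seed)
  s[!s$familiarization, ]
}

# Observed series for a noise-free self-consistency fit: the model's own
# predicted peak displacement, with clamp trials unmeasured.
noise_free_obs <- function(schedule, params, compliance = NULL) {
  sim <- simulate_model(schedule, params, compliance = compliance)
  ifelse(sim$mode == "error_clamp", NA, sim$abs_error)
}
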