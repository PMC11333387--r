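# Shared fixtures: small configurations are built in code at test time.

small_config <- function(seed = 42L, ...) {
  sim_config(seed = seed, n_trials = 60L, n_respondents = 4000L, ...)
}

# A pooled-effects object whose draws are all equal to the supplied truth,
# used to isolate downstream stages from pooling noise.
exact_pooled <- function(smds = lbp_class_smds(), n_draws = 50L,
                         reference = "usual_care") {
  draws <- matrix(rep(smds, each = n_draws), n_draws, length(smds),
                  dimnames = list(NULL, names(smds)))
  structure(list(mean = smds, se = smds * 0, tau = 0, draws = draws,
                 included_classes = names(smds),
                 excluded_classes = character(0),
                 reference = reference, n_draws = n_draws),
            class = "lbp_pooled_effects")
}

# A crosswalk fit whose draws are all equal to the true coefficients.
exact_crosswalk <- function(intercept = 2, slope = -0.08, n_draws = 50L) {
  draws <- cbind(intercept = rep(intercept, n_draws),
                 slope = rep(slope, n_draws))
  structure(list(intercept = intercept, slope = slope, residual_sd = 0,
                 draws = draws, n = 2L),
            class = "lbp_crosswalk_fit")
}
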