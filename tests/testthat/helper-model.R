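# Shared fixtures: all synthetic, built in code.

# A small stochastic model at the default calibration with short horizons,
# cheap enough for repeated use in tests.
small_model <- function(horizon = 600, burn_in = 300, seed = 42,
                        n_seasons = 40) {
  k <- make_kernel(synthetic_kernel_spec(n_seasons = n_seasons, seed = seed))
  smpm(k, smpm_config(horizon = horizon, burn_in = burn_in))
}

# A deterministic (one-season) kernel at the default channel means.
deterministic_kernel <- function() {
  sp <- synthetic_kernel_spec(
    n_seasons = 1,
    sds = c(S_d = 0, S_h = 0, S_u = 0, R_d = 0, R_h = 0, f = 0),
    seed = 1)
  make_kernel(sp)
}

deterministic_model <- function(horizon = 400, burn_in = 200) {
  smpm(deterministic_kernel(), smpm_config(horizon = horizon,
                                           burn_in = burn_in))
}

# A kernel with hand-set constant intercepts (no stochasticity), useful when
# a test needs full control over every rate.
constant_kernel <- function(values, specs = default_rate_specs(),
                            standardisation = c(mean = 170, sd = 15)) {
  ic <- matrix(values[c("S_d", "S_h", "S_u", "R_d", "R_h", "f")],
               nrow = 1, dimnames = list("only", names(values)))
  smpm_kernel(ic, specs = specs, standardisation = standardisation)
}

# Rate specs with every slope zero (rates depend on the intercept only).
flat_specs <- function(p_help_intercept = 0) {
  list(S_d = rate_spec("S_d"), S_h = rate_spec("S_h"),
       S_u = rate_spec("S_u"), R_d = rate_spec("R_d"),
       R_h = rate_spec("R_h"), f = rate_spec("f"),
       p_help = rate_spec("p_help", intercept = p_help_intercept,
                          seasonal = FALSE))
}

logit <- function(p) log(p / (1 - p))
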