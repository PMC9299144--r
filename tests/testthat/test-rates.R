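test_that("logistic_rate reproduces the closed form and saturates", {
  sp0 <- rate_spec("R_h")
  expect_equal(logistic_rate(sp0, intercept = 0), 0.5)
  expect_lt(logistic_rate(sp0, intercept = -30), 1e-12)

  # independent direct evaluation of the logistic form
  sp <- rate_spec("R_h", c(a = 0.1))
  eta <- 0.3 + 0.1 * 2
  expect_equal(logistic_rate(sp, intercept = 0.3, cov = list(a = 2)),
               exp(eta) / (1 + exp(eta)), tolerance = 1e-15)

  # vectorised over an age grid
  ages <- seq(0.5, 15, 0.5)
  expect_equal(logistic_rate(sp, 0.3, list(a = ages)),
               plogis(0.3 + 0.1 * ages))
})

test_that("missing covariates and bad inputs are reported by name", {
  sp <- rate_spec("S_h", c(a = -0.1, N = -0.2))
  expect_error(logistic_rate(sp, 0, cov = list(a = 1)), "covariate 'N'")
  expect_error(logistic_rate(sp, NA, cov = list(a = 1, N = 0)), "intercept")
  expect_error(rate_spec("S_h", c(bogus = 1)), "covariate terms")
  expect_error(rate_spec("p_help", seasonal = FALSE), "intercept")
  expect_error(rate_spec("S_d", c(a = Inf)), "finite")
})

test_that("help probability peaks at 10 years and increases with the ratio", {
  ages <- seq(0.5, 15, 0.5)
  ph <- help_probability(ages, r = 0.55)
  expect_equal(ages[which.max(ph)], 10)
  # beta_r > 0: strictly increasing in r at fixed age
  expect_true(all(help_probability(ages, 0.8) > help_probability(ages, 0.4)))
  expect_error(help_probability(5, r = -1), "non-negative")
  # all-zero coefficients give 1/2 everywhere
  flat <- rate_spec("p_help", intercept = 0, seasonal = FALSE)
  expect_equal(help_probability(ages, 3, spec = flat), rep(0.5, length(ages)))
})

test_that("rate_profile matches pointwise logistic_rate calls", {
  k <- make_kernel(synthetic_kernel_spec(seed = 7))
  rp <- rate_profile(k, "season_03", N = 165, r = 0.6)
  N_std <- (165 - 170) / 15
  ic <- k$intercepts["season_03", ]
  for (i in c(1, 10, 30)) {
    a <- k$age_sub[i]
    expect_equal(rp$S_h[i], logistic_rate(k$specs$S_h, ic[["S_h"]],
                                          list(a = a, N = N_std)))
    expect_equal(rp$R_h[i], logistic_rate(k$specs$R_h, ic[["R_h"]],
                                          list(a = a, N = N_std)))
  }
  for (i in c(1, 15, 29)) {
    a <- k$age_dom[i]
    expect_equal(rp$R_d_q1[i], logistic_rate(k$specs$R_d, ic[["R_d"]],
                                             list(a = a, N = N_std, q = 1)))
    expect_equal(rp$S_d[i], logistic_rate(k$specs$S_d, ic[["S_d"]],
                                          list(a = a, N = N_std)))
  }
  expect_error(rate_profile(k, "no_such_season", N = 165, r = 0.6),
               "not present")
})

test_that("an all-zero parameterisation yields 1/2 everywhere", {
  k <- smpm_kernel(matrix(0, 1, 6,
                          dimnames = list("s1", c("S_d", "S_h", "S_u",
                                                  "R_d", "R_h", "f"))),
                   specs = flat_specs())
  rp <- rate_profile(k, "s1", N = 170, r = 1)
  for (nm in c("S_d", "S_h", "S_u", "R_d_q0", "R_d_q1", "R_h",
               "f_sub", "f_dom", "p_help")) {
    expect_true(all(rp[[nm]] == 0.5), info = nm)
  }
})

test_that("default shapes: helped dominants reproduce independently of age, and
           density dependence has the documented signs", {
  k <- make_kernel(synthetic_kernel_spec(seed = 7))
  rp <- rate_profile(k, "season_01", N = 170, r = 0.55)
  # with help: the q interactions cancel the age terms exactly
  expect_lt(diff(range(rp$R_d_q1)), 1e-12)
  # without help: rises then falls with age
  i_max <- which.max(rp$R_d_q0)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(rp$R_d_q0))
  # density dependence: higher N lowers subordinate survival and reproduction
  hiN <- rate_profile(k, "season_01", N = 200, r = 0.55)
  expect_true(all(hiN$S_h < rp$S_h))
  expect_true(all(hiN$S_u < rp$S_u))
  expect_true(all(hiN$R_d_q0 < rp$R_d_q0))
  expect_true(all(hiN$R_h < rp$R_h))
  # offspring more likely to recruit as helpers under older mothers
  expect_true(all(diff(rp$f_sub) > 0))
})
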