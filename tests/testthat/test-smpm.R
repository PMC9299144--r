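test_that("a lethal environment empties the population in one step", {
  k <- constant_kernel(c(S_d = -40, S_h = -40, S_u = -40,
                         R_d = -40, R_h = -40, f = -40),
                       specs = flat_specs(p_help_intercept = -40))
  mod <- smpm(k, smpm_config(horizon = 10, burn_in = 1))
  nxt <- project_step(mod, default_state(mod), k$intercepts[1, ])
  expect_equal(sum(nxt$d) + sum(nxt$h) + sum(nxt$u), 0)
})

test_that("with only unhelped dominant reproduction, newborns enter as
           non-helpers and equal the number of dominant mothers", {
  k <- constant_kernel(c(S_d = -40, S_h = -40, S_u = -40,
                         R_d = 40, R_h = -40, f = -40),
                       specs = flat_specs(p_help_intercept = -40))
  mod <- smpm(k, smpm_config(horizon = 10, burn_in = 1))
  st <- default_state(mod, density = 1.5)
  nxt <- project_step(mod, st, k$intercepts[1, ])
  expect_equal(sum(nxt$d), 0)
  expect_equal(sum(nxt$h), 0)
  expect_equal(nxt$u[1], sum(st$d), tolerance = 1e-12)
  expect_equal(sum(nxt$u[-1]), 0)
})

test_that("the realized projection matrix forbids stage switching", {
  mod <- small_model()
  det <- project_step(mod, default_state(mod), mod$kernel$intercepts[1, ],
                      details = TRUE)
  K <- det$K
  n_dom <- length(mod$kernel$age_dom)
  n_sub <- length(mod$kernel$age_sub)
  i_h <- n_dom + seq_len(n_sub)
  i_u <- n_dom + n_sub + seq_len(n_sub)
  # helpers never flow into non-helper classes above age 0.5, nor vice versa
  expect_true(all(K[i_u[-1], i_h] == 0))
  expect_true(all(K[i_h[-1], i_u] == 0))
  # non-helpers do not reproduce: no flow into either newborn class
  expect_true(all(K[c(i_h[1], i_u[1]), i_u] == 0))
})

test_that("trajectories conserve identities and stay non-negative", {
  mod <- small_model(horizon = 200, burn_in = 50)
  sim <- simulate(mod, seed = 8)
  tr <- sim$trajectory
  expect_equal(tr$N, tr$n_d + tr$n_h + tr$n_u, tolerance = 1e-12)
  expect_true(all(sim$ensemble >= 0))
  expect_true(all(is.finite(sim$ensemble)))
  # ratio recomputed from the census
  expect_equal(tr$ratio, (tr$n_h + tr$n_u) / tr$n_d, tolerance = 1e-12)
  # reproducibility under a fixed seed
  sim2 <- simulate(mod, seed = 8)
  expect_identical(sim$trajectory$N_next, sim2$trajectory$N_next)
})

test_that("a deterministic kernel converges to its fixed point", {
  mod <- deterministic_model(horizon = 400, burn_in = 350)
  eq <- equilibrium(mod)
  expect_true(eq$converged)
  sim <- simulate(mod, seed = 1)
  expect_equal(sim$N_hat, eq$N, tolerance = 1e-6)
  expect_equal(state_to_vector(sim$final_state), state_to_vector(eq$state),
               tolerance = 1e-6)
})

test_that("doubling capacity and the density scale doubles the equilibrium", {
  # rates depend on density only through (N - mean)/sd and the ratio r, and
  # the lottery through x/(e^b nh + nu); doubling termax together with the
  # standardisation constants therefore rescales the whole model by 2
  k1 <- deterministic_kernel()
  k2 <- k1
  k2$standardisation <- c(mean = 2 * k1$standardisation[["mean"]],
                          sd = 2 * k1$standardisation[["sd"]])
  eq1 <- equilibrium(smpm(k1, smpm_config(termax = 111.2)))
  eq2 <- equilibrium(smpm(k2, smpm_config(termax = 222.4)))
  expect_equal(sum(eq1$state$d), 111.2, tolerance = 1e-8)
  expect_equal(sum(eq2$state$d), 222.4, tolerance = 1e-8)
  expect_equal(state_to_vector(eq2$state), 2 * state_to_vector(eq1$state),
               tolerance = 1e-6)
})

test_that("extinction truncates the trajectory with a warning", {
  k <- constant_kernel(c(S_d = -4, S_h = -4, S_u = -4,
                         R_d = -6, R_h = -6, f = 0),
                       specs = flat_specs())
  mod <- smpm(k, smpm_config(termax = 50, horizon = 500, burn_in = 10))
  expect_warning(sim <- simulate(mod, seed = 2), "extinct")
  expect_false(is.na(sim$extinct_at))
  expect_lt(nrow(sim$trajectory), 500)
})

test_that("stage-age distributions tabulate the ensemble and normalise", {
  mod <- small_model(horizon = 260, burn_in = 200)
  sim <- simulate(mod, seed = 9)
  d <- stage_age_distribution(sim)
  for (st in names(d)) {
    expect_equal(sum(d[[st]]$mean), 1, tolerance = 1e-12)
    expect_true(all(d[[st]]$q25 <= d[[st]]$q75 + 1e-12))
  }
  # direct tabulation oracle for the dominant stage
  n_dom <- length(mod$kernel$age_dom)
  m <- sim$ensemble[, seq_len(n_dom), drop = FALSE]
  norm <- m / rowSums(m)
  direct <- colMeans(norm); direct <- direct / sum(direct)
  expect_equal(d$dominant$mean, unname(direct), tolerance = 1e-12)
  # a single-class ensemble is a point mass
  fake <- sim
  fake$ensemble[, ] <- 0
  fake$ensemble[, 3] <- 7
  d2 <- stage_age_distribution(fake)
  expect_equal(d2$dominant$mean[3], 1)
  expect_equal(sum(d2$dominant$mean[-3]), 0)
})

test_that("NaN-producing rates are reported with the function name", {
  mod <- small_model()
  st <- default_state(mod)
  bad_ic <- mod$kernel$intercepts[1, ]
  bad_ic[["R_h"]] <- NaN
  expect_error(project_step(mod, st, bad_ic), "R_h|intercept")
})
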