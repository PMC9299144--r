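# A lethal-free, reproduction-free parameterisation for exact stepping
identity_model <- function(termax, beta = 0) {
  k <- constant_kernel(c(S_d = 40, S_h = 40, S_u = 40,
                         R_d = -40, R_h = -40, f = 0),
                       specs = flat_specs(p_help_intercept = 0))
  smpm(k, smpm_config(termax = termax, beta = beta,
                      horizon = 10, burn_in = 1))
}

make_pop <- function(n_d = 0, n_h = 0, n_u = 0, age = 1) {
  n <- n_d + n_h + n_u
  data.frame(id = seq_len(n), age = age,
             stage = rep(c("d", "h", "u"), c(n_d, n_h, n_u)),
             mother_id = NA_integer_, stringsAsFactors = FALSE)
}

test_that("ibm_from_state rounds densities to whole birds", {
  mod <- small_model()
  st <- default_state(mod)
  pop <- ibm_from_state(st)
  expect_equal(nrow(pop), sum(round(st$d)) + sum(round(st$h)) + sum(round(st$u)))
  expect_equal(sum(pop$stage == "d"), sum(round(st$d)))
  expect_true(all(pop$age %in% c(st$age_dom, st$age_sub)))
  expect_equal(anyDuplicated(pop$id), 0L)
})

test_that("with certain survival, no reproduction and a full territory grid,
           a step only advances ages", {
  mod <- identity_model(termax = 4)
  pop <- make_pop(n_d = 4, n_h = 3, n_u = 2, age = 2)
  pop$age[1] <- mod$kernel$age_max        # top class recursion
  st <- ibm_step(pop, mod, mod$kernel$intercepts[1, ])
  expect_equal(nrow(st$pop), nrow(pop))
  expect_equal(st$pop$stage, pop$stage)   # x = 0: nobody promoted
  expect_equal(st$pop$age[1], mod$kernel$age_max)
  expect_equal(st$pop$age[-1], pop$age[-1] + 0.5)
  expect_true(all(st$records$outcome == 0))
  expect_equal(nrow(st$records), 5)       # one record per surviving subordinate
  expect_equal(st$records$x, rep(0L, 5))
})

test_that("promotions exactly fill the vacant territories", {
  mod <- identity_model(termax = 3)
  pop <- make_pop(n_d = 0, n_h = 10, n_u = 10)
  set.seed(1)
  st <- ibm_step(pop, mod, mod$kernel$intercepts[1, ])
  expect_equal(sum(st$pop$stage == "d"), 3)
  expect_equal(sum(st$records$outcome), 3)
  expect_equal(unique(st$records$x), 3L)
  expect_equal(unique(st$records$nh), 10L)
  expect_equal(unique(st$records$nu), 10L)
})

test_that("at beta = 0 the lottery is fair between stages", {
  mod <- identity_model(termax = 5, beta = 0)
  pop <- make_pop(n_d = 0, n_h = 20, n_u = 20)
  set.seed(12)
  n_rep <- 400
  helper_wins <- 0
  for (i in seq_len(n_rep)) {
    st <- ibm_step(pop, mod, mod$kernel$intercepts[1, ])
    helper_wins <- helper_wins +
      sum(st$records$outcome[st$records$stage == "helper"])
  }
  # per replicate the helper win count is hypergeometric(20, 20, 5):
  # mean 2.5, variance 5 * .5 * .5 * 35/39
  mu <- n_rep * 2.5
  sd_tot <- sqrt(n_rep * 5 * 0.25 * 35 / 39)
  expect_lt(abs(helper_wins - mu), 4 * sd_tot)
})

test_that("fit_beta on IBM transition records recovers a null contrast", {
  mod <- identity_model(termax = 5, beta = 0)
  pop <- make_pop(n_d = 0, n_h = 20, n_u = 20)
  set.seed(13)
  recs <- do.call(rbind, lapply(seq_len(400), function(i) {
    ibm_step(pop, mod, mod$kernel$intercepts[1, ])$records
  }))
  fit <- fit_beta(recs)
  expect_lt(abs(coef(fit)[["beta"]]), 0.1)
  ci <- confint(fit)
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("ibm_simulate tracks counts, records and zero-inflated LRS", {
  mod <- small_model(horizon = 100, burn_in = 50)
  sim <- ibm_simulate(mod, n_steps = 60, seed = 17)
  expect_s3_class(sim, "ibm_sim")
  expect_equal(nrow(sim$counts), 60)
  expect_equal(sim$counts$n, sim$counts$n_d + sim$counts$n_h + sim$counts$n_u)
  expect_true(all(c("stage", "x", "nh", "nu", "outcome", "season", "step")
                  %in% names(sim$records)))
  expect_true(all(sim$records$outcome %in% 0:1))
  expect_true(all(sim$lrs$lrs >= 0))
  # demographic stochasticity: a sizeable share of completed lives left
  # no offspring at all, unlike the strictly positive expected-LRS cohorts
  done <- sim$lrs[sim$lrs$died, ]
  expect_gt(nrow(done), 50)
  expect_gt(mean(done$lrs == 0), 0.1)
  expect_output(print(sim), "complete lifetimes")
})

test_that("the posterior-predictive-style check summarises each dataset", {
  mod <- small_model(horizon = 100, burn_in = 50)
  draws <- list(make_kernel(synthetic_kernel_spec(seed = 1)),
                make_kernel(synthetic_kernel_spec(seed = 2)))
  ppc <- posterior_predictive_check(mod, draws, n_datasets = 2, n_steps = 30,
                                    seed = 19,
                                    observed = list(mean_N = 170))
  expect_s3_class(ppc, "ppc")
  expect_equal(nrow(ppc$summaries), 2)
  expect_true(all(is.finite(ppc$summaries$mean_N)))
  expect_true(all(ppc$summaries$mean_sub_observed <= ppc$summaries$mean_sub + 1e-9))
  expect_output(print(ppc), "artificial datasets")
})
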