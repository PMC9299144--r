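test_that("reward_chain validates its inputs", {
  expect_error(reward_chain(matrix(c(0.6, 0.6, 0.3, 0.2), 2), c(0.1, 0.1)),
               "at most 1")
  expect_error(reward_chain(matrix(0.5), 1.2), "rewards")
  ch <- reward_chain(matrix(0.5), 0.3, labels = "only")
  expect_s3_class(ch, "reward_chain")
  expect_equal(ch$labels, "only")
})

test_that("one-state chain matches the geometric closed forms", {
  # survival 0.8, Bernoulli(0.4) reward per census
  m <- lrs_moments(reward_chain(matrix(0.8), 0.4))
  expect_equal(m$mean, 0.4 / 0.2, tolerance = 1e-12)           # 2
  # rho2 = (p + 2 p s rho1) / (1 - s) = (0.4 + 2*0.4*0.8*2) / 0.2 = 8.4
  expect_equal(m$var, 8.4 - 4, tolerance = 1e-12)              # 4.4
  expect_equal(m$cv, sqrt(4.4) / 2, tolerance = 1e-12)
  # rho3 = (p + 3 p s rho1 + 3 p s rho2) / (1 - s) = 51.92
  expect_equal(m$skew, (51.92 - 3 * 2 * 8.4 + 2 * 8) / 4.4^1.5,
               tolerance = 1e-12)
})

test_that("zero rewards give zero moments and immortal chains are rejected", {
  m <- lrs_moments(reward_chain(matrix(0.9), 0))
  expect_equal(m$mean, 0)
  expect_equal(m$var, 0)
  expect_true(is.na(m$skew))
  expect_error(lrs_moments(reward_chain(matrix(1), 0.1)), "immortal")
  U <- matrix(c(0, 1, 1, 0), 2)          # deterministic 2-cycle, no mortality
  expect_error(lrs_moments(reward_chain(U, c(0.1, 0.2))), "immortal")
})

test_that("simulated lifetimes agree with the moment recursions", {
  # two transient classes with promotion, mortality and distinct rewards
  U <- matrix(c(0.3, 0.5,            # from class 1: stay 0.3, promote 0.5
                0.0, 0.85), 2)       # from class 2: stay 0.85
  ch <- reward_chain(U, c(0.1, 0.45))
  m <- lrs_moments(ch)
  set.seed(31)
  n <- 40000L
  draws <- simulate_lifetimes(ch, start = 1L, n = n)
  se_mean <- sqrt(m$var[1] / n)
  expect_lt(abs(mean(draws) - m$mean[1]), 3 * se_mean)
  # variance within 3 s.e. (s.e. of the sample variance via fourth moment)
  se_var <- sqrt((mean((draws - mean(draws))^4) -
                    stats::var(draws)^2 * (n - 3) / (n - 1)) / n)
  expect_lt(abs(stats::var(draws) - m$var[1]), 3 * se_var)
})

test_that("one-state zero-inflation matches its closed form", {
  s <- 0.8; p <- 0.4
  ch <- reward_chain(matrix(s), p)
  set.seed(7)
  n <- 20000L
  draws <- simulate_lifetimes(ch, n = n)
  p0 <- (1 - s) * (1 - p) / (1 - s * (1 - p))
  expect_lt(abs(mean(draws == 0) - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("cohort tracking produces coherent survivorship and LRS series", {
  mod <- small_model(horizon = 100, burn_in = 60)
  co <- track_cohort(mod, "helper", n_cohorts = 12, burn_in = 60, seed = 5)
  expect_s3_class(co, "cohort_lrs")
  expect_length(co$lrs, 12)
  expect_true(all(co$lrs >= 0))
  expect_equal(co$median, stats::median(co$lrs))
  expect_equal(unname(co$iqr), unname(stats::quantile(co$lrs, c(0.25, 0.75))))
  s <- co$series
  # survivorship never increases, accrued LRS never decreases
  expect_true(all(diff(s$l) <= 1e-12))
  expect_true(all(diff(s$lrs) >= -1e-12))
  expect_equal(s$l, s$occ_d + s$occ_h + s$occ_u, tolerance = 1e-12)
  expect_equal(s$l[1], 1)                      # unit mass at entry
  expect_equal(s$occ_h[1], 1)                  # ... in the helper stage
  # reproducibility
  co2 <- track_cohort(mod, "helper", n_cohorts = 12, burn_in = 60, seed = 5)
  expect_identical(co$lrs, co2$lrs)
  # the non-helper entry point works too
  cu <- track_cohort(mod, "nonhelper", n_cohorts = 3, burn_in = 60, seed = 6)
  expect_equal(cu$series$occ_u[1], 1)
})

test_that("reproductive values solve the left eigenproblem of the mean K", {
  mod <- deterministic_model(horizon = 260, burn_in = 240)
  sim <- simulate(mod, seed = 4)
  rv <- reproductive_values(sim)
  expect_equal(rv$v[1], 1)
  expect_true(all(rv$v >= 0))
  lam <- attr(rv, "lambda")
  # at the deterministic fixed point the realized matrix has lambda = 1
  expect_equal(lam, 1, tolerance = 1e-6)
  # independent residual check: v' K = lambda v'
  resid <- as.numeric(rv$v %*% sim$mean_K) - lam * rv$v
  expect_lt(max(abs(resid)), 1e-8)
  expect_error(reproductive_values(simulate(mod, seed = 4, keep_K = FALSE)),
               "keep_K")
})
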