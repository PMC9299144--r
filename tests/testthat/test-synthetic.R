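test_that("zero spread collapses every season onto the channel means", {
  sp <- synthetic_kernel_spec(
    n_seasons = 5,
    sds = c(S_d = 0, S_h = 0, S_u = 0, R_d = 0, R_h = 0, f = 0),
    seed = 1)
  k <- make_kernel(sp)
  for (s in seq_len(5)) {
    expect_equal(unname(k$intercepts[s, ]), unname(sp$means),
                 tolerance = 1e-12)
  }
})

test_that("kernel draws recover the generating moments", {
  sp <- synthetic_kernel_spec(n_seasons = 10000, seed = 44)
  k <- make_kernel(sp)
  ic <- k$intercepts
  n <- nrow(ic)
  for (ch in colnames(ic)) {
    se <- sp$sds[[ch]] / sqrt(n)
    expect_lt(abs(mean(ic[, ch]) - sp$means[[ch]]), 3 * se)
    # s.e. of a normal sample sd is about sd / sqrt(2 n)
    expect_lt(abs(stats::sd(ic[, ch]) - sp$sds[[ch]]),
              3 * sp$sds[[ch]] / sqrt(2 * n))
  }
  # cross-channel correlation close to the generating 0.3
  rho <- stats::cor(ic[, "S_d"], ic[, "R_d"])
  expect_lt(abs(rho - 0.3), 3 * (1 - 0.3^2) / sqrt(n))
})

test_that("subordinate survival is one shared draw unless decoupled", {
  k <- make_kernel(synthetic_kernel_spec(seed = 9))
  expect_identical(k$intercepts[, "S_h"], k$intercepts[, "S_u"])
  k2 <- make_kernel(synthetic_kernel_spec(
    shared_subordinate_survival = FALSE, seed = 9))
  expect_false(isTRUE(all.equal(k2$intercepts[, "S_h"],
                                k2$intercepts[, "S_u"])))
})

test_that("spec validation rejects bad moments and correlations", {
  expect_error(synthetic_kernel_spec(sds = c(S_d = -0.1, S_h = 0.1,
                                             S_u = 0.1, R_d = 0.1,
                                             R_h = 0.1, f = 0.1)),
               "non-negative")
  expect_error(synthetic_kernel_spec(means = c(S_d = 1)), "channels")
  expect_error(synthetic_kernel_spec(correlation = -0.9),
               "positive semi-definite")
})

test_that("transition records reflect the generating contrast", {
  set.seed(3)
  rec <- make_transition_records(true_beta = 0, n_records = 4000)
  expect_equal(nrow(rec), 4000)
  expect_true(all(rec$outcome %in% 0:1))
  expect_true(all(rec$nh + rec$nu >= 1))
  expect_setequal(unique(rec$stage), c("helper", "non-helper"))
  # beta = 0: helper and non-helper success rates coincide
  ph <- mean(rec$outcome[rec$stage == "helper"])
  pu <- mean(rec$outcome[rec$stage == "non-helper"])
  pool <- mean(rec$outcome)
  se <- sqrt(pool * (1 - pool) *
               (1 / sum(rec$stage == "helper") +
                  1 / sum(rec$stage == "non-helper")))
  expect_lt(abs(ph - pu), 4 * se)
  # strongly negative beta: helpers win far less often
  set.seed(4)
  rec2 <- make_transition_records(true_beta = -3, n_records = 4000)
  expect_lt(mean(rec2$outcome[rec2$stage == "helper"]),
            mean(rec2$outcome[rec2$stage == "non-helper"]) / 2)
  expect_error(make_transition_records(0, n_records = 50), "at least 100")
})

test_that("masking hides exactly the requested share of subordinate rows", {
  set.seed(5)
  rec <- make_transition_records(true_beta = -0.5, n_records = 500)
  expect_identical(mask_status(rec, 0), rec)
  m <- mask_status(rec, 0.25)
  expect_equal(sum(is.na(m$stage)), round(0.25 * nrow(rec)))
  full <- mask_status(rec, 1)
  expect_true(all(is.na(full$stage)))
  # dominant rows are never masked
  mix <- data.frame(stage = c("d", "d", "helper", "u"), x = 1)
  mm <- mask_status(mix, 1)
  expect_equal(mm$stage[1:2], c("d", "d"))
  expect_true(all(is.na(mm$stage[3:4])))
  expect_error(mask_status(rec, 1.5), "fraction")
})

test_that("transition records survive a CSV round trip", {
  set.seed(6)
  rec <- make_transition_records(true_beta = -0.5, n_records = 200)
  tmp <- tempfile(fileext = ".csv")
  write_transition_records(rec, tmp)
  back <- read_transition_records(tmp)
  expect_equal(back, rec)
  # ... and still fit
  expect_s3_class(fit_beta(back), "lottery_fit")
  unlink(tmp)
})
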