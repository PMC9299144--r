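#' Create an individual-based population from a density state
#'
#' Rounds the (st)age densities of a \code{\link{population_state}} to whole
#' birds and lays them out as one row per individual.
#'
#' @param state A \code{\link{population_state}}.
#' @return Data frame with columns \code{id}, \code{age}, \code{stage}
#'   (\code{"d"}, \code{"h"}, \code{"u"}) and \code{mother_id} (NA for
#'   founders).
#' @export
ibm_from_state <- function(state) {
  stopifnot(inherits(state, "population_state"))
  rows <- list()
  add <- function(ages, counts, stage) {
    counts <- round(counts)
    keep <- counts > 0
    if (!any(keep)) return(NULL)
    data.frame(age = rep(ages[keep], counts[keep]), stage = stage,
               stringsAsFactors = FALSE)
  }
  pop <- rbind(add(state$age_dom, state$d, "d"),
               add(state$age_sub, state$h, "h"),
               add(state$age_sub, state$u, "u"))
  if (is.null(pop)) {
    pop <- data.frame(age = numeric(0), stage = character(0))
  }
  pop$id <- seq_len(nrow(pop))
  pop$mother_id <- NA_integer_
  pop[, c("id", "age", "stage", "mother_id")]
}

#' One step of the individual-based model
#'
#' Stochastic, discrete-bird counterpart of \code{\link{project_step}}:
#' survival is a Bernoulli draw per bird from its (st)age rate; the integer
#' number of vacant territories (capacity rounded to the nearest whole
#' territory minus surviving dominants) is filled by weighted sampling
#' without replacement among surviving subordinates with weights
#' \eqn{e^\beta} (helpers) and 1 (non-helpers); every dominant draws its
#' help status Bernoulli(\code{p_help}(age, r)) and reproduces
#' Bernoulli(\code{R_d}) accordingly, helpers reproduce
#' Bernoulli(\code{R_h}); and each newborn becomes a helper with probability
#' \code{f}(mother's age, N).  Reproduction uses the time-\emph{t}
#' population, matching the census timing of the density model.
#'
#' @param pop Individual table as from \code{\link{ibm_from_state}}.
#' @param model A \code{\link{smpm}}.
#' @param intercepts Seasonal intercept vector.
#' @param next_id First id to assign to newborns.
#' @return List with \code{pop} (the individuals alive at \emph{t} + 0.5,
#'   ages advanced with a recursive top class), \code{records} (one
#'   transition record per surviving subordinate: \code{stage}, \code{x},
#'   \code{nh}, \code{nu}, \code{outcome}), \code{events} (per-individual
#'   survival/reproduction flags for the step) and \code{next_id}.
#' @export
ibm_step <- function(pop, model, intercepts, next_id = max(c(0L, pop$id)) + 1L) {
  k <- model$kernel
  cfg <- model$config
  n <- nrow(pop)
  if (n == 0L) {
    return(list(pop = pop, records = NULL, events = NULL, next_id = next_id))
  }
  N_raw <- n
  n_dom <- sum(pop$stage == "d")
  r <- if (n_dom > 0) (n - n_dom) / n_dom else 0
  rates <- rate_profile_from_intercepts(k, intercepts, N = N_raw, r = r)
  sub_idx <- function(age) as.integer(round(age / k$age_step))
  dom_idx <- function(age) as.integer(round(age / k$age_step)) - 1L

  p_surv <- numeric(n)
  is_d <- pop$stage == "d"; is_h <- pop$stage == "h"; is_u <- pop$stage == "u"
  p_surv[is_d] <- rates$S_d[dom_idx(pop$age[is_d])]
  p_surv[is_h] <- rates$S_h[sub_idx(pop$age[is_h])]
  p_surv[is_u] <- rates$S_u[sub_idx(pop$age[is_u])]
  survived <- stats::runif(n) < p_surv

  # integer vacancies: whole territories cannot be fractionally occupied
  x <- max(0L, as.integer(round(cfg$termax)) - sum(survived & is_d))
  claimants <- which(survived & !is_d)
  promoted <- rep(FALSE, n)
  if (x > 0L && length(claimants) > 0L) {
    w <- ifelse(pop$stage[claimants] == "h", exp(cfg$beta), 1)
    take <- min(x, length(claimants))
    # sequential weighted draws without replacement; ties broken by the draw
    win <- if (length(claimants) == 1L) claimants else
      sample(claimants, take, prob = w)
    promoted[win] <- TRUE
  }

  # reproduction from the time-t population
  reproduced <- rep(FALSE, n)
  di <- which(is_d)
  if (length(di) > 0L) {
    ph <- rates$p_help[dom_idx(pop$age[di])]
    q <- stats::runif(length(di)) < ph
    pr <- ifelse(q, rates$R_d_q1[dom_idx(pop$age[di])],
                 rates$R_d_q0[dom_idx(pop$age[di])])
    reproduced[di] <- stats::runif(length(di)) < pr
  }
  hi <- which(is_h)
  if (length(hi) > 0L) {
    reproduced[hi] <- stats::runif(length(hi)) < rates$R_h[sub_idx(pop$age[hi])]
  }
  mothers <- which(reproduced)
  newborns <- NULL
  if (length(mothers) > 0L) {
    f_m <- logistic_rate(k$specs$f, intercepts[["f"]],
                         list(a = pop$age[mothers],
                              N = (N_raw - k$standardisation[["mean"]]) /
                                  k$standardisation[["sd"]]))
    helper_born <- stats::runif(length(mothers)) < f_m
    newborns <- data.frame(id = next_id + seq_along(mothers) - 1L,
                           age = k$age_step,
                           stage = ifelse(helper_born, "h", "u"),
                           mother_id = pop$id[mothers],
                           stringsAsFactors = FALSE)
    next_id <- next_id + length(mothers)
  }

  nh_s <- sum(survived & is_h)
  nu_s <- sum(survived & is_u)
  sub_surv <- which(survived & !is_d)
  records <- if (length(sub_surv) > 0L) {
    data.frame(stage = ifelse(pop$stage[sub_surv] == "h", "helper",
                              "non-helper"),
               x = x, nh = nh_s, nu = nu_s,
               outcome = as.integer(promoted[sub_surv]),
               id = pop$id[sub_surv],
               stringsAsFactors = FALSE)
  }
  events <- data.frame(id = pop$id, age = pop$age, stage = pop$stage,
                       alive = survived, reproduced = reproduced,
                       promoted = promoted, stringsAsFactors = FALSE)

  out <- pop[survived, , drop = FALSE]
  out$stage[promoted[survived]] <- "d"
  out$age <- pmin(out$age + k$age_step, k$age_max)
  out <- rbind(out, newborns)
  rownames(out) <- NULL
  list(pop = out, records = records, events = events, next_id = next_id)
}

#' Simulate the individual-based model
#'
#' Runs \code{\link{ibm_step}} for \code{n_steps} seasons with kernel
#' resampling, collecting per-season population tables, per-bird-season
#' records and realised per-individual lifetime reproductive success.
#' Unlike the density model, trajectories carry demographic stochasticity,
#' so individual LRS is typically zero-inflated and right-skewed.
#'
#' @param model A \code{\link{smpm}}.
#' @param n_steps Number of half-year steps.
#' @param init Initial individuals (default: rounded
#'   \code{\link{default_state}}).
#' @param seed Optional RNG seed.
#' @return Object of class \code{"ibm_sim"} with components \code{counts}
#'   (per-step totals by stage), \code{records} (lottery transition records
#'   with a \code{season} column, suitable for \code{\link{fit_beta}}),
#'   \code{history} (per-bird-season rows: season, id, age, stage, alive,
#'   reproduced, promoted) and \code{lrs} (data frame of realised offspring
#'   counts per individual, with a flag for individuals whose death was
#'   observed within the horizon).
#' @export
ibm_simulate <- function(model, n_steps, init = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- ibm_from_state(default_state(model))
  pop <- init
  next_id <- max(c(0L, pop$id)) + 1L
  counts <- data.frame(step = seq_len(n_steps), n = NA_real_, n_d = NA_real_,
                       n_h = NA_real_, n_u = NA_real_)
  recs <- vector("list", n_steps)
  hist <- vector("list", n_steps)
  offspring <- integer(0)       # indexed by id
  seen_dead <- integer(0)
  grow <- function(v, id) { if (id > length(v)) v[id] <- 0L; v }
  for (t in seq_len(n_steps)) {
    counts$n[t] <- nrow(pop)
    counts$n_d[t] <- sum(pop$stage == "d")
    counts$n_h[t] <- sum(pop$stage == "h")
    counts$n_u[t] <- sum(pop$stage == "u")
    if (nrow(pop) == 0L) break
    dr <- draw_season(model$kernel)
    st <- ibm_step(pop, model, dr$intercepts, next_id)
    if (!is.null(st$records)) {
      st$records$season <- dr$season
      st$records$step <- t
      recs[[t]] <- st$records
    }
    ev <- st$events
    ev$season <- dr$season
    ev$step <- t
    hist[[t]] <- ev
    rep_ids <- ev$id[ev$reproduced]
    for (id in rep_ids) {
      offspring <- grow(offspring, id)
      offspring[id] <- offspring[id] + 1L
    }
    dead <- ev$id[!ev$alive]
    seen_dead <- c(seen_dead, dead)
    pop <- st$pop
    next_id <- st$next_id
  }
  all_ids <- unique(unlist(lapply(hist, function(h) h$id)))
  offspring <- grow(offspring, max(c(1L, all_ids)))
  lrs <- data.frame(id = all_ids,
                    lrs = offspring[all_ids],
                    died = all_ids %in% seen_dead)
  lrs$lrs[is.na(lrs$lrs)] <- 0L
  structure(list(counts = counts,
                 records = do.call(rbind, recs[!vapply(recs, is.null, TRUE)]),
                 history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
                 lrs = lrs,
                 model = model),
            class = "ibm_sim")
}

#' @export
print.ibm_sim <- function(x, ...) {
  n <- nrow(x$counts)
  cat("<ibm_sim> ", n, " steps; final N = ",
      x$counts$n[max(which(!is.na(x$counts$n)))], "\n", sep = "")
  cat("  ", nrow(x$lrs), " individuals tracked; ",
      sum(x$lrs$died), " complete lifetimes; ",
      sprintf("%.0f%% of complete lifetimes with LRS = 0\n",
              100 * mean(x$lrs$lrs[x$lrs$died] == 0)), sep = "")
  invisible(x)
}

#' Posterior-predictive-style check via artificial datasets
#'
#' Generates an ensemble of artificial datasets from the individual-based
#' model, one per parameter draw, randomly masks a fraction of the
#' observation rows (mimicking subordinates lacking behavioural
#' classification), and tabulates summary metrics of each dataset
#' (population size, subordinate counts, zero fraction and skew of
#' individual LRS).  When reference metrics are supplied the summary states
#' whether they are bracketed by the ensemble.
#'
#' @param model A \code{\link{smpm}} carrying the baseline configuration.
#' @param parameter_draws List of \code{\link{smpm_kernel}} objects (e.g.
#'   posterior draws, or replicate synthetic kernels); datasets cycle
#'   through them.
#' @param n_datasets Number of artificial datasets.
#' @param n_steps Seasons per dataset.
#' @param mask_fraction Fraction of per-bird-season rows whose stage label
#'   is hidden before summarising (default 0.1).
#' @param init Initial individuals.
#' @param seed Optional RNG seed.
#' @param observed Optional named list of reference metrics
#'   (\code{N}, \code{n_sub}) to compare against.
#' @return Object of class \code{"ppc"} with \code{summaries} (one row per
#'   dataset: mean N, mean subordinate count, LRS mean, zero fraction,
#'   skewness) and \code{observed}.
#' @export
posterior_predictive_check <- function(model, parameter_draws,
                                       n_datasets = length(parameter_draws),
                                       n_steps = 80, mask_fraction = 0.1,
                                       init = NULL, seed = NULL,
                                       observed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(parameter_draws) >= 1L)
  rows <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    kk <- parameter_draws[[((i - 1L) %% length(parameter_draws)) + 1L]]
    mm <- smpm(kk, model$config)
    sim <- ibm_simulate(mm, n_steps = n_steps, init = init)
    hist <- sim$history
    hist <- mask_status(hist, mask_fraction)
    n_sub_obs <- tapply(is.na(hist$stage) | hist$stage != "d", hist$step, sum)
    complete <- sim$lrs[sim$lrs$died, , drop = FALSE]
    lrs <- complete$lrs
    sk <- if (length(lrs) > 2 && stats::sd(lrs) > 0) {
      mean((lrs - mean(lrs))^3) / stats::sd(lrs)^3
    } else NA_real_
    rows[[i]] <- data.frame(
      dataset = i,
      mean_N = mean(sim$counts$n, na.rm = TRUE),
      mean_sub = mean(sim$counts$n_h + sim$counts$n_u, na.rm = TRUE),
      mean_sub_observed = mean(n_sub_obs),
      lrs_mean = if (length(lrs)) mean(lrs) else NA_real_,
      lrs_zero_fraction = if (length(lrs)) mean(lrs == 0) else NA_real_,
      lrs_skew = sk)
  }
  structure(list(summaries = do.call(rbind, rows), observed = observed,
                 mask_fraction = mask_fraction),
            class = "ppc")
}

#' @export
print.ppc <- function(x, ...) {
  s <- x$summaries
  cat("Posterior-predictive-style check over", nrow(s), "artificial datasets",
      sprintf("(%.0f%% of rows masked)\n", 100 * x$mask_fraction))
  for (m in c("mean_N", "mean_sub", "lrs_mean", "lrs_zero_fraction")) {
    qs <- stats::quantile(s[[m]], c(0.05, 0.5, 0.95), na.rm = TRUE)
    cat(sprintf("  %-18s median %.2f  [90%% band %.2f, %.2f]",
                m, qs[2], qs[1], qs[3]))
    if (!is.null(x$observed[[m]])) {
      inside <- x$observed[[m]] >= qs[1] && x$observed[[m]] <= qs[3]
      cat(sprintf("  observed %.2f %s", x$observed[[m]],
                  if (inside) "(bracketed)" else "(outside)"))
    }
    cat("\n")
  }
  invisible(x)
}
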