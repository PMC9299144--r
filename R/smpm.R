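#' Population state by stage and age
#'
#' Densities of dominants (\code{d}, ages 1.0 to \code{age_max}), helpers
#' (\code{h}) and non-helpers (\code{u}) (both ages 0.5 to \code{age_max})
#' on the half-year grid.  Offspring enter the population at age 0.5 as
#' helpers or non-helpers only; dominants therefore have no 0.5-year class.
#' Densities are continuous expected values; the individual-based
#' counterpart (see \code{\link{ibm_simulate}}) uses integer birds.
#'
#' @param d,h,u Non-negative density vectors (lengths must match the grids:
#'   29 dominant and 30 subordinate classes for the default 15-year grid).
#' @param age_max,age_step Age grid (years).
#' @return Object of class \code{"population_state"}.
#' @export
population_state <- function(d, h, u, age_max = 15, age_step = 0.5) {
  age_sub <- seq(age_step, age_max, by = age_step)
  age_dom <- seq(2 * age_step, age_max, by = age_step)
  if (length(d) != length(age_dom) || length(h) != length(age_sub) ||
      length(u) != length(age_sub)) {
    stop("state lengths must match the age grids (",
         length(age_dom), " dominant / ", length(age_sub),
         " subordinate classes)", call. = FALSE)
  }
  if (any(!is.finite(c(d, h, u))) || any(c(d, h, u) < 0)) {
    stop("densities must be finite and non-negative", call. = FALSE)
  }
  structure(list(d = as.numeric(d), h = as.numeric(h), u = as.numeric(u),
                 age_sub = age_sub, age_dom = age_dom),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> N =", format(sum(x$d) + sum(x$h) + sum(x$u)),
      "( d:", format(sum(x$d)), " h:", format(sum(x$h)),
      " u:", format(sum(x$u)), ")\n")
  invisible(x)
}

# Flatten a state to the [d, h, u] vector used by the projection matrix.
state_to_vector <- function(state) c(state$d, state$h, state$u)

vector_to_state <- function(v, age_max = 15, age_step = 0.5) {
  nd <- length(seq(2 * age_step, age_max, by = age_step))
  ns <- length(seq(age_step, age_max, by = age_step))
  population_state(v[seq_len(nd)], v[nd + seq_len(ns)], v[nd + ns + seq_len(ns)],
                   age_max = age_max, age_step = age_step)
}

#' Construct a stochastic matrix population model
#'
#' Binds a seasonal parameter kernel to a structural configuration
#' (capacity, lottery contrast, horizon).  The resulting object is the
#' package's central model class: \code{\link{simulate.smpm}} projects it,
#' \code{\link{project_step}} advances a single census step,
#' \code{\link{track_cohort}}, \code{\link{reproductive_values}},
#' \code{\link{ltre_random_design}} and \code{\link{elasticity}} interrogate
#' it.
#'
#' @param kernel A \code{\link{smpm_kernel}}.
#' @param config A \code{\link{smpm_config}}.
#' @return Object of class \code{"smpm"}.
#' @examples
#' mod <- smpm(make_kernel(synthetic_kernel_spec(seed = 1)),
#'             smpm_config(horizon = 500, burn_in = 200))
#' sim <- simulate(mod, seed = 1)
#' summary(sim)
#' @export
smpm <- function(kernel, config = smpm_config()) {
  stopifnot(inherits(kernel, "smpm_kernel"), inherits(config, "smpm_config"))
  if (kernel$age_max != config$age_max || kernel$age_step != config$age_step) {
    stop("kernel and config age grids disagree", call. = FALSE)
  }
  structure(list(kernel = kernel, config = config), class = "smpm")
}

#' @export
print.smpm <- function(x, ...) {
  cat("Stochastic (st)age-structured matrix population model\n")
  cat("  ", length(x$kernel$seasons), " seasons in kernel; termax ",
      x$config$termax, "; lottery beta ", x$config$beta, "\n", sep = "")
  cat("  horizon ", x$config$horizon, " half-year steps (burn-in ",
      x$config$burn_in, ")\n", sep = "")
  invisible(x)
}

#' Default initial state
#'
#' Uniform small densities across all (st)age classes; the burn-in removes
#' initialisation effects before any stationary summary is computed.
#'
#' @param model A \code{\link{smpm}}.
#' @param density Density per class.
#' @return A \code{\link{population_state}}.
#' @export
default_state <- function(model, density = 2) {
  k <- model$kernel
  population_state(rep(density, length(k$age_dom)),
                   rep(density, length(k$age_sub)),
                   rep(density, length(k$age_sub)),
                   age_max = k$age_max, age_step = k$age_step)
}

# Transition-only part of the projection (survival, ageing, promotion) plus
# the per-class expected-offspring rewards and newborn-split probabilities.
# Column order: dominants (ages 1..m), helpers, non-helpers.
transition_parts <- function(rates, g, n_dom, n_sub) {
  n <- n_dom + 2L * n_sub
  U <- matrix(0, n, n)
  i_d <- seq_len(n_dom)
  i_h <- n_dom + seq_len(n_sub)
  i_u <- n_dom + n_sub + seq_len(n_sub)
  # dominants survive and age (recursive top class)
  dd <- cbind(i_d[pmin(seq_len(n_dom) + 1L, n_dom)], i_d)
  U[dd] <- U[dd] + rates$S_d
  # subordinates: promotion into the dominant vector aged by half a year,
  # or ageing within stage
  dom_dest <- i_d[pmin(seq_len(n_sub), n_dom)]
  hp <- cbind(dom_dest, i_h)
  U[hp] <- U[hp] + g[["g_h"]] * rates$S_h
  hs <- cbind(i_h[pmin(seq_len(n_sub) + 1L, n_sub)], i_h)
  U[hs] <- U[hs] + (1 - g[["g_h"]]) * rates$S_h
  up <- cbind(dom_dest, i_u)
  U[up] <- U[up] + g[["g_u"]] * rates$S_u
  us <- cbind(i_u[pmin(seq_len(n_sub) + 1L, n_sub)], i_u)
  U[us] <- U[us] + (1 - g[["g_u"]]) * rates$S_u
  Rmix <- rates$p_help * rates$R_d_q1 + (1 - rates$p_help) * rates$R_d_q0
  rewards <- c(Rmix, rates$R_h, rep(0, n_sub))
  f_split <- c(rates$f_dom, rates$f_sub, rep(0, n_sub))
  labels <- c(sprintf("d_%g", seq(1, by = 0.5, length.out = n_dom)),
              sprintf("h_%g", seq(0.5, by = 0.5, length.out = n_sub)),
              sprintf("u_%g", seq(0.5, by = 0.5, length.out = n_sub)))
  list(U = U, rewards = rewards, f_split = f_split, labels = labels,
       i_d = i_d, i_h = i_h, i_u = i_u)
}

# Assemble the realized projection matrix K_t = transitions + reproduction.
build_projection_matrix <- function(rates, g, n_dom, n_sub) {
  tp <- transition_parts(rates, g, n_dom, n_sub)
  K <- tp$U
  K[tp$i_h[1L], ] <- K[tp$i_h[1L], ] + tp$f_split * tp$rewards
  K[tp$i_u[1L], ] <- K[tp$i_u[1L], ] + (1 - tp$f_split) * tp$rewards
  K
}

# One projection step given an intercept vector.  Returns the new state plus
# step diagnostics (and the realized K if requested).
.step <- function(model, state, intercepts, build_K = FALSE) {
  k <- model$kernel
  cfg <- model$config
  N_raw <- sum(state$d) + sum(state$h) + sum(state$u)
  sum_d <- sum(state$d)
  r <- if (sum_d > 0) (sum(state$h) + sum(state$u)) / sum_d else 0
  rates <- rate_profile_from_intercepts(k, intercepts, N = N_raw, r = r)
  for (nm in c("S_d", "S_h", "S_u", "R_d_q0", "R_d_q1", "R_h",
               "f_sub", "f_dom", "p_help")) {
    if (anyNA(rates[[nm]])) {
      stop("NaN rate in function '", nm, "'", call. = FALSE)
    }
  }
  surv_d <- rates$S_d * state$d
  x <- vacancy_count(cfg$termax, surv_d)
  nh <- sum(rates$S_h * state$h)
  nu <- sum(rates$S_u * state$u)
  g <- transition_probs(x, nh, nu, cfg$beta)
  n_dom <- length(k$age_dom)
  n_sub <- length(k$age_sub)
  K <- build_projection_matrix(rates, g, n_dom, n_sub)
  v_new <- as.numeric(K %*% state_to_vector(state))
  if (any(v_new < 0)) {
    stop("internal error: negative density produced by projection step",
         call. = FALSE)
  }
  new_state <- vector_to_state(v_new, age_max = k$age_max,
                               age_step = k$age_step)
  list(state = new_state, x = x, g = g, N = N_raw, r = r,
       nh = nh, nu = nu, rates = rates, K = if (build_K) K else NULL)
}

#' Advance the population by one half-year census step
#'
#' Applies, in order: (st)age-specific survival; opening of vacancies where
#' dominants died; the weighted lottery promoting surviving subordinates
#' into the dominant vector aged by half a year; ageing within stage with a
#' recursive top age class; and reproduction from the time-\emph{t} counts,
#' with dominant reproduction mixing the with-help and without-help rates by
#' the help probability and newborns recruiting as helpers with probability
#' \code{f}(mother's age, N).  Covariates (N, r) are computed from the
#' time-\emph{t} census.
#'
#' @param model A \code{\link{smpm}}.
#' @param state A \code{\link{population_state}} at time \emph{t}.
#' @param intercepts Named intercept vector over the six seasonal channels
#'   (e.g. one row of the kernel, or \code{draw_season(kernel)$intercepts}).
#' @param details If \code{TRUE}, return a list with the new state plus the
#'   step diagnostics (vacancies \code{x}, lottery probabilities \code{g},
#'   covariates, rate profile and realized projection matrix \code{K}).
#' @return The \code{\link{population_state}} at time \emph{t} + 0.5, or the
#'   detail list.
#' @export
project_step <- function(model, state, intercepts, details = FALSE) {
  stopifnot(inherits(model, "smpm"), inherits(state, "population_state"))
  res <- .step(model, state, intercepts, build_K = details)
  if (details) res else res$state
}

#' Simulate the stochastic projection model
#'
#' Iterates \code{\link{project_step}} for \code{horizon} half-year steps,
#' drawing a whole season's intercept vector from the kernel at every step
#' (kernel resampling).  Returns the per-step trajectory, the post-burn-in
#' state ensemble used for stationary summaries, and the running mean of the
#' realized projection matrices (basis of the reproductive-value
#' calculation).
#'
#' @param object A \code{\link{smpm}}.
#' @param nsim Number of independent replicate simulations.
#' @param seed Optional RNG seed.
#' @param init Initial \code{\link{population_state}}; defaults to
#'   \code{\link{default_state}}.
#' @param keep_K Accumulate mean realized projection matrices (needed by
#'   \code{\link{reproductive_values}}); disable for speed in perturbation
#'   loops.
#' @param n_chunks Number of post-burn-in chunks over which chunk-mean
#'   projection matrices are kept (for interquartile bands of derived
#'   quantities).
#' @param ... Unused.
#' @return An object of class \code{"smpm_sim"} (or a list of them when
#'   \code{nsim > 1}) with components \code{trajectory} (data frame: one row
#'   per step with season, stage totals, ratio, vacancies, lottery
#'   probabilities and the drawn intercepts), \code{ensemble} (matrix of
#'   post-burn-in census states), \code{mean_K}, \code{chunk_K},
#'   \code{N_hat} (stochastic mean population size) and \code{extinct_at}.
#' @export
simulate.smpm <- function(object, nsim = 1, seed = NULL, init = NULL,
                          keep_K = TRUE, n_chunks = 20, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (nsim > 1) {
    return(lapply(seq_len(nsim), function(i) {
      simulate.smpm(object, nsim = 1, init = init, keep_K = keep_K,
                    n_chunks = n_chunks)
    }))
  }
  k <- object$kernel
  cfg <- object$config
  if (is.null(init)) init <- default_state(object)
  horizon <- cfg$horizon
  burn_in <- cfg$burn_in
  n_dom <- length(k$age_dom)
  n_sub <- length(k$age_sub)
  dim_n <- n_dom + 2L * n_sub

  season <- character(horizon)
  ics <- matrix(NA_real_, horizon, length(.kernel_channels),
                dimnames = list(NULL, .kernel_channels))
  N <- n_d <- n_h <- n_u <- ratio <- x_t <- g_h <- g_u <- N_next <-
    numeric(horizon)
  n_post <- horizon - burn_in
  ensemble <- matrix(NA_real_, n_post, dim_n)
  mean_K <- if (keep_K) matrix(0, dim_n, dim_n) else NULL
  chunk_K <- if (keep_K) array(0, c(n_chunks, dim_n, dim_n)) else NULL
  chunk_n <- integer(n_chunks)
  chunk_of <- function(i_post) {
    pmin(n_chunks, 1L + ((i_post - 1L) * n_chunks) %/% n_post)
  }

  state <- init
  extinct_at <- NA_integer_
  n_K <- 0L
  for (t in seq_len(horizon)) {
    dr <- draw_season(k)
    res <- .step(object, state, dr$intercepts,
                 build_K = keep_K && t > burn_in)
    season[t] <- dr$season
    ics[t, ] <- dr$intercepts[.kernel_channels]
    N[t] <- res$N
    n_d[t] <- sum(state$d); n_h[t] <- sum(state$h); n_u[t] <- sum(state$u)
    ratio[t] <- res$r
    x_t[t] <- res$x
    g_h[t] <- res$g[["g_h"]]; g_u[t] <- res$g[["g_u"]]
    state <- res$state
    N_next[t] <- sum(state$d) + sum(state$h) + sum(state$u)
    if (t > burn_in) {
      i_post <- t - burn_in
      ensemble[i_post, ] <- state_to_vector(state)
      if (keep_K) {
        mean_K <- mean_K + res$K
        ck <- chunk_of(i_post)
        chunk_K[ck, , ] <- chunk_K[ck, , ] + res$K
        chunk_n[ck] <- chunk_n[ck] + 1L
        n_K <- n_K + 1L
      }
    }
    if (N_next[t] < 1e-8) {
      extinct_at <- t
      warning("population extinct at step ", t, "; trajectory truncated")
      break
    }
  }
  keep <- if (is.na(extinct_at)) seq_len(horizon) else seq_len(extinct_at)
  traj <- data.frame(step = keep, season = season[keep], N = N[keep],
                     n_d = n_d[keep], n_h = n_h[keep], n_u = n_u[keep],
                     ratio = ratio[keep], x = x_t[keep],
                     g_h = g_h[keep], g_u = g_u[keep],
                     N_next = N_next[keep], stringsAsFactors = FALSE)
  traj <- cbind(traj, as.data.frame(ics[keep, , drop = FALSE]))
  if (keep_K && n_K > 0L) {
    mean_K <- mean_K / n_K
    for (ck in seq_len(n_chunks)) {
      if (chunk_n[ck] > 0L) chunk_K[ck, , ] <- chunk_K[ck, , ] / chunk_n[ck]
    }
  }
  post <- traj$step > burn_in
  structure(list(
    trajectory = traj,
    ensemble = ensemble[stats::complete.cases(ensemble), , drop = FALSE],
    mean_K = mean_K,
    chunk_K = chunk_K,
    chunk_n = chunk_n,
    N_hat = mean(traj$N_next[post]),
    final_state = state,
    extinct_at = extinct_at,
    model = object
  ), class = "smpm_sim")
}

#' @export
print.smpm_sim <- function(x, ...) {
  cat("<smpm_sim> ", nrow(x$trajectory), " steps; N_hat = ",
      format(x$N_hat), "\n", sep = "")
  invisible(x)
}

#' @export
summary.smpm_sim <- function(object, ...) {
  cfg <- object$model$config
  post <- object$trajectory[object$trajectory$step > cfg$burn_in, ]
  out <- list(
    N_hat = object$N_hat,
    stages = rbind(
      mean = c(d = mean(post$n_d), h = mean(post$n_h), u = mean(post$n_u)),
      sd = c(d = stats::sd(post$n_d), h = stats::sd(post$n_h),
             u = stats::sd(post$n_u))),
    ratio = c(mean = mean(post$ratio), sd = stats::sd(post$ratio)),
    vacancies = c(mean = mean(post$x), sd = stats::sd(post$x)),
    steps = nrow(object$trajectory),
    extinct_at = object$extinct_at)
  class(out) <- "summary.smpm_sim"
  out
}

#' @export
print.summary.smpm_sim <- function(x, ...) {
  cat("Stationary summary over", x$steps, "steps (post burn-in)\n")
  cat(sprintf("  N_hat = %.2f\n", x$N_hat))
  print(round(x$stages, 2))
  cat(sprintf("  subordinate:dominant ratio %.3f (sd %.3f)\n",
              x$ratio[["mean"]], x$ratio[["sd"]]))
  cat(sprintf("  vacancies per step %.2f (sd %.2f)\n",
              x$vacancies[["mean"]], x$vacancies[["sd"]]))
  if (!is.na(x$extinct_at)) cat("  population extinct at step", x$extinct_at, "\n")
  invisible(x)
}

#' @export
plot.smpm_sim <- function(x, which = c("totals", "ratio"), ...) {
  which <- match.arg(which)
  tr <- x$trajectory
  if (which == "totals") {
    graphics::matplot(tr$step, cbind(tr$N, tr$n_d, tr$n_h, tr$n_u),
                      type = "l", lty = 1,
                      col = c("black", "purple", "orange", "darkgreen"),
                      xlab = "half-year step", ylab = "females", ...)
    graphics::legend("topleft", c("total", "dominants", "helpers",
                                  "non-helpers"),
                     col = c("black", "purple", "orange", "darkgreen"),
                     lty = 1, bty = "n")
  } else {
    graphics::plot(tr$step, tr$ratio, type = "l",
                   xlab = "half-year step",
                   ylab = "subordinates per dominant", ...)
  }
  invisible(x)
}

#' Deterministic fixed point of the projection
#'
#' Iterates \code{\link{project_step}} with a fixed intercept vector until
#' the state stops changing.  With a one-season (deterministic) kernel the
#' stochastic simulation converges to this fixed point, which also supplies
#' the frozen environment for the Markov-reward lifetime reproductive
#' success calculation.
#'
#' @param model A \code{\link{smpm}}.
#' @param intercepts Intercept vector; defaults to the kernel's first season.
#' @param init Initial state.
#' @param tol Convergence tolerance on the max absolute density change.
#' @param max_iter Iteration cap.
#' @return List with \code{state} (the fixed point), \code{x}, \code{g},
#'   \code{rates}, \code{N}, \code{r}, \code{iterations} and
#'   \code{converged}.
#' @export
equilibrium <- function(model, intercepts = model$kernel$intercepts[1L, ],
                        init = NULL, tol = 1e-10, max_iter = 10000) {
  if (is.null(init)) init <- default_state(model)
  state <- init
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    res <- .step(model, state, intercepts)
    delta <- max(abs(state_to_vector(res$state) - state_to_vector(state)))
    state <- res$state
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("fixed-point iteration did not converge in ",
                          max_iter, " steps (last delta ", signif(delta, 3), ")")
  res <- .step(model, state, intercepts)
  list(state = state, x = res$x, g = res$g, rates = res$rates, N = res$N,
       r = res$r, iterations = it, converged = converged)
}

#' Stationary (st)age distributions
#'
#' Normalised age distributions per stage at stochastic quasi-equilibrium,
#' with interquartile bands taken across the post-burn-in census steps.
#'
#' @param sim A \code{"smpm_sim"} from \code{\link{simulate.smpm}}.
#' @return Object of class \code{"stage_age_distribution"}: a named list of
#'   data frames (\code{dominant}, \code{helper}, \code{nonhelper}) with
#'   columns \code{age}, \code{mean}, \code{q25}, \code{q75}; the
#'   \code{mean} column of each stage sums to 1.
#' @export
stage_age_distribution <- function(sim) {
  stopifnot(inherits(sim, "smpm_sim"))
  k <- sim$model$kernel
  n_dom <- length(k$age_dom)
  n_sub <- length(k$age_sub)
  idx <- list(dominant = seq_len(n_dom),
              helper = n_dom + seq_len(n_sub),
              nonhelper = n_dom + n_sub + seq_len(n_sub))
  ages <- list(dominant = k$age_dom, helper = k$age_sub,
               nonhelper = k$age_sub)
  out <- lapply(names(idx), function(st) {
    m <- sim$ensemble[, idx[[st]], drop = FALSE]
    tot <- rowSums(m)
    ok <- tot > 0
    norm <- m[ok, , drop = FALSE] / tot[ok]
    data.frame(age = ages[[st]],
               mean = colMeans(norm),
               q25 = apply(norm, 2, stats::quantile, 0.25),
               q75 = apply(norm, 2, stats::quantile, 0.75),
               row.names = NULL)
  })
  names(out) <- names(idx)
  # renormalise the mean so each stage's distribution sums to exactly 1
  for (st in names(out)) out[[st]]$mean <- out[[st]]$mean / sum(out[[st]]$mean)
  structure(out, class = "stage_age_distribution")
}

#' @export
print.stage_age_distribution <- function(x, ...) {
  for (st in names(x)) {
    young <- sum(x[[st]]$mean[x[[st]]$age < 2])
    cat(sprintf("%-10s mean age %.2f yr; mass below 2 yr: %.1f%%\n",
                st, sum(x[[st]]$age * x[[st]]$mean), 100 * young))
  }
  invisible(x)
}
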