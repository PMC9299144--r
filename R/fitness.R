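#' Cohort-based lifetime reproductive success
#'
#' Follows cohorts of helpers or non-helpers through a stochastic resident
#' environment.  The resident population is first burnt in, then each cohort
#' starts as a unit mass at age 0.5 in its stage and is projected with the
#' per-step rates the resident environment generates (including
#' lottery promotion to dominance and subsequent dominant reproduction),
#' accumulating expected offspring until the cohort is extinct.  Cohorts
#' experience a shared resident environment within a replicate; fresh
#' seasonal draws are used across replicates, so the spread of cohort LRS
#' reflects environmental stochasticity only (never zero-inflation, which
#' requires individual-level demographic stochasticity; see
#' \code{\link{ibm_simulate}}).
#'
#' @param model A \code{\link{smpm}}.
#' @param start_stage \code{"helper"} or \code{"nonhelper"}.
#' @param n_cohorts Number of replicate cohorts (default 100).
#' @param init Initial resident state; defaults to
#'   \code{\link{default_state}}.
#' @param burn_in Resident burn-in steps before the first cohort starts;
#'   defaults to the model configuration.
#' @param max_steps Cap on cohort lifespan in steps; if the cohort mass has
#'   not fallen below \code{tol} by then, accumulation is truncated with a
#'   warning.
#' @param tol Cohort-extinction threshold on surviving mass.
#' @param seed Optional RNG seed.
#' @return Object of class \code{"cohort_lrs"} with components \code{lrs}
#'   (numeric, one expected LRS per cohort), \code{median},
#'   \code{iqr} (25\% and 75\% quantiles), \code{start_stage} and
#'   \code{series} (per-step survivorship, stage occupancy and accrued
#'   offspring for the first cohort).
#' @export
track_cohort <- function(model, start_stage = c("helper", "nonhelper"),
                         n_cohorts = 100, init = NULL,
                         burn_in = model$config$burn_in,
                         max_steps = 400, tol = 1e-10, seed = NULL) {
  start_stage <- match.arg(start_stage)
  if (!is.null(seed)) set.seed(seed)
  k <- model$kernel
  n_dom <- length(k$age_dom)
  n_sub <- length(k$age_sub)
  if (is.null(init)) init <- default_state(model)

  state <- init
  for (t in seq_len(burn_in)) {
    state <- .step(model, state, draw_season(k)$intercepts)$state
  }

  lrs <- numeric(n_cohorts)
  series <- NULL
  for (ci in seq_len(n_cohorts)) {
    res_state <- state
    cd <- rep(0, n_dom); ch <- rep(0, n_sub); cu <- rep(0, n_sub)
    if (start_stage == "helper") ch[1L] <- 1 else cu[1L] <- 1
    acc <- 0
    rec <- if (ci == 1L) {
      data.frame(step = integer(0), l = numeric(0), occ_d = numeric(0),
                 occ_h = numeric(0), occ_u = numeric(0), lrs = numeric(0))
    }
    extinct <- FALSE
    for (t in seq_len(max_steps)) {
      res <- .step(model, res_state, draw_season(k)$intercepts)
      rates <- res$rates
      g <- res$g
      # reward accrual from the time-t cohort occupancy
      Rmix <- rates$p_help * rates$R_d_q1 + (1 - rates$p_help) * rates$R_d_q0
      acc <- acc + sum(Rmix * cd) + sum(rates$R_h * ch)
      if (ci == 1L) {
        rec <- rbind(rec, data.frame(step = t, l = sum(cd) + sum(ch) + sum(cu),
                                     occ_d = sum(cd), occ_h = sum(ch),
                                     occ_u = sum(cu), lrs = acc))
      }
      # cohort transition with the resident environment's realized rates
      tp <- transition_parts(rates, g, n_dom, n_sub)
      cvec <- as.numeric(tp$U %*% c(cd, ch, cu))
      cd <- cvec[tp$i_d]; ch <- cvec[tp$i_h]; cu <- cvec[tp$i_u]
      res_state <- res$state
      if (sum(cvec) < tol) { extinct <- TRUE; break }
    }
    if (!extinct) {
      warning("cohort ", ci, " not extinct after ", max_steps,
              " steps (remaining mass ", signif(sum(cd) + sum(ch) + sum(cu), 3),
              "); LRS truncated")
    }
    lrs[ci] <- acc
    if (ci == 1L) series <- rec
  }
  structure(list(lrs = lrs,
                 median = stats::median(lrs),
                 iqr = stats::quantile(lrs, c(0.25, 0.75)),
                 start_stage = start_stage,
                 series = series),
            class = "cohort_lrs")
}

#' @export
print.cohort_lrs <- function(x, ...) {
  cat(sprintf("Cohort LRS (%s): median %.3f [IQR %.3f, %.3f] over %d cohorts\n",
              x$start_stage, x$median, x$iqr[[1L]], x$iqr[[2L]],
              length(x$lrs)))
  invisible(x)
}

#' Absorbing Markov chain with Bernoulli reproduction rewards
#'
#' A transient transition matrix \code{U} (column \emph{j} holds the
#' probabilities of moving from (st)age class \emph{j} to each class; column
#' sums below 1, the deficit being mortality) together with the per-class
#' probability of producing one offspring while occupying the class.
#' Because the per-step reward is Bernoulli, all its raw moments equal the
#' success probability.
#'
#' @param U Square transient transition matrix (column-substochastic).
#' @param rewards Per-class reproduction probabilities in [0, 1].
#' @param labels Optional class labels.
#' @return Object of class \code{"reward_chain"}.
#' @seealso \code{\link{reward_chain_from_equilibrium}},
#'   \code{\link{lrs_moments}}.
#' @export
reward_chain <- function(U, rewards, labels = NULL) {
  U <- as.matrix(U)
  stopifnot(nrow(U) == ncol(U), length(rewards) == nrow(U),
            all(rewards >= 0 & rewards <= 1), all(U >= 0))
  if (any(colSums(U) > 1 + 1e-9)) {
    stop("columns of U must sum to at most 1", call. = FALSE)
  }
  if (is.null(labels)) labels <- as.character(seq_len(nrow(U)))
  structure(list(U = U, rewards = as.numeric(rewards), labels = labels),
            class = "reward_chain")
}

#' Build the reward chain from a frozen environment
#'
#' Freezes the density-dependent covariates and the lottery at an
#' equilibrium (or any reference state) of the projection model and returns
#' the corresponding absorbing chain over all (st)age classes, with
#' reproduction probabilities as rewards.
#'
#' @param model A \code{\link{smpm}}.
#' @param eq Output of \code{\link{equilibrium}}, or a list with elements
#'   \code{state} and \code{intercepts}.
#' @param intercepts Intercept vector when \code{eq} carries only a state.
#' @return A \code{\link{reward_chain}}.
#' @export
reward_chain_from_equilibrium <- function(model, eq, intercepts = NULL) {
  state <- eq$state
  if (is.null(intercepts)) {
    intercepts <- eq$intercepts %||% model$kernel$intercepts[1L, ]
  }
  res <- .step(model, state, intercepts)
  k <- model$kernel
  tp <- transition_parts(res$rates, res$g, length(k$age_dom),
                         length(k$age_sub))
  reward_chain(tp$U, tp$rewards, tp$labels)
}

#' Moments of lifetime reproductive success by starting class
#'
#' Implements the moment recursions for rewards accumulated on an absorbing
#' Markov chain.  Writing \eqn{\rho_k} for the vector of \emph{k}-th moments
#' of future accumulated reward by current class, and using that every raw
#' moment of a Bernoulli(\emph{p}) per-step reward equals \emph{p}:
#' \deqn{\rho_1 = (I - U^T)^{-1} p}
#' \deqn{\rho_2 = (I - U^T)^{-1} (p + 2 p \circ U^T \rho_1)}
#' \deqn{\rho_3 = (I - U^T)^{-1} (p + 3 p \circ U^T \rho_1 +
#'   3 p \circ U^T \rho_2)}
#' from which the variance, coefficient of variation and skewness follow.
#'
#' @param chain A \code{\link{reward_chain}}.
#' @return Data frame with one row per class: \code{class}, \code{mean},
#'   \code{var}, \code{cv}, \code{skew}.
#' @examples
#' # one transient state, survival 0.8, reproduction 0.4:
#' lrs_moments(reward_chain(matrix(0.8), 0.4))  # mean = 0.4/0.2 = 2
#' @export
lrs_moments <- function(chain) {
  stopifnot(inherits(chain, "reward_chain"))
  U <- chain$U
  p <- chain$rewards
  sr <- max(Mod(eigen(U, only.values = TRUE)$values))
  if (sr >= 1) {
    stop("spectral radius of U is ", signif(sr, 6),
         " >= 1: the chain is immortal and LRS diverges", call. = FALSE)
  }
  n <- nrow(U)
  A <- diag(n) - t(U)
  rho1 <- solve(A, p)
  rho2 <- solve(A, p + 2 * p * as.numeric(t(U) %*% rho1))
  rho3 <- solve(A, p + 3 * p * as.numeric(t(U) %*% rho1) +
                     3 * p * as.numeric(t(U) %*% rho2))
  v <- rho2 - rho1^2
  v[v < 0 & v > -1e-12] <- 0
  skew <- ifelse(v > 0, (rho3 - 3 * rho1 * rho2 + 2 * rho1^3) / v^1.5, NA_real_)
  data.frame(class = chain$labels, mean = rho1, var = v,
             cv = ifelse(rho1 > 0, sqrt(v) / rho1, NA_real_),
             skew = skew, row.names = NULL)
}

#' Simulate individual lifetimes on a reward chain
#'
#' Monte-Carlo counterpart of \code{\link{lrs_moments}}: draws individual
#' trajectories through the chain, each census accruing a Bernoulli
#' offspring with the occupied class's reward probability, until
#' absorption (death).  Used as an independent cross-check of the moment
#' recursions; unlike the cohort calculation, these individual LRS values
#' carry demographic stochasticity and are typically zero-inflated.
#'
#' @param chain A \code{\link{reward_chain}}.
#' @param start Starting class index.
#' @param n Number of lifetimes.
#' @param max_steps Safety cap per lifetime.
#' @return Integer vector of realised LRS values.
#' @export
simulate_lifetimes <- function(chain, start = 1L, n = 1000L,
                               max_steps = 10000L) {
  U <- chain$U
  p <- chain$rewards
  k <- nrow(U)
  surv <- colSums(U)
  # conditional destination distributions per class
  dest <- lapply(seq_len(k), function(j) {
    if (surv[j] > 0) U[, j] / surv[j] else rep(0, k)
  })
  lrs <- integer(n)
  state <- rep.int(start, n)
  alive <- rep(TRUE, n)
  for (t in seq_len(max_steps)) {
    idx <- which(alive)
    if (length(idx) == 0L) break
    s <- state[idx]
    lrs[idx] <- lrs[idx] + (stats::runif(length(idx)) < p[s])
    die <- stats::runif(length(idx)) > surv[s]
    alive[idx[die]] <- FALSE
    idx <- idx[!die]
    if (length(idx) == 0L) next
    # advance survivors class by class
    for (j in unique(state[idx])) {
      jj <- idx[state[idx] == j]
      state[jj] <- sample.int(k, length(jj), replace = TRUE, prob = dest[[j]])
    }
  }
  if (any(alive)) warning(sum(alive), " lifetimes still alive after ",
                          max_steps, " steps; truncated")
  lrs
}

#' Age-specific reproductive values
#'
#' Reproductive value measures the relative expected contribution of each
#' (st)age class to future population size.  It is computed here as the
#' dominant left eigenvector of the mean realized projection matrix at
#' stochastic quasi-equilibrium (the average of the per-step matrices
#' \eqn{K_t} over post-burn-in steps), normalised so the age-1 dominant
#' class has value 1.  Interquartile bands are taken across the chunk-mean
#' matrices retained by \code{\link{simulate.smpm}}.
#'
#' @param sim A \code{"smpm_sim"} simulated with \code{keep_K = TRUE}.
#' @return Object of class \code{"reproductive_values"}: a data frame with
#'   columns \code{stage}, \code{age}, \code{v}, \code{q25}, \code{q75},
#'   plus attribute \code{lambda} (dominant eigenvalue of the mean matrix).
#' @export
reproductive_values <- function(sim) {
  stopifnot(inherits(sim, "smpm_sim"))
  if (is.null(sim$mean_K)) {
    stop("simulation was run with keep_K = FALSE; re-run with keep_K = TRUE",
         call. = FALSE)
  }
  k <- sim$model$kernel
  n_dom <- length(k$age_dom)
  n_sub <- length(k$age_sub)
  left_ev <- function(K) {
    e <- eigen(t(K))
    i <- which.max(Mod(e$values))
    if (abs(Im(e$values[i])) > 1e-8) {
      stop("dominant eigenvalue of the mean projection matrix is complex; ",
           "power iteration did not isolate a real dominant root",
           call. = FALSE)
    }
    v <- Re(e$vectors[, i])
    if (sum(v) < 0) v <- -v
    if (any(v < -1e-8)) {
      stop("dominant left eigenvector has mixed signs; mean matrix is not ",
           "primitive enough for a reproductive-value interpretation",
           call. = FALSE)
    }
    pmax(v, 0) / v[1L]          # normalise: age-1 dominant class = 1
  }
  v <- left_ev(sim$mean_K)
  chunks <- which(sim$chunk_n > 0L)
  vb <- vapply(chunks, function(ck) left_ev(sim$chunk_K[ck, , ]),
               numeric(length(v)))
  q25 <- apply(vb, 1L, stats::quantile, 0.25)
  q75 <- apply(vb, 1L, stats::quantile, 0.75)
  lambda <- max(Mod(eigen(sim$mean_K, only.values = TRUE)$values))
  df <- data.frame(
    stage = rep(c("dominant", "helper", "nonhelper"),
                c(n_dom, n_sub, n_sub)),
    age = c(k$age_dom, k$age_sub, k$age_sub),
    v = v, q25 = q25, q75 = q75, row.names = NULL)
  structure(df, class = c("reproductive_values", "data.frame"),
            lambda = lambda)
}

#' @export
print.reproductive_values <- function(x, ...) {
  cat("Reproductive values (age-1 dominant = 1); lambda of mean K:",
      format(attr(x, "lambda")), "\n")
  print.data.frame(utils::head(x, 8L))
  cat("...\n")
  invisible(x)
}

#' @export
plot.reproductive_values <- function(x, stages = c("helper", "nonhelper"),
                                     ...) {
  cols <- c(dominant = "purple", helper = "orange", nonhelper = "darkgreen")
  sub <- x[x$stage %in% stages, ]
  graphics::plot(range(sub$age), range(c(sub$q25, sub$q75)), type = "n",
                 xlab = "age (years)", ylab = "reproductive value", ...)
  for (st in stages) {
    s <- sub[sub$stage == st, ]
    graphics::polygon(c(s$age, rev(s$age)), c(s$q25, rev(s$q75)),
                      col = grDevices::adjustcolor(cols[[st]], 0.2),
                      border = NA)
    graphics::lines(s$age, s$v, col = cols[[st]], lwd = 2)
  }
  graphics::legend("topright", stages, col = cols[stages], lwd = 2, bty = "n")
  invisible(x)
}
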