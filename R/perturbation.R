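#' Random-design life table response experiment
#'
#' Retrospective decomposition of the variance of population size into
#' contributions from the six stochastically varying intercept channels
#' (\code{S_d}, \code{S_h}, \code{S_u}, \code{R_d}, \code{R_h}, \code{f}).
#' A long stochastic simulation records, per post-burn-in step, the drawn
#' intercept vector and the resulting next-step population size; a random
#' forest of regression trees of the response on the six channels then
#' attributes importance (normalised variance-reduction importance, in
#' percent) to each channel, together with the total fraction of response
#' variance the ensemble explains.  A finite-difference analytic
#' approximation (sensitivity of the stochastic mean population size to each
#' channel's mean, times the channel's among-season standard deviation,
#' squared and normalised) is returned as a cross-check.
#'
#' @param model A \code{\link{smpm}}.
#' @param n_steps Post-burn-in steps to record; defaults to
#'   \code{horizon - burn_in} from the model configuration.
#' @param seed Optional RNG seed.
#' @param ntree Trees in the ensemble.
#' @param response \code{"step"} (default): next-step total population size
#'   per step, capturing the step-level environmental response.
#'   \code{"block"}: block-mean population size regressed on block-mean
#'   intercepts over contiguous post-burn-in blocks.
#' @param block_size Steps per block when \code{response = "block"}.
#' @param analytic Also compute the finite-difference approximation (adds
#'   six paired simulations).
#' @param init Initial state.
#' @return Object of class \code{"ltre"}: list with \code{importance}
#'   (named percentages, summing to 100), \code{variance_explained}
#'   (fraction of Var(response) captured by the forest), \code{analytic}
#'   (named percentages or NULL) and \code{forest}.
#' @export
ltre_random_design <- function(model, n_steps = NULL, seed = NULL,
                               ntree = 500, response = c("step", "block"),
                               block_size = 20, analytic = TRUE,
                               init = NULL) {
  response <- match.arg(response)
  if (!is.null(seed)) set.seed(seed)
  cfg <- model$config
  k <- model$kernel
  sds <- apply(k$intercepts, 2, stats::sd)
  sds[is.na(sds)] <- 0          # a single-season kernel has no variation
  if (all(sds < 1e-12)) {
    stop("all intercept channels are constant across seasons; the LTRE ",
         "requires stochastic variation", call. = FALSE)
  }
  if (is.null(n_steps)) n_steps <- cfg$horizon - cfg$burn_in
  cfg2 <- smpm_config(termax = cfg$termax, beta = cfg$beta,
                      horizon = cfg$burn_in + n_steps, burn_in = cfg$burn_in,
                      age_max = cfg$age_max, age_step = cfg$age_step)
  m2 <- smpm(k, cfg2)
  sim <- simulate(m2, init = init, keep_K = FALSE)
  tr <- sim$trajectory
  post <- tr[tr$step > cfg$burn_in, ]
  X <- as.matrix(post[, .kernel_channels])
  y <- post$N_next
  if (response == "block") {
    grp <- (seq_len(nrow(post)) - 1L) %/% block_size
    X <- apply(X, 2, function(col) tapply(col, grp, mean))
    y <- as.numeric(tapply(y, grp, mean))
  }
  rf <- randomForest::randomForest(x = as.data.frame(X), y = y,
                                   ntree = ntree, importance = TRUE)
  imp <- randomForest::importance(rf, type = 2)[, 1L]
  imp <- pmax(imp, 0)
  importance <- 100 * imp / sum(imp)
  analytic_imp <- NULL
  if (analytic) {
    delta <- .Machine$double.eps^(1 / 3)
    base_seed <- sample.int(.Machine$integer.max, 1L)
    nhat <- function(kk) {
      set.seed(base_seed)        # common random numbers across channels
      simulate(smpm(kk, cfg2), init = init, keep_K = FALSE)$N_hat
    }
    N0 <- nhat(k)
    contrib <- vapply(.kernel_channels, function(ch) {
      if (sds[[ch]] < 1e-12) return(0)
      step_c <- delta * max(1, abs(mean(k$intercepts[, ch])))
      k2 <- k
      k2$intercepts[, ch] <- k2$intercepts[, ch] + step_c
      sens <- (nhat(k2) - N0) / step_c
      (sens * sds[[ch]])^2
    }, numeric(1))
    analytic_imp <- if (sum(contrib) > 0) 100 * contrib / sum(contrib) else contrib
  }
  structure(list(importance = importance,
                 variance_explained = utils::tail(rf$rsq, 1L),
                 analytic = analytic_imp,
                 n_steps = length(y),
                 forest = rf),
            class = "ltre")
}

#' @export
print.ltre <- function(x, ...) {
  cat("Random-design LTRE on mean population size\n")
  ord <- order(x$importance, decreasing = TRUE)
  for (i in ord) {
    cat(sprintf("  %-4s %6.1f%%", names(x$importance)[i], x$importance[i]))
    if (!is.null(x$analytic)) {
      cat(sprintf("   (analytic approx %5.1f%%)", x$analytic[i]))
    }
    cat("\n")
  }
  cat(sprintf("  variance explained by the forest: %.1f%% (n = %d)\n",
              100 * x$variance_explained, x$n_steps))
  invisible(x)
}

#' @export
plot.ltre <- function(x, ...) {
  ord <- order(x$importance, decreasing = TRUE)
  graphics::barplot(x$importance[ord], ylab = "importance (%)",
                    xlab = "stochastic intercept channel", ...)
  invisible(x)
}

.elasticity_channels <- c(.kernel_channels, "p_help", "q_contrast", "termax")

# Return a copy of the model with one parameter channel perturbed
# multiplicatively by (1 + delta) on the logit scale.
perturb_channel <- function(model, channel, delta) {
  channel <- match.arg(channel, .elasticity_channels)
  k <- model$kernel
  if (channel %in% .kernel_channels) {
    k$intercepts[, channel] <- k$intercepts[, channel] * (1 + delta)
  } else if (channel == "p_help") {
    sp <- k$specs$p_help
    k$specs$p_help <- rate_spec("p_help", sp$slopes,
                                intercept = sp$intercept * (1 + delta),
                                seasonal = FALSE)
  } else if (channel == "termax") {
    cfg <- model$config
    cfg$termax <- cfg$termax * (1 + delta)
    return(smpm(k, cfg))
  } else { # q_contrast: helper-presence contrast in dominant reproduction
    sl <- k$specs$R_d$slopes
    if (!"q" %in% names(sl)) {
      stop("the R_d specification carries no helper-presence term 'q'",
           call. = FALSE)
    }
    sl[["q"]] <- sl[["q"]] * (1 + delta)
    k$specs$R_d <- rate_spec("R_d", sl)
  }
  smpm(k, model$config)
}

#' Elasticity of the stochastic mean population size
#'
#' Prospective perturbation analysis: the proportional response of the
#' stochastic mean population size \eqn{\hat N} to a proportional change in
#' one model parameter,
#' \eqn{[\log \hat N(x(1+\delta)) - \log \hat N(x)] / \log(1+\delta)}.
#' Intercepts are perturbed multiplicatively on the logit scale (the
#' proportional-change contract is the definition used, since logit-scale
#' intercepts can be negative).  Base and perturbed runs share the same
#' seasonal draw sequence (common random numbers), which sharply reduces
#' the Monte-Carlo variance of the estimate.
#'
#' @param model A \code{\link{smpm}}.
#' @param channel One of the six seasonal intercept channels
#'   (\code{"S_d"}, \code{"S_h"}, \code{"S_u"}, \code{"R_d"}, \code{"R_h"},
#'   \code{"f"}), the help-probability intercept \code{"p_help"}, or the
#'   helper-presence contrast of dominant reproduction
#'   \code{"q_contrast"}, or the territory capacity \code{"termax"}.
#' @param delta Proportional perturbation (default 0.01).
#' @param seed Seed shared by the paired runs.
#' @param common_rng Use common random numbers for the paired runs
#'   (default TRUE; FALSE gives independent draws, mainly useful to
#'   demonstrate the variance reduction).
#' @param init Initial state.
#' @return Object of class \code{"smpm_elasticity"} with \code{value},
#'   \code{channel}, \code{delta}, \code{N_hat_base}, \code{N_hat_pert}.
#' @export
elasticity <- function(model, channel, delta = 0.01, seed = 1,
                       common_rng = TRUE, init = NULL) {
  channel <- match.arg(channel, .elasticity_channels)
  m_pert <- perturb_channel(model, channel, delta)
  set.seed(seed)
  base <- simulate(model, init = init, keep_K = FALSE)
  if (common_rng) set.seed(seed)
  pert <- simulate(m_pert, init = init, keep_K = FALSE)
  if (!is.finite(base$N_hat) || !is.finite(pert$N_hat) ||
      base$N_hat <= 0 || pert$N_hat <= 0) {
    stop("mean population size is zero or undefined in one of the paired ",
         "runs; elasticity is not computable", call. = FALSE)
  }
  structure(list(channel = channel, delta = delta,
                 value = (log(pert$N_hat) - log(base$N_hat)) / log1p(delta),
                 N_hat_base = base$N_hat, N_hat_pert = pert$N_hat,
                 seed = seed),
            class = "smpm_elasticity")
}

#' @export
print.smpm_elasticity <- function(x, ...) {
  cat(sprintf("Elasticity of N_hat to %s (delta = %g): %.4f\n",
              x$channel, x$delta, x$value))
  cat(sprintf("  N_hat: %.3f -> %.3f\n", x$N_hat_base, x$N_hat_pert))
  invisible(x)
}

#' Elasticities for every parameter channel
#'
#' @param model A \code{\link{smpm}}.
#' @param channels Channels to perturb (default: all).
#' @param ... Passed to \code{\link{elasticity}}.
#' @return Data frame with columns \code{channel} and \code{elasticity}.
#' @export
elasticity_table <- function(model, channels = .elasticity_channels, ...) {
  vals <- vapply(channels, function(ch) elasticity(model, ch, ...)$value,
                 numeric(1))
  data.frame(channel = channels, elasticity = vals, row.names = NULL)
}
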