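#' Weighted-lottery transition probabilities
#'
#' Surviving subordinates compete for vacant dominant positions in a
#' frequency-dependent weighted lottery: helpers carry weight
#' \eqn{e^\beta} and non-helpers weight 1.  The per-capita probability that
#' a surviving non-helper acquires a dominant position is
#' \eqn{g_u = \min(1,\; x / (e^\beta n_h + n_u))} and for a helper
#' \eqn{g_h = \min(1,\; e^\beta x / (e^\beta n_h + n_u))}, each capped at 1
#' independently.  When neither cap binds the filled positions conserve the
#' vacancies exactly: \eqn{g_h n_h + g_u n_u = x}.
#'
#' @param x Expected number of vacant dominant positions (>= 0).
#' @param nh,nu Expected numbers of surviving helpers / non-helpers (>= 0).
#' @param beta Log-weight contrast of helpers versus non-helpers.
#' @return Named numeric vector \code{c(g_h =, g_u =)} in [0, 1].  When
#'   there are no claimants but vacancies exist, both probabilities are 0
#'   and a warning is issued.
#' @examples
#' transition_probs(x = 10, nh = 40, nu = 10, beta = -0.549)
#' @export
transition_probs <- function(x, nh, nu, beta) {
  stopifnot(is.finite(x), is.finite(nh), is.finite(nu), is.finite(beta),
            x >= 0, nh >= 0, nu >= 0)
  if (nh == 0 && nu == 0) {
    if (x > 0) warning("vacancies present but no surviving subordinates to claim them")
    return(c(g_h = 0, g_u = 0))
  }
  denom <- exp(beta) * nh + nu
  g_u_unc <- x / denom
  c(g_h = min(1, exp(beta) * g_u_unc), g_u = min(1, g_u_unc))
}

#' Number of vacant dominant positions
#'
#' Vacancies open when dominants die: \eqn{x = \max(0,\;
#' \mathrm{termax} - \sum_a S_{d,a} d_a)}, the capacity minus the expected
#' number of surviving dominants.
#'
#' @param termax Territory capacity (> 0).
#' @param surviving_dominants Vector (or scalar total) of expected surviving
#'   dominants by age class.
#' @return Non-negative vacancy count (possibly non-integer).
#' @export
vacancy_count <- function(termax, surviving_dominants) {
  stopifnot(termax > 0, all(is.finite(surviving_dominants)))
  max(0, termax - sum(surviving_dominants))
}

# Bernoulli log-likelihood of the lottery transition records at a given beta.
# Per-record success probabilities follow the capped log-link model:
# p_h = min(1, e^beta x / (e^beta nh + nu)), p_u = min(1, x / (e^beta nh + nu)).
.lottery_loglik <- function(beta, records) {
  denom <- exp(beta) * records$nh + records$nu
  p <- records$x / denom
  p[records$stage == "helper"] <- exp(beta) * p[records$stage == "helper"]
  p <- pmin(1, p)
  eps <- 1e-12
  p <- pmin(1 - eps, pmax(eps, p))
  sum(records$outcome * log(p) + (1 - records$outcome) * log1p(-p))
}

#' Maximum-likelihood fit of the lottery contrast beta
#'
#' Fits the single parameter \eqn{\beta} of the weighted lottery to
#' individual transition records (one row per subordinate-season) by
#' maximising the Bernoulli log-likelihood with the capped log-link success
#' probabilities of the lottery model.  A Wald-type 95\% confidence
#' interval is derived from the numerical Hessian at the optimum.
#'
#' @param records Data frame with columns \code{stage} (\code{"helper"} or
#'   \code{"non-helper"}), \code{x}, \code{nh}, \code{nu} (season-level
#'   counts) and \code{outcome} (0/1: acquired a dominant position).
#' @param interval Search interval for \eqn{\beta}.
#' @param level Confidence level for the Wald interval.
#' @return An object of class \code{"lottery_fit"} with components
#'   \code{beta} (the MLE), \code{se}, \code{ci}, \code{logLik},
#'   \code{n} and \code{records}.  Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{vcov}, \code{confint}, \code{logLik}.
#' @examples
#' rec <- make_transition_records(true_beta = -0.5, n_records = 648)
#' fit <- fit_beta(rec)
#' coef(fit); confint(fit)
#' @export
fit_beta <- function(records, interval = c(-8, 8), level = 0.95) {
  records <- as.data.frame(records)
  need <- c("stage", "x", "nh", "nu", "outcome")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records$stage <- as.character(records$stage)
  if (!all(records$stage %in% c("helper", "non-helper"))) {
    stop("stage must be 'helper' or 'non-helper'", call. = FALSE)
  }
  if (length(unique(records$stage)) < 2L) {
    stop("records must contain both helper and non-helper rows", call. = FALSE)
  }
  if (length(unique(records$outcome)) < 2L) {
    stop("records must contain both outcomes (0 and 1)", call. = FALSE)
  }
  if (any(records$nh + records$nu < 1)) {
    stop("each record needs at least one surviving subordinate (nh + nu >= 1)",
         call. = FALSE)
  }
  # Detect a flat likelihood (e.g. every record saturated at p = 1).
  grid <- seq(interval[1], interval[2], length.out = 41L)
  ll_grid <- vapply(grid, .lottery_loglik, numeric(1), records = records)
  if (diff(range(ll_grid)) < 1e-8) {
    stop("log-likelihood is flat in beta (all success probabilities ",
         "saturated); beta is not identifiable from these records",
         call. = FALSE)
  }
  opt <- stats::optimize(.lottery_loglik, interval = interval,
                         records = records, maximum = TRUE, tol = 1e-9)
  beta_hat <- opt$maximum
  if (min(abs(beta_hat - interval)) < 1e-3) {
    stop("optimiser hit the boundary of the search interval (beta = ",
         signif(beta_hat, 4), "); possible separation or degenerate records",
         call. = FALSE)
  }
  h <- 1e-4
  d2 <- (.lottery_loglik(beta_hat + h, records) -
         2 * .lottery_loglik(beta_hat, records) +
         .lottery_loglik(beta_hat - h, records)) / h^2
  if (!is.finite(d2) || d2 >= 0) {
    stop("numerical Hessian is not negative definite at the optimum ",
         "(observed information ", signif(-d2, 4), "); fit unreliable",
         call. = FALSE)
  }
  se <- sqrt(-1 / d2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(beta = beta_hat, se = se,
                 ci = c(lower = beta_hat - z * se, upper = beta_hat + z * se),
                 level = level, logLik = opt$objective,
                 n = nrow(records), records = records),
            class = "lottery_fit")
}

#' @export
print.lottery_fit <- function(x, ...) {
  cat("Weighted-lottery transition model (maximum likelihood)\n")
  cat(sprintf("  beta = %.4f (SE %.4f), %d records\n", x$beta, x$se, x$n))
  cat(sprintf("  %.0f%% CI [%.4f, %.4f];  helper weight e^beta = %.4f\n",
              100 * x$level, x$ci[["lower"]], x$ci[["upper"]], exp(x$beta)))
  invisible(x)
}

#' @export
summary.lottery_fit <- function(object, ...) {
  tab <- table(stage = object$records$stage, outcome = object$records$outcome)
  out <- list(fit = object, outcomes = tab)
  class(out) <- "summary.lottery_fit"
  out
}

#' @export
print.summary.lottery_fit <- function(x, ...) {
  print(x$fit)
  cat("  log-likelihood:", format(x$fit$logLik), "\n")
  cat("  outcome table:\n")
  print(x$outcomes)
  invisible(x)
}

#' @export
coef.lottery_fit <- function(object, ...) c(beta = object$beta)

#' @export
vcov.lottery_fit <- function(object, ...) {
  matrix(object$se^2, 1, 1, dimnames = list("beta", "beta"))
}

#' @export
confint.lottery_fit <- function(object, parm = "beta", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$beta - z * object$se, object$beta + z * object$se),
              nrow = 1,
              dimnames = list("beta", sprintf("%.1f %%",
                                              100 * c((1 - level) / 2,
                                                      1 - (1 - level) / 2))))
  m
}

#' @export
logLik.lottery_fit <- function(object, ...) {
  structure(object$logLik, df = 1L, nobs = object$n, class = "logLik")
}
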