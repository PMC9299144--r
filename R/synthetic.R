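#' Specification of a synthetic seasonal parameter kernel
#'
#' Describes the among-season distribution of the logit-scale intercepts of
#' the six seasonal demographic functions: per-channel means, among-season
#' standard deviations and a cross-channel correlation (good seasons tend to
#' be good for several vital rates at once).  With
#' \code{shared_subordinate_survival = TRUE} (the default) helpers and
#' non-helpers share a single subordinate-survival parameter set: one
#' intercept is drawn per season and written to both the \code{S_h} and
#' \code{S_u} channels, which remain separately perturbable.
#'
#' The default calibration targets the published scale of the Seychelles
#' warbler system: capacity 111.2 dominant territories held full, roughly
#' fifty helpers and a dozen non-helpers at quasi-equilibrium, high adult
#' survival, and among-season variation concentrated in the dominants'
#' reproduction and survival.
#'
#' @param n_seasons Number of seasons in the kernel (default 40).
#' @param means,sds Named numeric vectors over the channels \code{S_d},
#'   \code{S_h}, \code{S_u}, \code{R_d}, \code{R_h}, \code{f}.
#' @param correlation Either a single pairwise correlation applied to all
#'   channel pairs, or a full correlation matrix over the six channels.
#' @param shared_subordinate_survival Draw one subordinate-survival
#'   intercept per season for both \code{S_h} and \code{S_u}.
#' @param specs Slope compositions (\code{\link{default_rate_specs}}).
#' @param standardisation Population-size standardisation constants.
#' @param seed Optional seed stored in the spec and used by
#'   \code{\link{make_kernel}}.
#' @return Object of class \code{"synthetic_kernel_spec"}.
#' @export
synthetic_kernel_spec <- function(
    n_seasons = 40,
    means = c(S_d = 2.20, S_h = 1.70, S_u = 1.70,
              R_d = -3.00, R_h = -3.20, f = 0.45),
    sds = c(S_d = 0.30, S_h = 0.12, S_u = 0.12,
            R_d = 0.45, R_h = 0.30, f = 0.20),
    correlation = 0.3,
    shared_subordinate_survival = TRUE,
    specs = default_rate_specs(),
    standardisation = c(mean = 170, sd = 15),
    seed = NULL) {
  means <- means[.kernel_channels]
  sds <- sds[.kernel_channels]
  if (anyNA(means) || anyNA(sds)) {
    stop("means and sds must cover channels ",
         paste(.kernel_channels, collapse = ", "), call. = FALSE)
  }
  if (any(sds < 0)) stop("sds must be non-negative", call. = FALSE)
  if (is.matrix(correlation)) {
    C <- correlation
    stopifnot(nrow(C) == 6L, ncol(C) == 6L)
  } else {
    C <- matrix(correlation, 6L, 6L)
    diag(C) <- 1
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  }
  dimnames(C) <- list(.kernel_channels, .kernel_channels)
  structure(list(n_seasons = as.integer(n_seasons), means = means, sds = sds,
                 correlation = C,
                 shared_subordinate_survival = shared_subordinate_survival,
                 specs = specs, standardisation = standardisation,
                 seed = seed),
            class = "synthetic_kernel_spec")
}

#' @export
print.synthetic_kernel_spec <- function(x, ...) {
  cat("<synthetic_kernel_spec> ", x$n_seasons, " seasons",
      if (x$shared_subordinate_survival) "; shared subordinate survival",
      "\n", sep = "")
  print(round(rbind(mean = x$means, sd = x$sds), 3))
  invisible(x)
}

#' Generate a seasonal parameter kernel with known truth
#'
#' Draws per-season intercept vectors from a multivariate normal with the
#' spec's moments and wraps them, together with the spec's slope
#' compositions, into a \code{\link{smpm_kernel}}.
#'
#' @param spec A \code{\link{synthetic_kernel_spec}}.
#' @param seed Optional seed (overrides the spec's).
#' @return A \code{\link{smpm_kernel}}.
#' @examples
#' k <- make_kernel(synthetic_kernel_spec(seed = 1))
#' k
#' @export
make_kernel <- function(spec = synthetic_kernel_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_kernel_spec"))
  if (!is.null(seed)) set.seed(seed)
  ch <- .kernel_channels
  if (spec$shared_subordinate_survival) {
    keep <- c("S_d", "S_h", "R_d", "R_h", "f")   # S_h stands for both
    mu <- spec$means[keep]
    sd_k <- spec$sds[keep]
    C <- spec$correlation[keep, keep]
    Sigma <- diag(sd_k) %*% C %*% diag(sd_k)
    draws <- MASS::mvrnorm(spec$n_seasons, mu, Sigma)
    if (!is.matrix(draws)) {
      draws <- matrix(draws, nrow = 1L, dimnames = list(NULL, keep))
    }
    draws <- cbind(draws, S_u = draws[, "S_h"])[, ch, drop = FALSE]
  } else {
    Sigma <- diag(spec$sds) %*% spec$correlation %*% diag(spec$sds)
    draws <- MASS::mvrnorm(spec$n_seasons, spec$means, Sigma)
    if (!is.matrix(draws)) {
      draws <- matrix(draws, nrow = 1L, dimnames = list(NULL, ch))
    }
    colnames(draws) <- ch
  }
  draws <- matrix(draws, nrow = spec$n_seasons,
                  dimnames = list(sprintf("season_%02d", seq_len(spec$n_seasons)),
                                  ch))
  smpm_kernel(draws, specs = spec$specs,
              standardisation = spec$standardisation)
}

#' Generate individual lottery transition records with known beta
#'
#' Simulates seasons of the weighted lottery: each season carries counts of
#' surviving helpers and non-helpers (helpers in the majority, as in the
#' study system) and a vacancy count, and every subordinate's outcome is a
#' Bernoulli draw with the capped log-link success probability of the
#' lottery model.  The resulting table is the fixture for
#' \code{\link{fit_beta}} recovery experiments.
#'
#' @param true_beta Generating log-weight contrast.
#' @param n_records Total number of subordinate-season rows (>= 100).
#' @param mean_nh,mean_nu,mean_x Poisson means of the per-season counts of
#'   surviving helpers, surviving non-helpers and vacancies.
#' @return Data frame with columns \code{season}, \code{stage}, \code{x},
#'   \code{nh}, \code{nu}, \code{outcome}.
#' @export
make_transition_records <- function(true_beta, n_records = 648,
                                    mean_nh = 40, mean_nu = 10, mean_x = 8) {
  if (n_records < 100) stop("n_records must be at least 100", call. = FALSE)
  rows <- list()
  total <- 0L
  season <- 0L
  while (total < n_records) {
    season <- season + 1L
    nh <- stats::rpois(1L, mean_nh)
    nu <- stats::rpois(1L, mean_nu)
    if (nh + nu < 1L) next
    x <- stats::rpois(1L, mean_x)
    g <- transition_probs(x, nh, nu, true_beta)
    stage <- c(rep("helper", nh), rep("non-helper", nu))
    p <- c(rep(g[["g_h"]], nh), rep(g[["g_u"]], nu))
    rows[[season]] <- data.frame(
      season = sprintf("season_%03d", season),
      stage = stage, x = x, nh = nh, nu = nu,
      outcome = as.integer(stats::runif(nh + nu) < p),
      stringsAsFactors = FALSE)
    total <- total + nh + nu
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[seq_len(n_records), ]
}

#' Hide the behavioural stage label on a fraction of subordinate rows
#'
#' Mimics the study-system missingness in which many subordinates carry no
#' behavioural information to classify them as helpers or non-helpers: a
#' random \code{fraction} of subordinate rows get their stage label set to
#' \code{NA}.
#'
#' @param records Data frame with a \code{stage} column; subordinate rows
#'   are those with stage \code{"helper"}, \code{"non-helper"}, \code{"h"}
#'   or \code{"u"}.
#' @param fraction Fraction of subordinate rows to mask, in [0, 1].
#' @return The records with masked stage labels.
#' @export
mask_status <- function(records, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  sub_rows <- which(records$stage %in% c("helper", "non-helper", "h", "u"))
  n_mask <- round(fraction * length(sub_rows))
  if (n_mask > 0L) {
    hide <- sample(sub_rows, n_mask)
    records$stage[hide] <- NA_character_
  }
  records
}

#' Write / read lottery transition records as CSV
#'
#' @param records Transition-record data frame
#'   (see \code{\link{make_transition_records}}).
#' @param file CSV path.
#' @export
write_transition_records <- function(records, file) {
  utils::write.csv(records, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_transition_records
#' @export
read_transition_records <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}
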