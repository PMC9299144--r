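#' Covariate transforms understood by demographic rate functions
#'
#' Each demographic probability is a logistic function of a linear predictor
#' built from a small set of covariate transforms: age \code{a} (years, on the
#' half-year grid), its square \code{a2} and cube \code{a3}, standardised
#' population size \code{N}, helper presence \code{q} (0/1) and its
#' interactions with age (\code{qa}, \code{qa2}), and the
#' subordinate-to-dominant ratio \code{r}.
#'
#' @keywords internal
#' @name rate-terms
NULL

.rate_terms <- c("a", "a2", "a3", "N", "q", "qa", "qa2", "r")

.eval_term <- function(term, cov) {
  need <- switch(term,
    a = "a", a2 = "a", a3 = "a",
    N = "N",
    q = "q", qa = c("q", "a"), qa2 = c("q", "a"),
    r = "r",
    stop("unknown covariate term '", term, "'", call. = FALSE))
  miss <- need[!need %in% names(cov) | vapply(need, function(x) is.null(cov[[x]]), TRUE)]
  if (length(miss) > 0L) {
    stop("covariate '", miss[1L], "' required by term '", term, "' is missing",
         call. = FALSE)
  }
  switch(term,
    a   = cov$a,
    a2  = cov$a^2,
    a3  = cov$a^3,
    N   = cov$N,
    q   = cov$q,
    qa  = cov$q * cov$a,
    qa2 = cov$q * cov$a^2,
    r   = cov$r)
}

#' Specify one demographic rate function
#'
#' A rate specification names a demographic probability (survival of
#' dominants \code{S_d}, helpers \code{S_h} or non-helpers \code{S_u};
#' reproduction of dominants \code{R_d} or helpers \code{R_h}; the
#' probability \code{f} that an offspring recruits as a helper; or the
#' probability \code{p_help} that a dominant receives help) together with the
#' fixed slopes of its linear predictor.  Seasonal functions take a
#' per-season intercept drawn from the kernel; \code{p_help} is the only
#' non-seasonal function and carries a single fixed intercept.
#'
#' @param name One of \code{"S_d"}, \code{"S_h"}, \code{"S_u"}, \code{"R_d"},
#'   \code{"R_h"}, \code{"f"}, \code{"p_help"}.
#' @param slopes Named numeric vector of slopes; names must be covariate
#'   transform labels (\code{a}, \code{a2}, \code{a3}, \code{N}, \code{q},
#'   \code{qa}, \code{qa2}, \code{r}).
#' @param intercept Single fixed intercept, required iff
#'   \code{seasonal = FALSE}.
#' @param seasonal Logical; does the intercept vary by season?
#' @return An object of class \code{"rate_spec"}.
#' @examples
#' rate_spec("R_h", c(a = 0.25, a2 = -0.025, N = -0.2))
#' @export
rate_spec <- function(name, slopes = numeric(0), intercept = NULL,
                      seasonal = name != "p_help") {
  name <- match.arg(name, c("S_d", "S_h", "S_u", "R_d", "R_h", "f", "p_help"))
  slopes <- unlist(slopes)
  if (length(slopes) > 0L) {
    if (is.null(names(slopes)) || any(!names(slopes) %in% .rate_terms)) {
      stop("slopes must be named with covariate terms among: ",
           paste(.rate_terms, collapse = ", "), call. = FALSE)
    }
    if (any(!is.finite(slopes))) stop("all slopes must be finite", call. = FALSE)
  }
  if (!seasonal) {
    if (is.null(intercept) || length(intercept) != 1L || !is.finite(intercept)) {
      stop("a non-seasonal rate_spec needs exactly one finite intercept",
           call. = FALSE)
    }
  } else if (!is.null(intercept)) {
    stop("a seasonal rate_spec takes its intercepts from the kernel, not here",
         call. = FALSE)
  }
  structure(list(name = name, slopes = slopes, intercept = intercept,
                 seasonal = seasonal),
            class = "rate_spec")
}

#' @export
print.rate_spec <- function(x, ...) {
  cat("<rate_spec> ", x$name,
      if (x$seasonal) " (seasonal intercepts)" else
        sprintf(" (fixed intercept %.4g)", x$intercept), "\n", sep = "")
  if (length(x$slopes) > 0L) {
    cat("  slopes: ",
        paste(sprintf("%s=%.4g", names(x$slopes), x$slopes), collapse = ", "),
        "\n", sep = "")
  } else {
    cat("  slopes: (none)\n")
  }
  invisible(x)
}

#' Evaluate a logistic demographic rate
#'
#' Computes \eqn{p = \mathrm{logit}^{-1}(\beta_0 + \sum_i \beta_i x_i)} for
#' one rate specification, a (seasonal) intercept and a covariate set.  This
#' is the elementary building block of every time-varying probability in the
#' projection model.
#'
#' @param spec A \code{\link{rate_spec}}.
#' @param intercept Intercept on the logit scale.  For a non-seasonal spec
#'   this defaults to the spec's own fixed intercept.
#' @param cov Named list of covariates (\code{a}, \code{N}, \code{q},
#'   \code{r}); vectors are recycled in the usual way so the rate can be
#'   evaluated over a whole age grid at once.
#' @return Probability (vector) strictly inside (0, 1) up to floating point.
#' @examples
#' sp <- rate_spec("R_h", c(a = 0.1))
#' logistic_rate(sp, intercept = 0.3, cov = list(a = 2))
#' @export
logistic_rate <- function(spec, intercept = spec$intercept, cov = list()) {
  stopifnot(inherits(spec, "rate_spec"))
  if (is.null(intercept) || anyNA(intercept)) {
    stop("no intercept supplied for rate '", spec$name, "'", call. = FALSE)
  }
  eta <- intercept
  for (term in names(spec$slopes)) {
    eta <- eta + spec$slopes[[term]] * .eval_term(term, cov)
  }
  if (any(!is.finite(eta))) {
    stop("non-finite linear predictor in rate '", spec$name, "'", call. = FALSE)
  }
  # a slope-free spec must still evaluate over the whole covariate grid
  n <- max(length(eta), if (length(cov) > 0L) max(lengths(cov)) else 1L, 1L)
  stats::plogis(rep_len(eta, n))
}

#' Probability that a dominant receives help
#'
#' The help probability is a time-constant logistic function of the
#' dominant's age (quadratic, so that helping peaks at intermediate to old
#' ages) and of the ratio of subordinates to dominants in the population.
#'
#' @param a Dominant age(s) in years, on the half-year grid.
#' @param r Subordinate-to-dominant ratio (scalar, >= 0).
#' @param spec A non-seasonal \code{\link{rate_spec}} named \code{"p_help"};
#'   defaults to the package's default parameterisation, which peaks at
#'   10 years of age and increases with \code{r}.
#' @return Probability vector along \code{a}.
#' @examples
#' help_probability(seq(0.5, 15, 0.5), r = 0.55)
#' @export
help_probability <- function(a, r, spec = default_rate_specs()$p_help) {
  if (any(r < 0)) stop("ratio r must be non-negative", call. = FALSE)
  logistic_rate(spec, cov = list(a = a, r = r))
}

#' Default rate-function parameterisation
#'
#' Returns the package's default slope compositions and the fixed
#' \code{p_help} intercept.  The compositions encode the qualitative shapes
#' of the warbler life cycle: dominant survival is high and flat until late
#' life (cubic age polynomial); subordinate survival declines with age and
#' with standardised population size, with identical slope values for
#' helpers and non-helpers; dominant reproduction without help rises then
#' falls with age and declines with density, while the helper-presence
#' interaction terms cancel the age dependence when help is present;
#' helper reproduction is low, age-humped and density dependent; offspring
#' recruit as helpers with a probability that increases with the mother's
#' age; and the help probability peaks at 10 years of age and increases with
#' the subordinate-to-dominant ratio.
#'
#' @return Named list of \code{\link{rate_spec}} objects
#'   (\code{S_d}, \code{S_h}, \code{S_u}, \code{R_d}, \code{R_h}, \code{f},
#'   \code{p_help}).
#' @export
default_rate_specs <- function() {
  list(
    S_d = rate_spec("S_d", c(a = 0.03, a2 = 0.02, a3 = -0.001605)),
    S_h = rate_spec("S_h", c(a = -0.08, N = -0.15)),
    S_u = rate_spec("S_u", c(a = -0.08, N = -0.15)),
    R_d = rate_spec("R_d", c(a = 0.5, a2 = -0.045, N = -0.2,
                             q = 1.45, qa = -0.5, qa2 = 0.045)),
    R_h = rate_spec("R_h", c(a = 0.25, a2 = -0.025, N = -0.2)),
    f   = rate_spec("f",   c(a = 0.15, N = -0.05)),
    p_help = rate_spec("p_help", c(a = 0.4, a2 = -0.02, r = 0.5),
                       intercept = -1.9, seasonal = FALSE)
  )
}

#' Tabulate all demographic rates for one season
#'
#' Vectorises \code{\link{logistic_rate}} over the age grids of each stage
#' and returns the full per-(st)age probability profile used by one
#' projection step: survival of dominants, helpers and non-helpers,
#' dominant reproduction with (\code{q = 1}) and without (\code{q = 0})
#' help, helper reproduction, the helper-recruitment probability \code{f}
#' of offspring by mother's age, and the help probability.
#'
#' @param kernel A \code{\link{smpm_kernel}}.
#' @param season Season label present in the kernel.
#' @param N Raw (unstandardised) population size.
#' @param r Subordinate-to-dominant ratio.
#' @return A list with elements \code{age_sub}, \code{age_dom} (the grids)
#'   and numeric vectors \code{S_d}, \code{S_h}, \code{S_u}, \code{R_d_q0},
#'   \code{R_d_q1}, \code{R_h}, \code{f_sub}, \code{f_dom}, \code{p_help}.
#' @export
rate_profile <- function(kernel, season, N, r) {
  stopifnot(inherits(kernel, "smpm_kernel"))
  season <- as.character(season)
  if (!season %in% kernel$seasons) {
    stop("season '", season, "' not present in kernel", call. = FALSE)
  }
  ic <- kernel$intercepts[season, ]
  rate_profile_from_intercepts(kernel, unlist(ic), N = N, r = r)
}

# Internal workhorse shared by rate_profile() and project_step(): evaluates
# every rate over its age grid given one intercept vector.
rate_profile_from_intercepts <- function(kernel, intercepts, N = NULL, r = NULL,
                                         N_std = NULL) {
  sp <- kernel$specs
  age_sub <- kernel$age_sub
  age_dom <- kernel$age_dom
  if (is.null(N_std)) {
    if (is.null(N)) stop("either N or N_std must be supplied", call. = FALSE)
    N_std <- (N - kernel$standardisation[["mean"]]) / kernel$standardisation[["sd"]]
  }
  if (is.null(r)) r <- 0
  list(
    age_sub = age_sub, age_dom = age_dom,
    S_d = logistic_rate(sp$S_d, intercepts[["S_d"]],
                        list(a = age_dom, N = N_std)),
    S_h = logistic_rate(sp$S_h, intercepts[["S_h"]],
                        list(a = age_sub, N = N_std)),
    S_u = logistic_rate(sp$S_u, intercepts[["S_u"]],
                        list(a = age_sub, N = N_std)),
    R_d_q0 = logistic_rate(sp$R_d, intercepts[["R_d"]],
                           list(a = age_dom, N = N_std, q = 0)),
    R_d_q1 = logistic_rate(sp$R_d, intercepts[["R_d"]],
                           list(a = age_dom, N = N_std, q = 1)),
    R_h = logistic_rate(sp$R_h, intercepts[["R_h"]],
                        list(a = age_sub, N = N_std)),
    f_sub = logistic_rate(sp$f, intercepts[["f"]],
                          list(a = age_sub, N = N_std)),
    f_dom = logistic_rate(sp$f, intercepts[["f"]],
                          list(a = age_dom, N = N_std)),
    p_help = help_probability(age_dom, r, sp$p_help)
  )
}
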