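.kernel_channels <- c("S_d", "S_h", "S_u", "R_d", "R_h", "f")

#' Seasonal parameter kernel
#'
#' The kernel holds the per-season logit-scale intercepts of the six
#' time-varying demographic functions, the fixed slopes of every function
#' (including the non-seasonal help probability), and the standardisation
#' constants for population size.  Environmental stochasticity enters the
#' projection by resampling whole seasons from this kernel: one season index
#' is drawn per time step and all functions take that season's intercepts
#' jointly, which preserves the within-season covariance among vital rates.
#'
#' @param intercepts Matrix or data frame with one row per season and
#'   columns \code{S_d}, \code{S_h}, \code{S_u}, \code{R_d}, \code{R_h},
#'   \code{f}; row names (or a \code{season} column) label the seasons.
#' @param specs Named list of \code{\link{rate_spec}} objects for all seven
#'   functions; defaults to \code{\link{default_rate_specs}}.
#' @param standardisation Named numeric vector \code{c(mean =, sd =)} used to
#'   standardise raw population size before it enters any linear predictor.
#' @param age_max Maximum age class in years (recursive top class).
#' @param age_step Census interval in years.
#' @return An object of class \code{"smpm_kernel"}.
#' @seealso \code{\link{make_kernel}} to generate a synthetic kernel,
#'   \code{\link{read_kernel}}/\code{\link{write_kernel}} for the CSV form.
#' @export
smpm_kernel <- function(intercepts, specs = default_rate_specs(),
                        standardisation = c(mean = 170, sd = 15),
                        age_max = 15, age_step = 0.5) {
  if (is.data.frame(intercepts)) {
    if ("season" %in% names(intercepts)) {
      rn <- as.character(intercepts$season)
      intercepts <- intercepts[setdiff(names(intercepts), "season")]
      rownames(intercepts) <- rn
    }
    intercepts <- as.matrix(intercepts)
  }
  if (!all(.kernel_channels %in% colnames(intercepts))) {
    stop("intercepts must have columns ",
         paste(.kernel_channels, collapse = ", "), call. = FALSE)
  }
  intercepts <- intercepts[, .kernel_channels, drop = FALSE]
  if (anyNA(intercepts) || any(!is.finite(intercepts))) {
    stop("kernel intercepts must be finite with no missing values",
         call. = FALSE)
  }
  if (is.null(rownames(intercepts))) {
    rownames(intercepts) <- as.character(seq_len(nrow(intercepts)))
  }
  standardisation <- unlist(standardisation)
  if (!all(c("mean", "sd") %in% names(standardisation)) ||
      standardisation[["sd"]] <= 0) {
    stop("standardisation must supply mean and sd with sd > 0", call. = FALSE)
  }
  needed <- c(.kernel_channels, "p_help")
  if (!all(needed %in% names(specs))) {
    stop("specs must contain: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  for (nm in needed) stopifnot(inherits(specs[[nm]], "rate_spec"))
  if (specs$p_help$seasonal) stop("p_help must be non-seasonal", call. = FALSE)
  structure(list(
    seasons = rownames(intercepts),
    intercepts = intercepts,
    specs = specs,
    standardisation = standardisation[c("mean", "sd")],
    age_max = age_max,
    age_step = age_step,
    age_sub = seq(age_step, age_max, by = age_step),
    age_dom = seq(2 * age_step, age_max, by = age_step)
  ), class = "smpm_kernel")
}

#' @export
print.smpm_kernel <- function(x, ...) {
  cat("<smpm_kernel> ", length(x$seasons), " seasons, channels: ",
      paste(.kernel_channels, collapse = ", "), "\n", sep = "")
  cat("  population-size standardisation: mean ",
      format(x$standardisation[["mean"]]), ", sd ",
      format(x$standardisation[["sd"]]), "\n", sep = "")
  cat("  age grid: ", x$age_step, "-", x$age_max,
      " yr (step ", x$age_step, ")\n", sep = "")
  print(utils::head(round(x$intercepts, 3), 4L))
  if (length(x$seasons) > 4L) cat("  ... (", length(x$seasons) - 4L,
                                  " more seasons)\n", sep = "")
  invisible(x)
}

#' Draw one season from the kernel
#'
#' Samples a season label uniformly and returns its full intercept vector,
#' so that all vital rates experience the same season jointly.  Draws are
#' independent across time steps (no temporal autocorrelation).
#'
#' @param kernel A \code{\link{smpm_kernel}}.
#' @return List with \code{season} (label) and \code{intercepts} (named
#'   numeric vector over the six seasonal channels).
#' @export
draw_season <- function(kernel) {
  stopifnot(inherits(kernel, "smpm_kernel"))
  i <- sample.int(length(kernel$seasons), 1L)
  list(season = kernel$seasons[i], intercepts = kernel$intercepts[i, ])
}

#' Read / write a kernel as CSV tables
#'
#' The on-disk form is two plain-text tables: an intercepts file with columns
#' \code{season}, \code{function}, \code{value} (long format, seasonal
#' channels only) and a slopes file with columns \code{function},
#' \code{term}, \code{value}, where the non-seasonal \code{p_help} intercept
#' appears with term \code{"intercept"}.  Standardisation constants and the
#' age grid live in the model configuration (see
#' \code{\link{read_config}}).
#'
#' @param intercepts_file,slopes_file CSV paths.
#' @param standardisation,age_max,age_step Passed to
#'   \code{\link{smpm_kernel}}.
#' @return \code{read_kernel} returns a \code{\link{smpm_kernel}};
#'   \code{write_kernel} invisibly returns the two file paths.
#' @export
read_kernel <- function(intercepts_file, slopes_file,
                        standardisation = c(mean = 170, sd = 15),
                        age_max = 15, age_step = 0.5) {
  ic <- utils::read.csv(intercepts_file, stringsAsFactors = FALSE)
  sl <- utils::read.csv(slopes_file, stringsAsFactors = FALSE)
  names(ic) <- tolower(names(ic))
  names(sl) <- tolower(names(sl))
  stopifnot(all(c("season", "function.", "value") %in% names(ic)) ||
            all(c("season", "function", "value") %in% names(ic)))
  fn_col <- if ("function." %in% names(ic)) "function." else "function"
  wide <- stats::reshape(ic[, c("season", fn_col, "value")],
                         idvar = "season", timevar = fn_col,
                         direction = "wide")
  colnames(wide) <- sub("^value\\.", "", colnames(wide))
  fn_col_s <- if ("function." %in% names(sl)) "function." else "function"
  specs <- list()
  for (nm in c(.kernel_channels, "p_help")) {
    rows <- sl[sl[[fn_col_s]] == nm, , drop = FALSE]
    slopes <- rows$value[rows$term != "intercept"]
    names(slopes) <- rows$term[rows$term != "intercept"]
    if (nm == "p_help") {
      b0 <- rows$value[rows$term == "intercept"]
      if (length(b0) != 1L) {
        stop("slopes file must carry exactly one p_help intercept",
             call. = FALSE)
      }
      specs[[nm]] <- rate_spec(nm, slopes, intercept = b0, seasonal = FALSE)
    } else {
      specs[[nm]] <- rate_spec(nm, slopes)
    }
  }
  smpm_kernel(wide, specs = specs, standardisation = standardisation,
              age_max = age_max, age_step = age_step)
}

#' @rdname read_kernel
#' @param kernel A \code{\link{smpm_kernel}} to serialise.
#' @export
write_kernel <- function(kernel, intercepts_file, slopes_file) {
  stopifnot(inherits(kernel, "smpm_kernel"))
  ic <- data.frame(
    season = rep(kernel$seasons, times = length(.kernel_channels)),
    `function` = rep(.kernel_channels, each = length(kernel$seasons)),
    value = as.vector(kernel$intercepts[, .kernel_channels]),
    check.names = FALSE)
  rows <- list()
  for (nm in c(.kernel_channels, "p_help")) {
    sp <- kernel$specs[[nm]]
    if (length(sp$slopes) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        `function` = nm, term = names(sp$slopes),
        value = unname(sp$slopes), check.names = FALSE)
    }
    if (!sp$seasonal) {
      rows[[length(rows) + 1L]] <- data.frame(
        `function` = nm, term = "intercept", value = sp$intercept,
        check.names = FALSE)
    }
  }
  sl <- do.call(rbind, rows)
  utils::write.csv(ic, intercepts_file, row.names = FALSE)
  utils::write.csv(sl, slopes_file, row.names = FALSE)
  invisible(c(intercepts = intercepts_file, slopes = slopes_file))
}

#' Model configuration
#'
#' Bundles the structural constants of the projection model: the territory
#' capacity \code{termax} (the mean observed number of dominant positions;
#' densities, so possibly non-integer), the lottery contrast \code{beta}
#' (log weight of helpers relative to non-helpers when competing for
#' vacancies), the simulation horizon and burn-in (in half-year steps), and
#' the maximum age.
#'
#' @param termax Territory capacity (> 0); default 111.2.
#' @param beta Lottery log-weight contrast; default -0.549 (helpers
#'   disadvantaged).
#' @param horizon Number of half-year steps to simulate; default 10000.
#' @param burn_in Steps discarded before computing stationary summaries;
#'   default 7000.
#' @param age_max,age_step Age grid (years).
#' @return An object of class \code{"smpm_config"}.
#' @export
smpm_config <- function(termax = 111.2, beta = -0.549, horizon = 10000,
                        burn_in = 7000, age_max = 15, age_step = 0.5) {
  stopifnot(termax > 0, burn_in < horizon, horizon >= 1)
  structure(list(termax = termax, beta = beta, horizon = as.integer(horizon),
                 burn_in = as.integer(burn_in), age_max = age_max,
                 age_step = age_step),
            class = "smpm_config")
}

#' @export
print.smpm_config <- function(x, ...) {
  cat("<smpm_config> termax ", x$termax, ", beta ", x$beta,
      ", horizon ", x$horizon, " steps (burn-in ", x$burn_in, ")\n", sep = "")
  invisible(x)
}

#' Read / write the model configuration as YAML
#'
#' @param file Path to a YAML file with keys \code{termax}, \code{beta},
#'   \code{horizon}, \code{burn_in}, \code{age_max}, \code{age_step} and a
#'   \code{standardisation} block (\code{mean}, \code{sd}).
#' @return \code{read_config} returns a list with elements \code{config}
#'   (a \code{\link{smpm_config}}) and \code{standardisation}.
#' @export
read_config <- function(file) {
  y <- yaml::read_yaml(file)
  cfg <- smpm_config(
    termax = y$termax %||% 111.2,
    beta = y$beta %||% -0.549,
    horizon = y$horizon %||% 10000,
    burn_in = y$burn_in %||% 7000,
    age_max = y$age_max %||% 15,
    age_step = y$age_step %||% 0.5)
  std <- c(mean = y$standardisation$mean %||% 170,
           sd = y$standardisation$sd %||% 15)
  list(config = cfg, standardisation = std)
}

#' @rdname read_config
#' @param config A \code{\link{smpm_config}}.
#' @param standardisation Named vector \code{c(mean =, sd =)}.
#' @export
write_config <- function(config, standardisation, file) {
  stopifnot(inherits(config, "smpm_config"))
  y <- list(termax = config$termax, beta = config$beta,
            horizon = config$horizon, burn_in = config$burn_in,
            age_max = config$age_max, age_step = config$age_step,
            standardisation = list(mean = unname(standardisation[["mean"]]),
                                   sd = unname(standardisation[["sd"]])))
  yaml::write_yaml(y, file)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
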