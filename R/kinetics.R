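#' Published force-transfer-time summary table
#'
#' The 18-force steered-transfer summary shipped with the package: mean
#' and standard deviation of the transfer time (ns) over four replicate
#' pulls at each driving force from 6 to 23 kcal/mol/A.
#'
#' @return Tibble with `force` (kcal/mol/A), `mean_ns`, `sd_ns`, `n`.
#' @export
#' @examples
#' ce_force_time_means()
ce_force_time_means <- function() {
  path <- system.file("extdata", "ce_force_time_means.tsv", package = "cetransit")
  tbl <- utils::read.delim(path, sep = "\t")
  tibble::as_tibble(tbl)
}

#' Fit a transfer-time power law Time = A * Force^-b
#'
#' Ordinary least squares of log(time) on log(force): the exponent is the
#' negated slope and the prefactor the exponentiated intercept; `r` is the
#' Pearson correlation of the log-log pairs. `weighting = "replicate"`
#' uses every replicate row (column `time_ns`); `weighting = "mean"` uses
#' one point per force (column `mean_ns`, or the per-force mean of
#' `time_ns`).
#'
#' @param table Force-time table: `force` plus `time_ns` (replicate rows)
#'   or `mean_ns` (aggregated).
#' @param weighting "replicate" or "mean".
#' @return A `power_law_fit` object: fields `A` (ns * (kcal/mol/A)^b),
#'   `b`, `r`, `n`, and the force range fitted. Has [tidy()], [glance()],
#'   [predict_time()] and [ggplot2::autoplot()] methods.
#' @export
#' @examples
#' fit_power_law(ce_force_time_means(), weighting = "mean")
fit_power_law <- function(table, weighting = c("replicate", "mean")) {
  stopifnot(is.data.frame(table), "force" %in% names(table))
  weighting <- match.arg(weighting)
  if (weighting == "replicate" && !"time_ns" %in% names(table)) {
    weighting <- "mean"
  }
  if (weighting == "mean") {
    if (!"mean_ns" %in% names(table)) {
      table <- dplyr::summarise(
        dplyr::group_by(table, .data$force),
        mean_ns = mean(.data$time_ns), .groups = "drop"
      )
    }
    x <- table$force
    y <- table$mean_ns
  } else {
    x <- table$force
    y <- table$time_ns
  }
  if (any(x <= 0) || any(y <= 0)) {
    rlang::abort("forces and times must be positive for a log-log fit")
  }
  if (length(unique(x)) < 2) {
    rlang::abort("at least 2 distinct forces are required")
  }
  lx <- log(x)
  ly <- log(y)
  fit <- stats::lm(ly ~ lx)
  structure(
    list(
      A = exp(unname(stats::coef(fit)[1])),
      b = -unname(stats::coef(fit)[2]),
      r = stats::cor(lx, ly),
      n = length(x),
      force_range = range(x),
      weighting = weighting,
      lm = fit
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: Time (ns) = %.4g * Force^-%.4g   (|r| = %.4f, n = %d, forces %.3g-%.3g)\n",
    x$A, x$b, abs(x$r), x$n, x$force_range[1], x$force_range[2]
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(
    term = c("prefactor_A", "exponent_b"),
    estimate = c(x$A, x$b),
    std.error = c(
      x$A * summary(x$lm)$coefficients[1, 2],
      summary(x$lm)$coefficients[2, 2]
    )
  )
}

#' @exportS3Method generics::glance
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(
    A = x$A, b = x$b, r = x$r, r.squared = x$r^2, n = x$n,
    force_min = x$force_range[1], force_max = x$force_range[2]
  )
}

#' Predict transfer times from a power-law fit
#'
#' Evaluates `A * force^-b`. Forces outside the fitted range are flagged
#' as extrapolation (never silently), which matters when projecting
#' steered-force fits down three orders of magnitude to physiological
#' driving forces.
#'
#' @param fit A `power_law_fit`, or a list/vector with elements `A` and
#'   `b`.
#' @param force Driving forces, kcal/mol/A (positive).
#' @return Tibble with `force`, `time_ns`, `extrapolated`.
#' @export
#' @examples
#' predict_time(list(A = 475, b = 2.75), force = c(11, 0.018))
predict_time <- function(fit, force) {
  if (any(force <= 0)) rlang::abort("force must be positive")
  A <- fit$A
  b <- fit$b
  stopifnot(is.numeric(A), is.numeric(b), A > 0)
  rng <- if (inherits(fit, "power_law_fit")) fit$force_range else c(NA, NA)
  extra <- if (all(is.na(rng))) rep(NA, length(force)) else force < rng[1] | force > rng[2]
  tibble::tibble(
    force = force,
    time_ns = A * force^(-b),
    extrapolated = extra
  )
}

#' Summarise a replicate force-time table
#'
#' @param table Replicate-level table with `force` and `time_ns`.
#' @return Per-force tibble: `force`, `mean_ns`, `sd_ns` (`NA` and
#'   flagged when a force has a single replicate), `n`.
#' @export
summarize_force_times <- function(table) {
  stopifnot(is.data.frame(table), all(c("force", "time_ns") %in% names(table)))
  out <- dplyr::summarise(
    dplyr::group_by(table, .data$force),
    mean_ns = mean(.data$time_ns),
    sd_ns = stats::sd(.data$time_ns),
    n = dplyr::n(),
    .groups = "drop"
  )
  dplyr::mutate(out, sd_undefined = .data$n < 2)
}
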