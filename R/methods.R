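#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a kinetic fit
#'
#' One row per parameter, broom-style. If `ci` (from [bootstrap_ci()]) has
#' been attached to the fit, `conf.low`/`conf.high` columns are included.
#'
#' @param x A `logistic_fit` or `lp_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` (plus interval
#'   columns when available).
#' @export
tidy.kinetic_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$estimate),
                        estimate = unname(x$estimate),
                        std.error = unname(x$se[names(x$estimate)]))
  if (!is.null(x$ci)) {
    out <- dplyr::left_join(out,
                            dplyr::select(x$ci, "term", "conf.low",
                                          "conf.high"),
                            by = "term")
  }
  out
}

#' Glance at a kinetic fit
#'
#' @param x A `logistic_fit` or `lp_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `r.squared`, `sigma` (residual standard
#'   deviation), `converged`, `n.obs` and `model`.
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = stats::sd(x$residuals),
    converged = x$converged,
    n.obs = x$n_obs,
    model = if (inherits(x, "logistic_fit")) "logistic" else "luedeking_piret"
  )
}

#' Augment the data behind a kinetic fit
#'
#' @param x A `logistic_fit` or `lp_fit` object.
#' @param ... Unused.
#' @return The fitting data with `.fitted` and `.resid` columns appended.
#' @export
augment.kinetic_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = x$residuals)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  model <- if (inherits(x, "logistic_fit")) "Logistic growth"
           else "Luedeking-Piret production"
  cat(sprintf("%s fit (%d observations)\n", model, x$n_obs))
  print(x$params)
  cat(sprintf("  R2 = %.5f, converged: %s\n", x$r_squared, x$converged))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

fit_curve_frame <- function(x, n = 200) {
  t <- seq(min(x$data$time_h), max(x$data$time_h), length.out = n)
  y <- if (inherits(x, "logistic_fit")) {
    logistic_solution(x$params, t)
  } else {
    lp_solution(x$growth, x$params, t)
  }
  tibble::tibble(time_h = t, value = y)
}

#' Plot a kinetic fit
#'
#' Observed points (one series per replicate when available) with the
#' fitted closed-form curve overlaid.
#'
#' @param object A `logistic_fit` or `lp_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  d <- object$data
  d$.value <- d[[object$response]]
  curve <- fit_curve_frame(object)
  ylab <- if (object$response == "biomass") "Biomass (g/L or OD600)"
          else "Product (g/L)"
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$.value))
  p <- if ("replicate" %in% names(d)) {
    p + ggplot2::geom_point(ggplot2::aes(shape = factor(.data$replicate)),
                            alpha = 0.8) +
      ggplot2::labs(shape = "Replicate")
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
  p +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$time_h, y = .data$value),
                       colour = "steelblue", linewidth = 0.8) +
    ggplot2::labs(x = "Time (h)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a replicated time course
#'
#' Biomass and product trajectories of a long-format time-course table,
#' faceted by condition and variable.
#'
#' @param data A tibble as produced by [simulate_timecourse()] or
#'   [read_timecourse_csv()].
#' @return A ggplot object.
#' @examples
#' plot_timecourse(simulate_study(default_scenarios(), seed = 1))
#' @export
plot_timecourse <- function(data) {
  long <- tidyr::pivot_longer(data, cols = c("biomass", "product"),
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$time_h, y = .data$value,
                               group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(variable ~ condition, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = NULL) +
    ggplot2::theme_minimal()
}
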