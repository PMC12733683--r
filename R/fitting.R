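#' Control settings for kinetic model fitting
#'
#' @param ftol Relative tolerance on the decrease of the residual sum of
#'   squares used to declare convergence.
#' @param maxfev Maximum number of objective evaluations.
#' @param n_starts Number of deterministic multi-start initialisations
#'   (the data-driven start plus `n_starts - 1` jittered variants) used as a
#'   guard against local minima.
#'
#' @return A list of control settings.
#' @export
kinetics_control <- function(ftol = 1e-10, maxfev = 10000, n_starts = 5) {
  stopifnot(ftol > 0, maxfev >= 1, n_starts >= 1)
  list(ftol = ftol, maxfev = maxfev, n_starts = n_starts)
}

# Fixed multiplicative perturbations applied to the data-driven start.
# Deterministic by construction: no RNG is consumed during fitting.
start_jitter <- function(n_starts) {
  base <- rbind(
    c(1.00, 1.00, 1.00),
    c(0.50, 1.10, 1.60),
    c(2.00, 0.95, 0.60),
    c(0.80, 1.30, 2.00),
    c(1.50, 1.05, 0.75)
  )
  base[rep_len(seq_len(nrow(base)), n_starts), , drop = FALSE]
}

check_timecourse_frame <- function(data, response, allow_constant = FALSE) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  need <- c("time_h", response)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("`data` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- is.finite(data$time_h) & is.finite(data[[response]])
  data <- data[keep, , drop = FALSE]
  if (any(data$time_h < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(data[[response]] < 0)) {
    stop("negative ", response, " values are not allowed", call. = FALSE)
  }
  if (length(unique(data$time_h)) < 4) {
    stop("at least 4 distinct time points with ", response,
         " values are required", call. = FALSE)
  }
  if (!allow_constant && stats::sd(data[[response]]) == 0) {
    stop("degenerate data: ", response, " is constant", call. = FALSE)
  }
  data
}

mean_by_time <- function(data, response) {
  agg <- stats::aggregate(data[[response]], by = list(time_h = data$time_h),
                          FUN = mean)
  names(agg)[2] <- response
  agg[order(agg$time_h), , drop = FALSE]
}

fit_standard_errors <- function(fit) {
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  if (is.null(se)) {
    se <- rep(NA_real_, length(stats::coef(fit)))
    names(se) <- names(stats::coef(fit))
  }
  se
}

new_kinetic_fit <- function(subclass, params, estimate, data, response,
                            fitted, converged, flags, extra = list()) {
  obs <- data[[response]]
  res <- obs - fitted
  if (stats::sd(obs) == 0) {
    # e.g. product stuck at P0: the null-production fit is legitimate but
    # variance explained is undefined
    r2 <- NA_real_
    flags <- c(flags, "constant_response")
  } else {
    r2 <- r_squared(obs, fitted)
  }
  out <- c(list(
    params = params,
    estimate = estimate,
    r_squared = r2,
    residuals = res,
    fitted = fitted,
    converged = converged,
    n_obs = length(obs),
    flags = flags,
    data = tibble::as_tibble(data),
    response = response,
    ci = NULL
  ), extra)
  structure(out, class = c(subclass, "kinetic_fit"))
}

# Best nlsLM fit over a deterministic set of starting values.
multistart_nlsLM <- function(formula, data, starts, lower, control) {
  ctl <- minpack.lm::nls.lm.control(ftol = control$ftol,
                                    maxfev = control$maxfev,
                                    maxiter = min(1024, control$maxfev))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      withCallingHandlers(
        minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                          control = ctl),
        warning = function(w) {
          # iteration-limit chatter from unlucky starts; convergence is
          # reported through the fit's `converged` field instead
          if (grepl("lmdif|lmder|iteration", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best)) {
      best <- fit
    }
  }
  best
}

#' Fit the logistic growth model to biomass observations
#'
#' Stage one of the two-stage kinetic analysis: nonlinear least-squares
#' estimation of (X0, Xmax, mu_max) by minimising the sum of squared
#' deviations between observed biomass and the closed-form logistic curve.
#' Replicates are pooled as independent observations by default; set
#' `average_replicates = TRUE` to average per time point before fitting.
#'
#' Starting values are data-driven: X0 from the earliest observed biomass,
#' Xmax from 1.05 times the maximum, mu_max from the log-linear slope over
#' the first three time points; a fixed set of multiplicative perturbations
#' of that start guards against local minima. All parameters are bounded
#' below by a small positive value.
#'
#' @param data A data frame with numeric columns `time_h` and `biomass`
#'   (a `replicate` column, if present, is used by `average_replicates` and
#'   `truncate_at_peak`). Long format, one row per replicate-time.
#' @param average_replicates Average replicate biomass per time point before
#'   fitting instead of pooling. Default `FALSE` (pooling).
#' @param truncate_at_peak Drop observations after the time of maximum mean
#'   biomass before fitting. Useful when late-time biomass declines (e.g.
#'   lysis or stress die-off), which a monotone logistic cannot represent.
#'   Default `FALSE`.
#' @param control A [kinetics_control()] list.
#'
#' @return An object of class `logistic_fit` with components `params`
#'   (a [growth_params()]), `r_squared`, `residuals`, `fitted`, `converged`,
#'   `n_obs`, `flags` and the data used. Supports [generics::tidy()],
#'   [generics::glance()], [generics::augment()] and
#'   [ggplot2::autoplot()].
#' @examples
#' sc <- default_scenarios()$heat_stress
#' tc <- simulate_timecourse(sc)
#' fit <- fit_logistic(tc)
#' fit$params$mu_max
#' @export
fit_logistic <- function(data, average_replicates = FALSE,
                         truncate_at_peak = FALSE,
                         control = kinetics_control()) {
  data <- check_timecourse_frame(data, "biomass")
  means <- mean_by_time(data, "biomass")
  if (truncate_at_peak) {
    t_peak <- means$time_h[which.max(means$biomass)]
    data <- data[data$time_h <= t_peak, , drop = FALSE]
    data <- check_timecourse_frame(data, "biomass")
    means <- mean_by_time(data, "biomass")
  }
  fit_data <- if (average_replicates) means else data

  # data-driven start
  x_first <- max(means$biomass[1], 1e-6)
  x_max0 <- 1.05 * max(data$biomass)
  head3 <- means[seq_len(min(3, nrow(means))), ]
  mu0 <- tryCatch({
    sl <- stats::coef(stats::lm(log(pmax(head3$biomass, 1e-12)) ~
                                  head3$time_h))[2]
    if (!is.finite(sl) || sl <= 0) 0.1 else unname(sl)
  }, error = function(e) 0.1)
  base_start <- c(X0 = min(x_first, 0.9 * x_max0), Xmax = x_max0,
                  mu_max = mu0)

  jit <- start_jitter(control$n_starts)
  starts <- lapply(seq_len(nrow(jit)), function(i) {
    st <- base_start * jit[i, ]
    st[["X0"]] <- min(st[["X0"]], 0.9 * st[["Xmax"]])
    as.list(st)
  })

  fit <- multistart_nlsLM(
    biomass ~ Xmax / (1 + ((Xmax - X0) / X0) * exp(-mu_max * time_h)),
    data = fit_data, starts = starts,
    lower = c(X0 = 1e-9, Xmax = 1e-9, mu_max = 1e-9),
    control = control
  )
  if (is.null(fit)) {
    stop("logistic fit failed from every starting value", call. = FALSE)
  }

  est <- stats::coef(fit)
  converged <- isTRUE(fit$convInfo$isConv)
  gp <- growth_params(X0 = est[["X0"]], Xmax = est[["Xmax"]],
                      mu_max = est[["mu_max"]])
  fitted_all <- logistic_solution(gp, data$time_h)

  flags <- character()
  res <- data$biomass - fitted_all
  late <- data$time_h == max(data$time_h)
  if (mean(res[late]) < -2 * stats::sd(res) && sum(!late) > 2) {
    flags <- c(flags, "systematic_late_residuals")
  }

  new_kinetic_fit("logistic_fit", gp, est, data, "biomass", fitted_all,
                  converged, flags,
                  extra = list(se = fit_standard_errors(fit),
                               average_replicates = average_replicates,
                               truncate_at_peak = truncate_at_peak))
}

#' Fit the Luedeking-Piret model to product observations
#'
#' Stage two of the two-stage kinetic analysis: least-squares estimation of
#' (P0, alpha, beta) with the logistic growth parameters held fixed at the
#' stage-one estimates. The fitted curve is the exact integral of
#' dP/dt = alpha X + beta dX/dt along the logistic trajectory
#' (see [lp_solution()]).
#'
#' Starting values: P0 from the earliest observed product; alpha and beta
#' from ordinary least squares on the rate form, using finite-difference
#' product rates against the fitted biomass curve. P0 is bounded below by
#' zero; alpha and beta are unbounded, so negative estimates are possible
#' and are flagged rather than clipped.
#'
#' @param data A data frame with numeric columns `time_h` and `product`
#'   (long format, one row per replicate-time).
#' @param growth A [growth_params()] object, normally from a converged
#'   [fit_logistic()] stage.
#' @inheritParams fit_logistic
#'
#' @return An object of class `lp_fit` with the same components as
#'   [fit_logistic()] (with `params` a [product_params()]), plus the
#'   `growth` parameters used.
#' @examples
#' tc <- simulate_timecourse(default_scenarios()$heat_stress)
#' gfit <- fit_logistic(tc)
#' pfit <- fit_luedeking_piret(tc, gfit$params)
#' classify_association(pfit$params)
#' @export
fit_luedeking_piret <- function(data, growth, average_replicates = FALSE,
                                control = kinetics_control()) {
  if (!inherits(growth, "growth_params")) {
    growth <- do.call(growth_params, as.list(growth)[c("X0", "Xmax", "mu_max")])
  }
  data <- check_timecourse_frame(data, "product", allow_constant = TRUE)
  means <- mean_by_time(data, "product")
  fit_data <- if (average_replicates) means else data

  # regressors of the integrated model, linear in (P0, alpha, beta)
  add_regressors <- function(d) {
    d$x_gain <- logistic_solution(growth, d$time_h) - growth$X0
    d$x_integral <- (growth$Xmax / growth$mu_max) *
      log_logistic_denominator(growth, d$time_h)
    d
  }
  fit_data <- add_regressors(fit_data)

  # rate-form OLS start via finite differences of the mean product curve
  p0_0 <- max(means$product[1], 0)
  ab0 <- tryCatch({
    tm <- means$time_h
    dp <- diff(means$product) / diff(tm)
    t_mid <- (tm[-1] + tm[-length(tm)]) / 2
    x_mid <- logistic_solution(growth, t_mid)
    dx_mid <- logistic_rate(growth, x_mid)
    cf <- stats::coef(stats::lm(dp ~ 0 + x_mid + dx_mid))
    c(alpha = unname(cf[["x_mid"]]), beta = unname(cf[["dx_mid"]]))
  }, error = function(e) c(alpha = 0.01, beta = 0.1))
  ab0[!is.finite(ab0)] <- 0.01

  jit <- start_jitter(control$n_starts)
  starts <- lapply(seq_len(nrow(jit)), function(i) {
    list(P0 = p0_0 * jit[i, 1], alpha = ab0[["alpha"]] * jit[i, 2],
         beta = ab0[["beta"]] * jit[i, 3])
  })

  fit <- multistart_nlsLM(
    product ~ P0 + beta * x_gain + alpha * x_integral,
    data = fit_data, starts = starts,
    lower = c(P0 = 0, alpha = -Inf, beta = -Inf),
    control = control
  )
  if (is.null(fit)) {
    stop("Luedeking-Piret fit failed from every starting value",
         call. = FALSE)
  }

  est <- stats::coef(fit)
  converged <- isTRUE(fit$convInfo$isConv)
  pp <- product_params(P0 = est[["P0"]], alpha = est[["alpha"]],
                       beta = est[["beta"]])
  fitted_all <- lp_solution(growth, pp, data$time_h)

  # The integrated model is linear in (P0, alpha, beta), so
  # heteroscedasticity-robust sandwich standard errors (HC3, leverage-
  # corrected for the small per-condition sample) stay honest under the
  # multiplicative (constant-CV) noise typical of OD and colorimetric
  # measurements.
  se <- {
    M <- cbind(P0 = 1, alpha = fit_data$x_integral, beta = fit_data$x_gain)
    r <- fit_data$product -
      (pp$P0 + pp$beta * fit_data$x_gain + pp$alpha * fit_data$x_integral)
    n <- nrow(M)
    bread <- tryCatch(solve(crossprod(M)), error = function(e) NULL)
    if (is.null(bread) || n <= ncol(M)) {
      fit_standard_errors(fit)
    } else {
      lev <- rowSums((M %*% bread) * M)
      V <- bread %*% crossprod(M * as.numeric(r) / (1 - lev)) %*% bread
      sqrt(diag(V))[names(est)]
    }
  }

  flags <- character()
  if (pp$alpha < 0) flags <- c(flags, "negative_alpha")
  if (pp$beta < 0) flags <- c(flags, "negative_beta")

  new_kinetic_fit("lp_fit", pp, est, data, "product", fitted_all,
                  converged, flags,
                  extra = list(se = se,
                               df_residual = nrow(fit_data) - 3L,
                               growth = growth,
                               average_replicates = average_replicates))
}

#' Coefficient of determination
#'
#' R-squared as 1 - SS_res / SS_tot, with the total sum of squares taken
#' about the mean of the observations. This is the standard fit-quality
#' measure for nonlinear curve fits; it can be negative for fits worse than
#' the mean-only model.
#'
#' @param observed Numeric vector of observations.
#' @param predicted Numeric vector of model predictions, same length.
#'
#' @return A length-1 numeric, at most 1.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4)) # 0.5
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have the same length", call. = FALSE)
  }
  if (length(observed) < 2) {
    stop("at least 2 observations are required", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("degenerate data: observed values are all identical", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Case-resampling bootstrap intervals for the two-stage fit
#'
#' Resamples replicate-time observations with replacement, refits the
#' logistic stage and (when a usable `product` column is present) the
#' Luedeking-Piret stage on each resample, and returns percentile
#' confidence intervals for every parameter. Resamples on which either
#' stage fails are dropped and counted in the reported failure fraction.
#'
#' @param data A long-format data frame as for [fit_logistic()]; a
#'   `product` column with at least 4 finite values enables the second
#'   stage.
#' @param n_boot Number of bootstrap resamples (at least 100).
#' @param seed Integer seed; results are fully determined by it.
#' @param level Confidence level, default 0.95.
#' @inheritParams fit_logistic
#'
#' @return A tibble with columns `term`, `estimate` (full-data fit),
#'   `conf.low`, `conf.high`, plus attributes `failure_fraction`, `level`
#'   and `n_boot`.
#' @examples
#' tc <- simulate_timecourse(default_scenarios()$normal)
#' bootstrap_ci(tc, n_boot = 100, seed = 7)
#' @export
bootstrap_ci <- function(data, n_boot = 200, seed, level = 0.95,
                         control = kinetics_control()) {
  stopifnot(is.numeric(n_boot), n_boot >= 100)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(level > 0, level < 1)

  has_product <- "product" %in% names(data) &&
    sum(is.finite(data$product)) >= 4

  fit_both <- function(d) {
    g <- fit_logistic(d, control = control)
    est <- g$estimate
    if (has_product) {
      p <- fit_luedeking_piret(d, g$params, control = control)
      est <- c(est, p$estimate)
    }
    est
  }

  full <- fit_both(data)
  draws <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(data), replace = TRUE)
      tryCatch(fit_both(data[idx, , drop = FALSE]), error = function(e) NULL)
    })
  })
  ok <- !vapply(draws, is.null, logical(1))
  mat <- do.call(rbind, draws[ok])
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(mat, 2, stats::quantile, probs = probs, names = FALSE)

  out <- tibble::tibble(
    term = names(full),
    estimate = unname(full),
    conf.low = qs[1, ],
    conf.high = qs[2, ]
  )
  attr(out, "failure_fraction") <- 1 - mean(ok)
  attr(out, "level") <- level
  attr(out, "n_boot") <- n_boot
  out
}
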