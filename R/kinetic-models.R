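#' Logistic growth rate
#'
#' Instantaneous biomass growth rate dX/dt = mu_max * (1 - X/Xmax) * X.
#'
#' @param growth A [growth_params()] object.
#' @param X Biomass concentration(s), non-negative; vectorised.
#'
#' @return Growth rate(s) in concentration units per hour.
#' @examples
#' gp <- growth_params(0.1, 10, 0.5)
#' logistic_rate(gp, 5) # 1.25
#' @export
logistic_rate <- function(growth, X) {
  stopifnot(inherits(growth, "growth_params"), is.numeric(X))
  if (any(X < 0)) stop("biomass X must be non-negative", call. = FALSE)
  growth$mu_max * (1 - X / growth$Xmax) * X
}

#' Closed-form logistic biomass trajectory
#'
#' Biomass as a function of time for the logistic model, computed with the
#' overflow-safe parameterisation
#' X(t) = Xmax / (1 + ((Xmax - X0)/X0) * exp(-mu_max * t)),
#' algebraically identical to
#' X(t) = X0 e^{mu t} / (1 - (X0/Xmax)(1 - e^{mu t})) but stable for large
#' mu_max * t.
#'
#' @param growth A [growth_params()] object.
#' @param t Time(s) in hours, non-negative; vectorised.
#'
#' @return Biomass concentration(s); strictly increasing in `t`, bounded by
#'   `Xmax`, equal to `X0` at `t = 0`.
#' @examples
#' gp <- growth_params(0.1, 8, 0.33528)
#' logistic_solution(gp, c(0, 6, 12, 24, 48))
#' @export
logistic_solution <- function(growth, t) {
  stopifnot(inherits(growth, "growth_params"), is.numeric(t))
  if (any(t < 0)) stop("time t must be non-negative", call. = FALSE)
  r <- (growth$Xmax - growth$X0) / growth$X0
  growth$Xmax / (1 + r * exp(-growth$mu_max * t))
}

# log of D(t) = 1 - (X0/Xmax)(1 - e^{mu t}), computed without overflow:
# D = (X0/Xmax) e^{mu t} (1 + r e^{-mu t}) with r = (Xmax - X0)/X0.
log_logistic_denominator <- function(growth, t) {
  r <- (growth$Xmax - growth$X0) / growth$X0
  growth$mu_max * t + log1p(r * exp(-growth$mu_max * t)) +
    log(growth$X0 / growth$Xmax)
}

#' Luedeking-Piret production rate
#'
#' Product formation rate dP/dt = alpha * X + beta * dX/dt, where alpha * X
#' is the non-growth-associated contribution and beta * dX/dt the
#' growth-associated contribution.
#'
#' @param product A [product_params()] object.
#' @param X Biomass concentration(s), non-negative.
#' @param dXdt Biomass growth rate(s), same length as `X` (or length 1).
#'
#' @return Product formation rate(s) in g/L/h.
#' @examples
#' pp <- product_params(0, alpha = 0.3, beta = 0.4)
#' lp_rate(pp, X = 2, dXdt = 1.25)
#' @export
lp_rate <- function(product, X, dXdt) {
  stopifnot(inherits(product, "product_params"),
            is.numeric(X), is.numeric(dXdt))
  if (any(X < 0)) stop("biomass X must be non-negative", call. = FALSE)
  product$alpha * X + product$beta * dXdt
}

#' Closed-form Luedeking-Piret product trajectory
#'
#' Exact integral of dP/dt = alpha * X + beta * dX/dt along the logistic
#' biomass trajectory:
#' P(t) = P0 + beta * (X(t) - X0) + alpha * (Xmax/mu_max) * ln D(t),
#' with D(t) = 1 - (X0/Xmax)(1 - e^{mu_max t}). The growth-associated term
#' integrates to beta * (X(t) - X0); the non-growth-associated term uses
#' the identity that the time integral of X over (0, t) equals
#' (Xmax/mu_max) * ln D(t). The logarithm is evaluated through a
#' `log1p`-based rearrangement so large `mu_max * t` does not overflow.
#'
#' @param growth A [growth_params()] object.
#' @param product A [product_params()] object.
#' @param t Time(s) in hours, non-negative; vectorised.
#'
#' @return Product concentration(s) (g/L); equal to `P0` at `t = 0`.
#' @examples
#' gp <- growth_params(0.1, 6, 0.33528)
#' pp <- product_params(0.05, alpha = 0.71, beta = 0.5)
#' lp_solution(gp, pp, c(0, 24, 120))
#' @export
lp_solution <- function(growth, product, t) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(product, "product_params"), is.numeric(t))
  if (any(t < 0)) stop("time t must be non-negative", call. = FALSE)
  X <- logistic_solution(growth, t)
  product$P0 + product$beta * (X - growth$X0) +
    product$alpha * (growth$Xmax / growth$mu_max) *
      log_logistic_denominator(growth, t)
}

#' Specific production rate q_P(t)
#'
#' Product formation rate per unit biomass, (dP/dt)/X. Along the logistic
#' trajectory this has the closed form
#' q_P(t) = alpha + beta * mu_max * (1 - X(t)/Xmax),
#' which is non-increasing in time whenever alpha, beta >= 0 (growth slows
#' as the culture approaches carrying capacity) and tends to alpha as
#' X approaches Xmax.
#'
#' @inheritParams lp_solution
#'
#' @return q_P value(s) in 1/h.
#' @examples
#' gp <- growth_params(0.1, 6, 0.33528)
#' pp <- product_params(0.05, alpha = 0.71, beta = 0.5)
#' specific_production_rate(gp, pp, c(0, 24, 120))
#' @export
specific_production_rate <- function(growth, product, t) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(product, "product_params"), is.numeric(t))
  if (any(t < 0)) stop("time t must be non-negative", call. = FALSE)
  X <- logistic_solution(growth, t)
  product$alpha + product$beta * growth$mu_max * (1 - X / growth$Xmax)
}

#' Maximum specific production rate q_P,max
#'
#' For non-negative alpha and beta, q_P(t) is non-increasing, so its maximum
#' over any window starting at inoculation is attained at t = 0:
#' q_P,max = alpha + beta * mu_max * (1 - X0/Xmax).
#' If either coefficient is negative q_P need not be monotone; the maximum
#' is then located by dense-grid evaluation (step 0.01 h) over
#' `[0, t_max]` and the result carries attribute `nonmonotone = TRUE`.
#'
#' @inheritParams lp_solution
#' @param t_max Upper end (h) of the search window used when alpha or beta
#'   is negative. Default 120, a typical batch-fermentation horizon.
#'
#' @return q_P,max (1/h), a length-1 numeric. When the closed-form t = 0
#'   shortcut does not apply, attribute `nonmonotone` is set to `TRUE` and
#'   attribute `t_at_max` records the maximising time.
#' @examples
#' gp <- growth_params(0.1, 6, 0.33528)
#' pp <- product_params(0.05, alpha = 0.71, beta = 0.5)
#' max_specific_production_rate(gp, pp)
#' @export
max_specific_production_rate <- function(growth, product, t_max = 120) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(product, "product_params"),
            is.numeric(t_max), t_max > 0)
  if (product$alpha >= 0 && product$beta >= 0) {
    return(specific_production_rate(growth, product, 0))
  }
  grid <- seq(0, t_max, by = 0.01)
  q <- specific_production_rate(growth, product, grid)
  i <- which.max(q)
  structure(q[i], nonmonotone = TRUE, t_at_max = grid[i])
}

#' Classify product formation by growth association
#'
#' Partitions a Luedeking-Piret parameter pair into the classical
#' categories: `"mixed"` (partially growth-coupled) when both alpha and
#' beta are nonzero, `"growth_associated"` when only beta is,
#' `"non_growth_associated"` when only alpha is, and `"none"` otherwise.
#'
#' For a plain [product_params()] object a coefficient counts as nonzero
#' when its magnitude exceeds `tol` (an absolute threshold in the
#' coefficient's own units). For a fitted model (an `lp_fit` from
#' [fit_luedeking_piret()]) magnitude alone is not meaningful — an
#' estimate from a truly-zero coefficient is almost never exactly zero —
#' so a coefficient counts as nonzero only when it is also statistically
#' distinguishable from zero: |estimate| > max(tol, q * standard error),
#' with `q` the two-sided t quantile at level `conf` and the fit's
#' residual degrees of freedom. The default `conf = 0.999` is deliberately
#' stringent: a parsimonious label is preferred when a term contributes
#' nothing, while genuinely active terms in these designs sit far above
#' any conventional cutoff.
#'
#' @param x A [product_params()] object or an `lp_fit`.
#' @param tol Absolute floor below which a coefficient counts as zero.
#'   Default 1e-6.
#' @param ... Passed to methods.
#'
#' @return A length-1 character: one of `"mixed"`, `"growth_associated"`,
#'   `"non_growth_associated"`, `"none"`.
#' @examples
#' classify_association(product_params(0, alpha = 0.2, beta = 0.5)) # mixed
#' classify_association(product_params(0, alpha = 0, beta = 0.5))
#' @export
classify_association <- function(x, tol = 1e-6, ...) {
  UseMethod("classify_association")
}

association_label <- function(a, b) {
  if (a && b) "mixed"
  else if (b) "growth_associated"
  else if (a) "non_growth_associated"
  else "none"
}

#' @rdname classify_association
#' @export
classify_association.product_params <- function(x, tol = 1e-6, ...) {
  stopifnot(is.numeric(tol), length(tol) == 1L, tol > 0)
  association_label(abs(x$alpha) > tol, abs(x$beta) > tol)
}

#' @rdname classify_association
#' @param conf Two-sided confidence level defining "statistically nonzero"
#'   for fitted coefficients. Default 0.999.
#' @export
classify_association.lp_fit <- function(x, tol = 1e-6, conf = 0.999, ...) {
  stopifnot(is.numeric(tol), length(tol) == 1L, tol > 0,
            conf > 0, conf < 1)
  df <- if (!is.null(x$df_residual) && x$df_residual > 0) x$df_residual
        else Inf
  z <- stats::qt(1 - (1 - conf) / 2, df)
  nonzero <- function(term) {
    est <- x$estimate[[term]]
    se <- x$se[[term]]
    cut <- if (is.finite(se)) max(tol, z * se) else tol
    abs(est) > cut
  }
  association_label(nonzero("alpha"), nonzero("beta"))
}
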