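#' Logistic growth parameters
#'
#' Bundle and validate the three parameters of the logistic growth model
#' dX/dt = mu_max * (1 - X/Xmax) * X: the initial biomass `X0`, the carrying
#' capacity `Xmax` (same units as `X0`, typically g/L or an OD600 equivalent)
#' and the maximum specific growth rate `mu_max` (1/h).
#'
#' @param X0 Initial biomass concentration; must satisfy 0 < X0 < Xmax.
#' @param Xmax Carrying capacity (asymptotic biomass), same units as `X0`.
#' @param mu_max Maximum specific growth rate (1/h), strictly positive.
#'
#' @return An object of class `growth_params` (a named list).
#' @examples
#' growth_params(X0 = 0.1, Xmax = 6, mu_max = 0.33528)
#' @export
growth_params <- function(X0, Xmax, mu_max) {
  stopifnot(is.numeric(X0), is.numeric(Xmax), is.numeric(mu_max),
            length(X0) == 1L, length(Xmax) == 1L, length(mu_max) == 1L)
  if (!is.finite(X0) || !is.finite(Xmax) || !is.finite(mu_max)) {
    stop("growth parameters must be finite", call. = FALSE)
  }
  if (X0 <= 0) stop("X0 must be > 0", call. = FALSE)
  if (Xmax <= X0) stop("Xmax must exceed X0", call. = FALSE)
  if (mu_max <= 0) stop("mu_max must be > 0", call. = FALSE)
  structure(list(X0 = X0, Xmax = Xmax, mu_max = mu_max),
            class = "growth_params")
}

#' Luedeking-Piret product-formation parameters
#'
#' Bundle and validate the parameters of the Luedeking-Piret law
#' dP/dt = alpha * X + beta * dX/dt. Following the rate-form labelling,
#' `alpha` multiplies biomass X (the non-growth-associated term, units 1/h
#' when P and X share concentration units) and `beta` multiplies the growth
#' rate dX/dt (the growth-associated term, g product per g biomass).
#'
#' Negative `alpha` or `beta` are accepted — fitted values can legitimately
#' come out negative — but downstream reporting flags them.
#'
#' @param P0 Initial product concentration (g/L), non-negative.
#' @param alpha Non-growth-associated coefficient (1/h).
#' @param beta Growth-associated coefficient (g product / g biomass).
#'
#' @return An object of class `product_params` (a named list).
#' @examples
#' product_params(P0 = 0.05, alpha = 0.7, beta = 0.5)
#' @export
product_params <- function(P0, alpha, beta) {
  stopifnot(is.numeric(P0), is.numeric(alpha), is.numeric(beta),
            length(P0) == 1L, length(alpha) == 1L, length(beta) == 1L)
  if (!is.finite(P0) || !is.finite(alpha) || !is.finite(beta)) {
    stop("product parameters must be finite", call. = FALSE)
  }
  if (P0 < 0) stop("P0 must be >= 0", call. = FALSE)
  structure(list(P0 = P0, alpha = alpha, beta = beta),
            class = "product_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Logistic growth parameters\n")
  cat(sprintf("  X0     = %g\n  Xmax   = %g\n  mu_max = %g 1/h\n",
              x$X0, x$Xmax, x$mu_max))
  invisible(x)
}

#' @export
print.product_params <- function(x, ...) {
  cat("Luedeking-Piret product parameters\n")
  cat(sprintf("  P0    = %g g/L\n  alpha = %g 1/h\n  beta  = %g\n",
              x$P0, x$alpha, x$beta))
  invisible(x)
}
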