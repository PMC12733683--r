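# Independent numerical oracle: integrate the coupled rate equations
#   dX/dt = mu_max (1 - X/Xmax) X
#   dP/dt = alpha X + beta dX/dt
# with a high-order Runge-Kutta solver, independent of the closed forms.
rk_oracle <- function(gp, pp, times) {
  rhs <- function(t, y, parms) {
    dx <- parms$mu * (1 - y[1] / parms$K) * y[1]
    dp <- parms$alpha * y[1] + parms$beta * dx
    list(c(dx, dp))
  }
  out <- deSolve::ode(
    y = c(X = gp$X0, P = pp$P0),
    times = sort(unique(c(0, times))),
    func = rhs,
    parms = list(mu = gp$mu_max, K = gp$Xmax, alpha = pp$alpha,
                 beta = pp$beta),
    method = "ode45", atol = 1e-13, rtol = 1e-12
  )
  out <- as.data.frame(out)
  out[match(times, out$time), , drop = FALSE]
}

# Random but reproducible parameter draws spanning realistic fermentation
# ranges.
draw_random_params <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      Xmax <- runif(1, 2, 12)
      list(
        gp = growth_params(X0 = runif(1, 0.02, 0.4), Xmax = Xmax,
                           mu_max = runif(1, 0.05, 0.5)),
        pp = product_params(P0 = runif(1, 0, 0.2),
                            alpha = runif(1, 0, 0.8),
                            beta = runif(1, 0, 1))
      )
    })
  })
}

# Printed integrated product form with coefficients in swapped roles
# (first coefficient on the biomass-gain term, second on the log term).
printed_product_form <- function(gp, a, b, t) {
  e <- exp(gp$mu_max * t)
  D <- 1 - (gp$X0 / gp$Xmax) * (1 - e)
  a * gp$X0 * (e / D - 1) + b * (gp$Xmax / gp$mu_max) * log(D)
}

# One simulated dataset and its two-stage fit, for recovery experiments.
simulate_and_fit <- function(sc, seed) {
  sc$seed <- seed
  tc <- simulate_timecourse(sc)
  g <- fit_logistic(tc)
  p <- fit_luedeking_piret(tc, g$params)
  list(tc = tc, growth = g, product = p)
}
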