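test_that("logistic rate has the right fixed points and arithmetic", {
  gp <- growth_params(X0 = 0.1, Xmax = 10, mu_max = 0.5)
  expect_identical(logistic_rate(gp, 0), 0)
  expect_identical(logistic_rate(gp, 10), 0)
  expect_equal(logistic_rate(gp, 5), 1.25)
  expect_error(logistic_rate(gp, -1), "non-negative")
})

test_that("closed-form logistic trajectory satisfies its boundary cases", {
  gp <- growth_params(X0 = 5, Xmax = 10, mu_max = 1)
  expect_equal(logistic_solution(gp, 0), 5)
  # half-capacity start reduces to Xmax * e^t / (1 + e^t)
  expect_equal(logistic_solution(gp, log(3)), 7.5)
  # overflow-safe at extreme times
  expect_equal(logistic_solution(growth_params(0.1, 8, 0.33528), 1e5), 8)
  expect_error(logistic_solution(gp, -1), "non-negative")
})

test_that("logistic trajectory is strictly increasing and bounded", {
  for (d in draw_random_params(25, seed = 101)) {
    x <- logistic_solution(d$gp, seq(0, 120, by = 2))
    expect_true(all(x >= d$gp$X0 * (1 - 1e-12) &
                      x <= d$gp$Xmax * (1 + 1e-12)))
    # strictly increasing until the curve saturates to Xmax in double
    # precision
    live <- x < d$gp$Xmax * (1 - 1e-12)
    expect_true(all(diff(x[live]) > 0))
    expect_true(all(diff(x) >= 0))
  }
})

test_that("Luedeking-Piret rate combines its two terms correctly", {
  expect_identical(lp_rate(product_params(0, 0, 0), X = 3, dXdt = 2), 0)
  expect_equal(lp_rate(product_params(0, alpha = 0.3, beta = 0), 2, 5), 0.6)
  expect_equal(lp_rate(product_params(0, alpha = 0, beta = 0.4), 2, 1.25),
               0.5)
})

test_that("product trajectory starts at P0 and reduces when alpha = 0", {
  gp <- growth_params(0.1, 6, 0.33528)
  pp <- product_params(P0 = 0.05, alpha = 0.7, beta = 0.5)
  expect_equal(lp_solution(gp, pp, 0), 0.05)

  pp0 <- product_params(P0 = 0.2, alpha = 0, beta = 0.8)
  t <- c(0, 6, 24, 48, 120)
  expect_equal(lp_solution(gp, pp0, t),
               0.2 + 0.8 * (logistic_solution(gp, t) - gp$X0))
})

test_that("closed forms agree with a Runge-Kutta oracle", {
  skip_if_not_installed("deSolve")
  times <- default_schedule()
  for (d in draw_random_params(20, seed = 202)) {
    ode <- rk_oracle(d$gp, d$pp, times)
    expect_equal(logistic_solution(d$gp, times), ode$X, tolerance = 1e-8)
    expect_equal(lp_solution(d$gp, d$pp, times), ode$P, tolerance = 1e-8)
  }
})

test_that("swapping alpha and beta reproduces the alternative integrated form", {
  t <- c(0, 3, 9, 20, 48)
  for (d in draw_random_params(10, seed = 303)) {
    a <- d$pp$alpha
    b <- d$pp$beta
    swapped <- product_params(d$pp$P0, alpha = b, beta = a)
    expect_equal(lp_solution(d$gp, swapped, t),
                 d$pp$P0 + printed_product_form(d$gp, a, b, t),
                 tolerance = 1e-10)
  }
})

test_that("specific production rate matches its limits and a finite-difference oracle", {
  gp <- growth_params(0.1, 6, 0.33528)
  pp <- product_params(0.05, alpha = 0.7, beta = 0.5)
  # plateau: X -> Xmax so q_P -> alpha
  expect_equal(specific_production_rate(gp, pp, 1e5), pp$alpha)
  expect_equal(specific_production_rate(gp, pp, 0),
               pp$alpha + pp$beta * gp$mu_max * (1 - gp$X0 / gp$Xmax))

  h <- 1e-5
  for (t in c(1, 10, 40, 90)) {
    fd <- (lp_solution(gp, pp, t + h) - lp_solution(gp, pp, t - h)) /
      (2 * h) / logistic_solution(gp, t)
    expect_equal(specific_production_rate(gp, pp, t), fd,
                 tolerance = 1e-6)
  }
})

test_that("maximum specific production rate is the t = 0 value for non-negative coefficients", {
  gp <- growth_params(0.1, 6, 0.5)
  expect_equal(
    max_specific_production_rate(gp, product_params(0, alpha = 0.3, beta = 0)),
    0.3)
  gp2 <- growth_params(X0 = 1, Xmax = 10, mu_max = 0.5)
  expect_equal(
    max_specific_production_rate(gp2, product_params(0, alpha = 0, beta = 1)),
    0.45)
  # grid-search oracle
  pp <- product_params(0.05, alpha = 0.7, beta = 0.5)
  grid <- seq(0, 120, by = 0.01)
  expect_equal(as.numeric(max_specific_production_rate(gp, pp)),
               max(specific_production_rate(gp, pp, grid)),
               tolerance = 1e-12)
})

test_that("negative coefficients trigger grid search with a non-monotonicity flag", {
  gp <- growth_params(0.1, 6, 0.33528)
  pp <- product_params(0.05, alpha = 0.5, beta = -0.3)
  q <- max_specific_production_rate(gp, pp)
  expect_true(attr(q, "nonmonotone"))
  grid <- seq(0, 120, by = 0.01)
  expect_equal(as.numeric(q),
               max(specific_production_rate(gp, pp, grid)))
})

test_that("growth-association classification covers all four categories", {
  expect_identical(
    classify_association(product_params(0, alpha = 0.2, beta = 0.5)),
    "mixed")
  expect_identical(
    classify_association(product_params(0, alpha = 0, beta = 0.5)),
    "growth_associated")
  expect_identical(
    classify_association(product_params(0, alpha = 0.2, beta = 0)),
    "non_growth_associated")
  expect_identical(
    classify_association(product_params(0, alpha = 0, beta = 0)),
    "none")
  # threshold is respected in the coefficient's own units
  expect_identical(
    classify_association(product_params(0, alpha = 1e-8, beta = 0.5),
                         tol = 1e-6),
    "growth_associated")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(growth_params(0, 5, 0.3), "X0")
  expect_error(growth_params(6, 5, 0.3), "Xmax")
  expect_error(growth_params(0.1, 5, -1), "mu_max")
  expect_error(product_params(-0.1, 0.2, 0.3), "P0")
  expect_silent(product_params(0, -0.2, -0.3)) # negative coefficients allowed
})
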