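noise_free_tc <- function(sc) {
  sc$noise_cv <- 0
  simulate_timecourse(sc)
}

test_that("logistic fit recovers exact parameters from noise-free data", {
  gp <- growth_params(X0 = 0.1, Xmax = 8, mu_max = 0.33528)
  sc <- scenario(gp, product_params(0.05, 0.3, 0.5), noise_cv = 0, seed = 1)
  fit <- fit_logistic(simulate_timecourse(sc))
  expect_true(fit$converged)
  expect_equal(fit$params$X0, gp$X0, tolerance = 1e-4)
  expect_equal(fit$params$Xmax, gp$Xmax, tolerance = 1e-4)
  expect_equal(fit$params$mu_max, gp$mu_max, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("Luedeking-Piret fit recovers exact parameters from noise-free data", {
  gp <- growth_params(0.1, 6, 0.33528)
  pp <- product_params(P0 = 0.05, alpha = 0.7, beta = 0.5)
  sc <- scenario(gp, pp, noise_cv = 0, seed = 1)
  tc <- simulate_timecourse(sc)
  fit <- fit_luedeking_piret(tc, gp)
  expect_true(fit$converged)
  expect_equal(fit$params$P0, pp$P0, tolerance = 1e-4)
  expect_equal(fit$params$alpha, pp$alpha, tolerance = 1e-4)
  expect_equal(fit$params$beta, pp$beta, tolerance = 1e-4)
})

test_that("noisy data still yield accurate growth and product estimates", {
  sc <- default_scenarios()$normal
  r <- simulate_and_fit(sc, seed = 7)
  expect_lt(abs(r$growth$params$mu_max / sc$growth$mu_max - 1), 0.10)
  expect_lt(abs(r$product$params$alpha / sc$product$alpha - 1), 0.25)
  expect_lt(abs(r$product$params$beta / sc$product$beta - 1), 0.25)
  expect_identical(classify_association(r$product), "mixed")
})

test_that("returned estimates never do worse than the generating truth", {
  scs <- default_scenarios()
  for (lbl in names(scs)) {
    sc <- scs[[lbl]]
    for (s in 1:10) {
      r <- simulate_and_fit(sc, seed = 4000 + s)
      tc <- r$tc
      rss_g_est <- sum(r$growth$residuals^2)
      rss_g_true <- sum((tc$biomass -
                           logistic_solution(sc$growth, tc$time_h))^2)
      expect_lte(rss_g_est, rss_g_true * (1 + 1e-8))
      rss_p_est <- sum(r$product$residuals^2)
      rss_p_true <- sum((tc$product -
                           lp_solution(r$growth$params, sc$product,
                                       tc$time_h))^2)
      expect_lte(rss_p_est, rss_p_true * (1 + 1e-6))
    }
  }
})

test_that("estimates are invariant to observation order", {
  tc <- simulate_timecourse(default_scenarios()$heat_stress)
  shuffled <- withr::with_seed(9, tc[sample.int(nrow(tc)), ])
  f1 <- fit_logistic(tc)
  f2 <- fit_logistic(shuffled)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-8)
  p1 <- fit_luedeking_piret(tc, f1$params)
  p2 <- fit_luedeking_piret(shuffled, f1$params)
  # agreement up to the optimizer's stopping tolerance
  expect_equal(p1$estimate, p2$estimate, tolerance = 1e-4)
})

test_that("degenerate and undersized inputs are rejected with clear errors", {
  tc <- simulate_timecourse(default_scenarios()$normal)
  expect_error(fit_logistic(tc[tc$time_h <= 24, ]), "4 distinct time points")
  flat <- tc
  flat$biomass <- 2
  expect_error(fit_logistic(flat), "degenerate")
  expect_error(fit_logistic(dplyr::select(tc, -"biomass")), "missing")
})

test_that("constant product fits as null production", {
  sc <- default_scenarios()$normal
  tc <- noise_free_tc(sc)
  tc$product <- 0.05
  fit <- fit_luedeking_piret(tc, sc$growth)
  expect_equal(fit$params$alpha, 0, tolerance = 1e-8)
  expect_equal(fit$params$beta, 0, tolerance = 1e-8)
  expect_identical(classify_association(fit$params), "none")
  expect_true("constant_response" %in% fit$flags)
  expect_true(is.na(fit$r_squared))
})

test_that("r_squared follows the coefficient-of-determination definition", {
  expect_identical(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(1, 4, 2, 5)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(1, 1), c(1, 2)), "identical")
  expect_error(r_squared(1:3, 1:4), "length")
})

test_that("bootstrap intervals are seed-deterministic and collapse on exact data", {
  tc <- simulate_timecourse(default_scenarios()$normal)
  ci1 <- bootstrap_ci(tc, n_boot = 100, seed = 21)
  ci2 <- bootstrap_ci(tc, n_boot = 100, seed = 21)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$conf.low <= ci1$estimate + 1e-12))
  expect_true(all(ci1$estimate <= ci1$conf.high + 1e-12))
  expect_error(bootstrap_ci(tc, n_boot = 50, seed = 1), "100")

  exact <- noise_free_tc(default_scenarios()$normal)
  ci0 <- bootstrap_ci(exact, n_boot = 100, seed = 5)
  expect_lt(max(ci0$conf.high - ci0$conf.low), 1e-5)
})

test_that("bootstrap intervals for mu_max have near-nominal coverage", {
  sc <- default_scenarios()$heat_stress
  covered <- vapply(1:100, function(s) {
    sc$seed <- 7000 + s
    tc <- simulate_timecourse(sc)
    tb <- tc[, c("condition", "replicate", "time_h", "biomass")]
    ci <- bootstrap_ci(tb, n_boot = 100, seed = 100 + s)
    row <- ci[ci$term == "mu_max", ]
    row$conf.low <= sc$growth$mu_max && sc$growth$mu_max <= row$conf.high
  }, logical(1))
  expect_gte(mean(covered), 0.85)
  expect_lte(mean(covered), 0.99)
})

test_that("truncate-at-peak rescues fits on cultures with late die-off", {
  gp <- growth_params(0.1, 6, 0.33528)
  sc <- scenario(gp, product_params(0.05, 0.7, 0.5), seed = 31,
                 decay_rate = 0.02, decay_onset = 48)
  tc <- simulate_timecourse(sc)
  plain <- fit_logistic(tc)
  trunc <- fit_logistic(tc, truncate_at_peak = TRUE)
  err_plain <- abs(plain$params$mu_max / gp$mu_max - 1)
  err_trunc <- abs(trunc$params$mu_max / gp$mu_max - 1)
  expect_lt(err_trunc, err_plain)
  expect_lt(err_trunc, 0.15)
})

test_that("broom-style accessors expose the fit in tidy form", {
  tc <- simulate_timecourse(default_scenarios()$normal)
  fit <- fit_logistic(tc)
  td <- tidy(fit)
  expect_identical(td$term, c("X0", "Xmax", "mu_max"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_identical(gl$model, "logistic")
  expect_identical(gl$n.obs, fit$n_obs)
  aug <- augment(fit)
  expect_equal(aug$.fitted + aug$.resid, tc$biomass)
  expect_s3_class(autoplot(fit), "ggplot")
})
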