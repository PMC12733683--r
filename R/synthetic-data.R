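#' Sampling schedule of the emulated shake-flask experiment
#'
#' Eight sampling times (h) spanning early exponential growth through late
#' stationary phase in a 5-day batch culture.
#'
#' @return A numeric vector of hours.
#' @export
default_schedule <- function() c(6, 12, 24, 36, 48, 72, 96, 120)

#' Define a simulation scenario
#'
#' A scenario bundles everything needed to generate one replicated noisy
#' time course: the generating kinetic parameters, the sampling schedule,
#' the number of replicates, the measurement-noise level and a seed.
#' Measurement noise is multiplicative Gaussian — each observation is the
#' noise-free curve value times an independent N(1, noise_cv) factor,
#' truncated below at zero — which mimics the roughly constant coefficient
#' of variation of optical-density and colorimetric assays.
#'
#' An optional die-off contamination mode (`decay_rate > 0`) multiplies the
#' mean biomass by an exponential decay after `decay_onset` hours, emulating
#' late-time biomass decline under stress that a monotone logistic cannot
#' represent; it exists to exercise the fitter's `truncate_at_peak` option
#' and is off by default.
#'
#' @param growth A [growth_params()] object.
#' @param product A [product_params()] object.
#' @param schedule Strictly increasing sampling times (h), all non-negative.
#' @param n_replicates Number of replicate cultures (>= 1).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (>= 0).
#' @param seed Integer seed for the noise draws.
#' @param label Condition label carried into generated tables.
#' @param decay_rate Exponential biomass decay rate (1/h) applied after
#'   `decay_onset`; 0 disables the contamination mode.
#' @param decay_onset Time (h) at which decay starts (required when
#'   `decay_rate > 0`).
#'
#' @return An object of class `scenario`.
#' @examples
#' scenario(growth_params(0.1, 6, 0.335), product_params(0.05, 0.7, 0.5),
#'          label = "heat_stress", seed = 1)
#' @export
scenario <- function(growth, product, schedule = default_schedule(),
                     n_replicates = 3, noise_cv = 0.03, seed = 1,
                     label = "condition", decay_rate = 0,
                     decay_onset = NULL) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(product, "product_params"),
            is.numeric(schedule), length(schedule) >= 1,
            n_replicates >= 1, noise_cv >= 0,
            is.character(label), length(label) == 1L,
            decay_rate >= 0)
  if (any(schedule < 0) || any(diff(schedule) <= 0)) {
    stop("schedule must be strictly increasing and non-negative",
         call. = FALSE)
  }
  if (decay_rate > 0 && is.null(decay_onset)) {
    stop("decay_onset is required when decay_rate > 0", call. = FALSE)
  }
  structure(list(growth = growth, product = product, schedule = schedule,
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, seed = as.integer(seed),
                 label = label, decay_rate = decay_rate,
                 decay_onset = decay_onset),
            class = "scenario")
}

#' Default two-temperature scenarios
#'
#' The two study conditions emulated by the generator: fermentation under
#' heat stress (30 degrees C) and under the strain's optimal temperature
#' (15 degrees C), sampled at eight time points over 120 h with three
#' replicates and 3% multiplicative measurement noise.
#'
#' The maximum specific growth rates are the reported fitted values for the
#' two temperatures: 0.33528 1/h under heat stress and 0.13286 1/h under
#' normal culture. The heat-stress non-growth-associated coefficient alpha
#' is chosen so that the maximum specific production rate
#' q_P,max = alpha + beta * mu_max * (1 - X0/Xmax) equals the reported
#' 0.87670 1/h. The remaining parameters (X0 = 0.1, Xmax = 6 under heat
#' stress and 10 under normal culture, P0 = 0.05 g/L, beta = 0.5) are
#' package defaults chosen to give well-conditioned fits on the 8-point
#' schedule; the lower carrying capacity under heat stress mirrors the
#' growth inhibition seen at the higher temperature.
#'
#' @param noise_cv Measurement-noise coefficient of variation for both
#'   scenarios. Default 0.03.
#' @param seed Base seed stored in each scenario. Default 1.
#'
#' @return A named list with elements `heat_stress` and `normal`, each a
#'   [scenario()].
#' @examples
#' scs <- default_scenarios()
#' scs$heat_stress$growth$mu_max / scs$normal$growth$mu_max # about 2.52
#' @export
default_scenarios <- function(noise_cv = 0.03, seed = 1) {
  q_p_max <- 0.87670
  beta <- 0.5

  g_heat <- growth_params(X0 = 0.1, Xmax = 6, mu_max = 0.33528)
  alpha_heat <- q_p_max -
    beta * g_heat$mu_max * (1 - g_heat$X0 / g_heat$Xmax)
  p_heat <- product_params(P0 = 0.05, alpha = alpha_heat, beta = beta)

  g_norm <- growth_params(X0 = 0.1, Xmax = 10, mu_max = 0.13286)
  p_norm <- product_params(P0 = 0.05, alpha = 0.05, beta = beta)

  list(
    heat_stress = scenario(g_heat, p_heat, noise_cv = noise_cv, seed = seed,
                           label = "heat_stress"),
    normal = scenario(g_norm, p_norm, noise_cv = noise_cv, seed = seed,
                      label = "normal")
  )
}

#' Simulate one replicated noisy time course
#'
#' Evaluates the closed-form biomass and product curves at the scenario's
#' schedule, multiplies every observation by an independent Gaussian factor
#' with mean 1 and standard deviation `noise_cv` (truncated below at 0),
#' and returns a long-format tibble. Output is fully determined by the
#' scenario's seed.
#'
#' @param sc A [scenario()] object.
#'
#' @return A tibble with columns `condition`, `replicate`, `time_h`,
#'   `biomass`, `product`, ordered by (replicate, time).
#' @examples
#' simulate_timecourse(default_scenarios()$heat_stress)
#' @export
simulate_timecourse <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  t <- sc$schedule
  x_mean <- logistic_solution(sc$growth, t)
  p_mean <- lp_solution(sc$growth, sc$product, t)
  if (sc$decay_rate > 0) {
    late <- t > sc$decay_onset
    x_mean[late] <- x_mean[late] *
      exp(-sc$decay_rate * (t[late] - sc$decay_onset))
  }

  n_t <- length(t)
  out <- withr::with_seed(sc$seed, {
    purrr::map_dfr(seq_len(sc$n_replicates), function(r) {
      fx <- pmax(stats::rnorm(n_t, mean = 1, sd = sc$noise_cv), 0)
      fp <- pmax(stats::rnorm(n_t, mean = 1, sd = sc$noise_cv), 0)
      tibble::tibble(
        condition = sc$label,
        replicate = r,
        time_h = t,
        biomass = x_mean * fx,
        product = p_mean * fp
      )
    })
  })
  dplyr::arrange(out, .data$replicate, .data$time_h)
}

# Deterministic 31-adic string hash folded into [1, 2^31 - 2]; combining the
# base seed with the scenario label gives every scenario an independent
# sub-seed, and adding a scenario never perturbs the draws of another.
derive_subseed <- function(seed, label) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Simulate a multi-condition study
#'
#' Generates one time course per scenario with independent sub-seeds
#' derived deterministically from `seed` and each scenario's label, and
#' row-binds them into a single long table.
#'
#' @param scenarios A non-empty named list of [scenario()] objects (names
#'   default to each scenario's label).
#' @param seed Integer base seed for the whole study.
#'
#' @return A tibble in the same format as [simulate_timecourse()], one
#'   block per condition.
#' @examples
#' simulate_study(default_scenarios(), seed = 42)
#' @export
simulate_study <- function(scenarios, seed) {
  stopifnot(is.list(scenarios), length(scenarios) >= 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  purrr::map_dfr(scenarios, function(sc) {
    stopifnot(inherits(sc, "scenario"))
    sc$seed <- derive_subseed(seed, sc$label)
    simulate_timecourse(sc)
  })
}
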