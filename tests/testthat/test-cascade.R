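exact_cascade_sweeps <- function(b_slope, b_int, a_slope, a_int,
                                 times = c(0, 8, 16, 24, 32),
                                 temp = seq(60, 110, 5), treatment = "C") {
  lapply(times, function(tp) {
    b <- b_slope * tp + b_int
    a <- a_slope * b + a_int
    exact_lioumbas_sweep(a, b, temp, t_P = tp, treatment = treatment,
                         sample_id = sprintf("%s-%g", treatment, tp))
  })
}

test_that("exact linear drifts are recovered with r2 = 1", {
  cm <- oil_cascade(exact_cascade_sweeps(-0.0006, -0.1964, -42.57, -2.04))
  expect_equal(cm$b_trend$slope, -0.0006, tolerance = 1e-9)
  expect_equal(cm$b_trend$intercept, -0.1964, tolerance = 1e-9)
  expect_equal(cm$a_of_b$slope, -42.57, tolerance = 1e-7)
  expect_equal(cm$a_of_b$intercept, -2.04, tolerance = 1e-6)
  expect_equal(cm$b_trend$r2, 1, tolerance = 1e-12)
  expect_equal(cm$a_of_b$r2, 1, tolerance = 1e-12)

  expect_error(build_cascade(data.frame(t_P = c(0, 8), a = c(6, 7),
                                        b = c(-0.19, -0.2))),
               class = "oilcascade_validation_error")
})

test_that("cascade prediction composes the three fitted relations", {
  cm <- oil_cascade(exact_cascade_sweeps(-0.0006, -0.1964, -42.57, -2.04))
  # direct arithmetic: b(16) = -0.206, a = -42.57*(-0.206) - 2.04
  b16 <- -0.0006 * 16 - 0.1964
  a16 <- -42.57 * b16 - 2.04
  expect_equal(predict(cm, 16, 60), exp(a16 + b16 * log(60)^2),
               ignore_attr = TRUE)
  expect_equal(as.numeric(predict(cm, 16, 60)), 26.47, tolerance = 0.005 / 26.47)
  # thinner at higher temperature while b < 0
  expect_lt(as.numeric(predict(cm, 16, 100)), as.numeric(predict(cm, 16, 60)))
  expect_error(predict(cm, 16, -10), class = "oilcascade_domain_error")
})

test_that("cascade round-trips the per-timepoint fits when drifts are exact", {
  sweeps <- exact_cascade_sweeps(-0.0007, -0.1950, -41.59, -1.89)
  cm <- oil_cascade(sweeps)
  for (s in sweeps) {
    per_fit <- fit_lioumbas(s)
    mu_cascade <- as.numeric(predict(cm, attr(s, "t_P"), s$temperature_C))
    mu_direct <- predict(per_fit, s$temperature_C)
    expect_equal(mu_cascade, mu_direct, tolerance = 1e-9)
  }
})

test_that("extrapolation beyond the fitted time range is flagged", {
  cm <- oil_cascade(exact_cascade_sweeps(-0.0006, -0.1964, -42.57, -2.04))
  expect_warning(mu <- predict(cm, 40, 60), "extrapolating")
  expect_true(attr(mu, "extrapolated"))
  expect_silent(mu_in <- predict(cm, 32, 60))
  expect_false(attr(mu_in, "extrapolated"))
})

test_that("noisy per-timepoint b values still recover the drift slope", {
  set.seed(11)
  times <- c(0, 8, 16, 24, 32)
  b_true <- -0.0007 * times - 0.195
  b_obs <- b_true + rnorm(5, 0, 0.002)
  tr <- fit_linear_trend(times, b_obs)
  expect_lt(abs(tr$slope - (-0.0007)) / 0.0007, 0.2)
})

test_that("trend slope signs are recovered from noisy synthetic studies", {
  cfg <- synthetic_config(seed = 23, log_noise_sd = 0.005)
  study <- generate_study(cfg)
  for (trt in cfg$treatments$name) {
    keep <- vapply(study$sweeps,
                   function(s) identical(attr(s, "treatment"), trt),
                   logical(1))
    cm <- oil_cascade(study$sweeps[keep])
    expect_lt(cm$b_trend$slope, 0)
    expect_lt(cm$a_of_b$slope, 0) # a falls as b falls toward more negative
  }
})

test_that("parity analysis reports residuals and percent deviations", {
  one <- parity_analysis(32.64, 30.33)
  expect_equal(one$residual, 2.31)
  expect_equal(round(one$deviation_pct, 2), 7.08)

  same <- parity_analysis(c(5, 10), c(5, 10))
  expect_equal(same$residual, c(0, 0))
  expect_equal(same$deviation_pct, c(0, 0))

  two <- parity_analysis(c(10, 20), c(9, 22))
  expect_equal(attr(two, "max_abs_residual"), 2)
  expect_equal(attr(two, "max_abs_deviation_pct"), 10)

  expect_error(parity_analysis(c(1, 0), c(1, 1)),
               class = "oilcascade_domain_error")
})

test_that("deviation percent is antisymmetric up to the denominator change", {
  set.seed(6)
  obs <- runif(20, 10, 40)
  calc <- obs * runif(20, 0.9, 1.1)
  fwd <- parity_analysis(obs, calc)
  rev <- parity_analysis(calc, obs)
  expect_equal(rev$deviation_pct, -fwd$deviation_pct * obs / calc)
})

test_that("the composition plane fit matches its oracle and degenerate cases", {
  set.seed(91)
  ecn <- seq(16.1, 16.3, length.out = 10)
  tpc <- seq(7, 35, length.out = 10) + rnorm(10, 0, 0.5)
  b_exact <- 0.2 - 0.024 * ecn - 0.001 * tpc
  # the narrow ECN range makes the design ill-conditioned, as in real studies;
  # recovery is exact up to that conditioning
  exact <- fit_b_on_composition(b_exact, ecn, tpc)
  expect_equal(coef(exact),
               c(intercept = 0.2, coef_ecn = -0.024, coef_tpc = -0.001),
               tolerance = 1e-6)
  expect_equal(exact$r2, 1, tolerance = 1e-9)

  # well-conditioned data: QR solution agrees with explicit normal equations
  x1 <- rnorm(10)
  x2 <- runif(10, -1, 1)
  y <- 0.3 + 0.5 * x1 - 0.2 * x2 + rnorm(10, 0, 0.05)
  noisy <- fit_b_on_composition(y, x1, x2)
  expect_equal(unname(coef(noisy)), plane_oracle(y, x1, x2),
               tolerance = 1e-10)

  flat <- fit_b_on_composition(rep(-0.2, 10), ecn, tpc)
  expect_equal(flat$coef_ecn, 0, tolerance = 1e-12)
  expect_equal(flat$coef_tpc, 0, tolerance = 1e-12)

  expect_error(fit_b_on_composition(b_exact, ecn, 2 * ecn),
               class = "oilcascade_singular_error")
})
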