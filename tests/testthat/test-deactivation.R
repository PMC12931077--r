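# Binomial multi-exponential deactivation: composition time constants,
# the tail model, and the global fit across a voltage family.

test_that("composition time constants follow the geometric f-scaling", {
  p <- deactivation_params(0.008, 5, 5)
  expect_equal(composition_time_constant(0, p), 0.008)
  expect_equal(composition_time_constant(3, p), 5)
  expect_equal(composition_time_constant(1, p), 0.2)   # tau_slow / f^2
  expect_equal(composition_time_constant(2, p), 1)     # tau_slow / f
  pf1 <- deactivation_params(0.008, 5, 1)
  expect_equal(composition_time_constant(1:3, pf1), rep(5, 3))
  expect_error(composition_time_constant(4, p), "no deactivation")
})

test_that("tail model: initial value, wild-type limit, decay", {
  p <- deactivation_params(0.008, 5, 5)
  for (ps in c(0, 0.3, 0.8))
    expect_equal(tail_mixture_model(0, p, p_s = ps, amplitude = 120),
                 120 * (1 - ps^4))
  t <- seq(0, 10, 0.01)
  expect_equal(tail_mixture_model(t, p, p_s = 0, amplitude = 50),
               50 * exp(-t / 0.008))
  y <- tail_mixture_model(t, p, p_s = 0.6, amplitude = 50)
  expect_true(all(y >= 0))
  expect_true(all(diff(y) < 0))
  expect_lt(tail_mixture_model(1e4, p, p_s = 0.6, amplitude = 50), 1e-12)
  expect_error(tail_mixture_model(-1, p), "non-negative")
})

test_that("analytic tail area matches numerical integration to 0.1%", {
  p <- deactivation_params(0.008, 5, 5)
  for (ps in c(0.2, 0.5, 0.8)) {
    analytic <- kvmix:::tail_mixture_area(p, p_s = ps, amplitude = 80)
    numeric <- stats::integrate(function(t)
      tail_mixture_model(t, p, p_s = ps, amplitude = 80),
      0, Inf, rel.tol = 1e-10)$value
    expect_lt(abs(analytic - numeric) / numeric, 1e-3)
  }
})

test_that("as p_s -> 1 the normalized decay approaches exp(-t/tau_slow)", {
  p <- deactivation_params(0.008, 5, 5)
  t <- seq(0, 15, 0.05)
  y <- tail_mixture_model(t, p, p_s = 0.999, amplitude = 1)
  expect_equal(y / y[1], exp(-t / 5), tolerance = 1e-2)
})

test_that("noise-free tail family is recovered exactly", {
  dp <- deactivation_params(0.008, 5, 5)
  spec <- tail_generator_spec(dp, p_s = c(0.8, 0.5), amplitude = c(80, 160),
                              test_voltages_mV = c(-40, 20), noise = 0,
                              duration_s = 15, seed = 1)
  fit <- global_fit_tails(gen_tail_dataset(spec))
  expect_true(fit$converged)
  expect_lt(abs(fit$parameters[["tau_slow"]] - 5) / 5, 1e-5)
  expect_lt(abs(fit$parameters[["f"]] - 5) / 5, 1e-5)
  expect_lt(abs(fit$parameters[["tau_fast"]] - 0.008) / 0.008, 1e-4)
})

test_that("shared-p_s mode fits a family generated with one p_s", {
  dp <- deactivation_params(0.008, 5, 5)
  spec <- tail_generator_spec(dp, p_s = c(0.6, 0.6), amplitude = c(80, 160),
                              test_voltages_mV = c(-40, 20), noise = 0.005,
                              duration_s = 15, seed = 8)
  fit <- global_fit_tails(gen_tail_dataset(spec), mode = "shared")
  expect_true(fit$converged)
  expect_equal(fit$parameters[["p_s"]], 0.6, tolerance = 0.05)
})

test_that("single-exponential input leaves the slow branch unconstrained", {
  dp <- deactivation_params(0.008, 5, 5)
  spec <- tail_generator_spec(dp, p_s = c(0, 0, 0),
                              amplitude = c(100, 150, 200),
                              test_voltages_mV = c(-20, 0, 20),
                              duration_s = 2, noise = 0.01, seed = 3)
  fit <- suppressWarnings(global_fit_tails(gen_tail_dataset(spec)))
  expect_true(!fit$converged ||
                any(c("tau_slow", "f") %in% fit$unidentifiable))
})

test_that("too few traces or samples raise informative errors", {
  dp <- deactivation_params(0.008, 5, 5)
  spec <- tail_generator_spec(dp, p_s = 0.5, amplitude = 100,
                              test_voltages_mV = 0, duration_s = 5,
                              seed = 1)
  expect_error(global_fit_tails(gen_tail_dataset(spec)),
               "at least two")
})

test_that("short traces trigger a truncation warning but still fit", {
  dp <- deactivation_params(0.008, 5, 5)
  spec <- tail_generator_spec(dp, p_s = c(0.8, 0.4), amplitude = c(80, 160),
                              test_voltages_mV = c(-40, 20),
                              duration_s = 3, noise = 0.005, seed = 5)
  expect_warning(global_fit_tails(gen_tail_dataset(spec)), "3 x")
})

test_that("95% CI coverage of the kinetic constants is 90-99%", {
  # 200 seeded replicates of a reduced three-trace family at 1% noise
  dp <- deactivation_params(0.008, 5, 5)
  set.seed(99)
  cov <- replicate(200, {
    spec <- tail_generator_spec(
      dp, p_s = c(0.9, 0.65, 0.4), amplitude = c(60, 120, 200),
      test_voltages_mV = c(-60, -20, 20), duration_s = 12,
      sample_rate_hz = 400, noise = 0.01, seed = sample.int(1e6, 1))
    g <- suppressWarnings(global_fit_tails(gen_tail_dataset(spec)))
    c(abs(g$parameters[["tau_fast"]] - 0.008) <= g$ci95[["tau_fast"]],
      abs(g$parameters[["tau_slow"]] - 5) <= g$ci95[["tau_slow"]],
      abs(g$parameters[["f"]] - 5) <= g$ci95[["f"]])
  })
  expect_true(all(rowMeans(cov) >= 0.90 & rowMeans(cov) <= 0.99))
})
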