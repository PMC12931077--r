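# IV fitting: exact self-consistency, noisy parameter recovery with CI
# coverage, coexpression mixture fits, and degenerate inputs.

test_that("noise-free wild-type IV is recovered exactly", {
  act <- kv101_act()
  y <- hh_current(act, grid_mV)
  iv <- iv_curve(grid_mV, y / y[grid_mV == 30], normalized = TRUE,
                 reference_mV = 30)
  fit <- fit_wildtype_iv(iv, activation_params(1, 2, -40, 8))
  expect_true(fit$converged)
  expect_lt(abs(fit$parameters[["v_n"]] - act$v_n), 1e-6)
  expect_lt(abs(fit$parameters[["k_n"]] - act$k_n), 1e-6)
})

test_that("wild-type recovery at 1% noise: small bias, ~95% coverage", {
  act <- kv101_act()
  set.seed(101)
  reps <- t(replicate(100, {
    iv <- gen_iv_curve(act, noise = 0.01)
    f <- fit_wildtype_iv(iv, activation_params(1, 2, -30, 10))
    c(v_n = f$parameters[["v_n"]],
      hit = abs(f$parameters[["v_n"]] - act$v_n) <= f$ci95[["v_n"]])
  }))
  expect_lt(abs(mean(reps[, "v_n"]) - act$v_n), 0.5)
  # mean within one simulated SD of the generating value (no bias)
  expect_lt(abs(mean(reps[, "v_n"]) - act$v_n), sd(reps[, "v_n"]))
  expect_gte(mean(reps[, "hit"]), 0.85)
})

test_that("monotone-decreasing IV yields a flagged non-convergent fit", {
  iv <- iv_curve(grid_mV, seq(1, -1, length.out = length(grid_mV)))
  fit <- fit_wildtype_iv(iv, activation_params(1, 2, -30, 12))
  expect_false(fit$converged)
})

test_that("degenerate all-zero IV errors out", {
  expect_error(fit_wildtype_iv(iv_curve(grid_mV, rep(0, 16)),
                               kv101_act()),
               "degenerate")
})

test_that("noise-free mixture IV is recovered exactly", {
  pr <- coexpr_preset()
  y <- mixture_iv(pr$act, pr$mix, grid_mV)
  iv <- iv_curve(grid_mV, y / y[grid_mV == 30], normalized = TRUE,
                 reference_mV = 30)
  fit <- fit_coexpression_iv(iv, pr$act, mixture_params(-70, 0.4))
  expect_true(fit$converged)
  expect_lt(abs(fit$parameters[["v_ns"]] - pr$mix$v_ns), 1e-5)
  expect_lt(abs(fit$parameters[["p_s"]] - pr$mix$p_s), 1e-7)
  # k_ns tied to k_n by default
  expect_equal(fit$parameters[["k_ns"]], pr$act$k_n)
})

test_that("coexpression recovery at 1% noise covers the truth", {
  pr <- coexpr_preset()
  set.seed(202)
  reps <- t(replicate(60, {
    iv <- gen_iv_curve(pr$act, pr$mix, noise = 0.01)
    f <- fit_coexpression_iv(iv, pr$act, mixture_params(-80, 0.5))
    c(v_ns = f$parameters[["v_ns"]], p_s = f$parameters[["p_s"]],
      hit = abs(f$parameters[["v_ns"]] - pr$mix$v_ns) <=
        f$ci95[["v_ns"]])
  }))
  expect_lt(abs(mean(reps[, "v_ns"]) - pr$mix$v_ns),
            sd(reps[, "v_ns"]))
  expect_lt(abs(mean(reps[, "p_s"]) - pr$mix$p_s), sd(reps[, "p_s"]))
  expect_gte(mean(reps[, "hit"]), 0.85)
})

test_that("pure wild-type data pushes p_s to zero, v_ns unidentifiable", {
  act <- kv101_act()
  set.seed(7)
  iv <- gen_iv_curve(act, mixture_params(-111, 0), noise = 0.01)
  fit <- fit_coexpression_iv(iv, act, mixture_params(-80, 0.5))
  expect_lte(fit$parameters[["p_s"]], 0.05)
  expect_true("v_ns" %in% fit$unidentifiable)
})

test_that("tail-activation curve fits: exact, noisy, and flat input", {
  p <- tail_activation_params(0.05, 1, -25, 7)
  v <- seq(-120, 30, 10)
  y <- tail_activation_ratio(p, v)
  fit <- fit_tail_activation(iv_curve(v, y))
  expect_true(fit$converged)
  expect_lt(abs(fit$parameters[["v_n"]] - p$v_n), 1e-6)
  set.seed(11)
  hits <- replicate(40, {
    yn <- y + rnorm(length(y), sd = 0.02)
    f <- fit_tail_activation(iv_curve(v, yn))
    all(abs(unlist(f$parameters[c("r_neg_inf", "r_inf", "v_n", "k_n")]) -
              unlist(p[c("r_neg_inf", "r_inf", "v_n", "k_n")])) <=
          unlist(f$ci95[c("r_neg_inf", "r_inf", "v_n", "k_n")]))
  })
  expect_gte(mean(hits), 0.75)   # joint coverage of all four parameters
  flat <- fit_tail_activation(iv_curve(v, rep(0.4, length(v))))
  expect_false(flat$converged)
  expect_match(flat$message, "flat")
})
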