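# Trace preprocessing: leak subtraction, steady-state IV extraction,
# gain-of-function current ratios, activation time courses.

make_traces <- function(leak_g = 0, noise = 0, tau_act = 0, seed = 1) {
  spec <- iv_generator_spec(kv101_act(), leak_g_nS = leak_g,
                            noise = noise, tau_act_s = tau_act,
                            step_duration_s = 1, tail_duration_s = 0.1,
                            sample_rate_hz = 500, seed = seed)
  gen_iv_dataset(spec)
}

test_that("steady-state extraction reproduces the model on clean traces", {
  tr <- make_traces()
  iv <- extract_steady_state_iv(tr, normalize_at = NULL)
  expect_equal(iv$current, hh_current(kv101_act(), grid_mV),
               tolerance = 1e-9)
  ivn <- extract_steady_state_iv(tr, normalize_at = 30)
  expect_equal(ivn$current[ivn$voltage_mV == 30], 1)
  expect_true(attr(ivn, "normalized"))
  expect_error(extract_steady_state_iv(tr, normalize_at = 25),
               "not part of the protocol")
})

test_that("a window inside the activation transient underestimates", {
  tr <- make_traces(tau_act = 0.3)
  # full steady state not reached by 1 s everywhere, but compare a
  # window at the end with one centered early in the step
  iv_late <- extract_steady_state_iv(tr, window_s = 0.1,
                                     normalize_at = NULL)
  tr_early <- tr
  tr_early$protocol$step_duration_s <- 0.3   # same data, earlier window
  iv_early <- extract_steady_state_iv(tr_early, window_s = 0.1,
                                      normalize_at = NULL)
  on <- abs(iv_late$current) > 1
  expect_true(all(abs(iv_early$current[on]) < abs(iv_late$current[on])))
})

test_that("linear leak is recovered and removed", {
  tr <- make_traces(leak_g = 0.2, noise = 0.01, seed = 4)
  corr <- subtract_linear_leak(tr)
  est <- attr(corr, "leak")
  expect_lt(abs(est$g_leak_nS - 0.2) / 0.2, 0.05)
  expect_true(corr$leak_corrected)
  # corrected steady-state IV matches the channel model
  iv <- extract_steady_state_iv(corr, normalize_at = NULL)
  expect_equal(iv$current, hh_current(kv101_act(), grid_mV),
               tolerance = 0.05 * max(abs(iv$current)))
})

test_that("pure-leak traces are flattened to the noise floor", {
  spec <- iv_generator_spec(activation_params(0, 2, -22, 12),
                            leak_g_nS = 0.5, noise = 0.005,
                            step_duration_s = 1, tail_duration_s = 0.1,
                            sample_rate_hz = 500, seed = 9)
  tr <- gen_iv_dataset(spec)
  corr <- subtract_linear_leak(tr)
  iv <- extract_steady_state_iv(corr, normalize_at = NULL)
  noise_floor <- 0.005 * 0.5 * 122          # noise fraction x max |leak|
  expect_true(all(abs(iv$current) < noise_floor))
})

test_that("leak estimation demands two sweeps in the leak window", {
  tr <- make_traces()
  expect_error(subtract_linear_leak(tr, leak_below_mV = -130),
               "at least two sweeps")
})

test_that("zero added leak leaves clean traces unchanged within noise", {
  tr <- make_traces(noise = 0.005, seed = 2)
  corr <- subtract_linear_leak(tr)
  expect_lt(abs(attr(corr, "leak")$g_leak_nS), 0.01)
  expect_lt(max(abs(corr$currents - tr$currents)), 1)  # pA
})

test_that("gof ratio: identity, masking, and model-curve behavior", {
  act <- kv101_act()
  mix <- mixture_params(-111, 0.7)
  v <- grid_mV
  wt <- hh_current(act, v); co <- mixture_iv(act, mix, v)
  iv_wt <- iv_curve(v, wt / wt[v == 30], normalized = TRUE,
                    reference_mV = 30)
  iv_co <- iv_curve(v, co / co[v == 30], normalized = TRUE,
                    reference_mV = 30)
  same <- gof_ratio(iv_wt, iv_wt)
  expect_equal(same$ratio[!is.na(same$ratio)],
               rep(1, sum(!is.na(same$ratio))))
  r <- gof_ratio(iv_co, iv_wt)
  expect_true(all(r$ratio[r$voltage_mV %in% c(10, 20)] > 1))
  expect_equal(r$ratio[r$voltage_mV == 30], 1)
  # monotone decrease over the outward limb when V_ns < V_n
  out_limb <- r$voltage_mV >= 10
  expect_true(all(diff(r$ratio[out_limb]) < 0))
  expect_error(gof_ratio(iv_co, iv_curve(v + 5, wt)), "different voltage")
})

test_that("activation time course normalizes to the 20 mV / 6.5 s peak", {
  peaks <- expand.grid(voltage_mV = c(-20, -10, 0, 20),
                       duration_s = c(0.2, 1, 3, 6.5))
  peaks$peak_pA <- 100 * (1 - exp(-peaks$duration_s / 1.5)) *
    boltzmann_open_fraction(peaks$voltage_mV, -20, 10)
  out <- activation_timecourse(peaks)
  expect_equal(out$activation[out$voltage_mV == 20 &
                                out$duration_s == 6.5], 1)
  expect_true(all(out$activation >= 0 & out$activation <= 1 + 1e-9))
  # normalized curves follow 1 - exp(-t/tau) per voltage
  for (vv in c(-20, 0, 20)) {
    sel <- out$voltage_mV == vv
    scale <- boltzmann_open_fraction(vv, -20, 10) /
      (boltzmann_open_fraction(20, -20, 10) * (1 - exp(-6.5 / 1.5)))
    expect_equal(out$activation[sel],
                 scale * (1 - exp(-out$duration_s[sel] / 1.5)),
                 tolerance = 1e-9)
  }
  expect_error(activation_timecourse(peaks[peaks$duration_s < 6, ]),
               "reference entry")
})

test_that("trace-set invariants are enforced", {
  expect_error(trace_set(c(0, 0.1, 0.3), matrix(0, 3, 2),
                         list(holding_mV = -120, step_mV = c(-20, 0),
                              step_duration_s = 0.3)),
               "uniform")
  expect_error(trace_set(seq(0, 1, 0.1), matrix(0, 11, 2),
                         list(holding_mV = -120, step_mV = c(0, -20),
                              step_duration_s = 1)),
               "strictly increasing")
})
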