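trapezoid_trace <- function(dt = 0.1) {
  t <- seq(0, 400, by = dt)
  vm <- rep(-80, length(t))
  vm[t >= 50 & t < 51] <- -80 + (t[t >= 50 & t < 51] - 50) * 100
  vm[t >= 51 & t < 220] <- 20
  fall <- t >= 220 & t < 280
  vm[fall] <- 20 - (t[fall] - 220) * (100 / 60)
  vm[t >= 280] <- -80
  stim <- as.numeric(t >= 50 & t < 51)
  list(time = t, Vm = vm, stim = stim)
}

test_that("APD is measured from maximum upstroke slope to the level crossing", {
  tr <- trapezoid_trace()
  m <- measure_apd(tr, 90)
  # construction: upstroke max slope at 50.05 ms; 90% repolarization
  # (Vm = -70) crossed at 220 + 0.9 * 60 = 274 ms
  expect_equal(m$status, "ok")
  expect_lt(abs(m$apd - (274 - 50.05)), 0.2)
  m50 <- measure_apd(tr, 50)
  expect_lt(abs(m50$apd - (220 + 0.5 * 60 - 50.05)), 0.2)
  expect_lte(m50$apd, m$apd)
})

test_that("a flat trace yields a no-AP result, not an error", {
  t <- seq(0, 300, 0.1)
  tr <- list(time = t, Vm = rep(-85, length(t)),
             stim = as.numeric(t >= 10 & t < 11))
  m <- measure_apd(tr, 90)
  expect_equal(m$status, "no_ap")
  expect_true(is.na(m$apd))
})

test_that("incomplete repolarization is flagged as censored", {
  t <- seq(0, 100, 0.1)
  vm <- rep(-80, length(t))
  vm[t >= 10 & t < 11] <- -80 + (t[t >= 10 & t < 11] - 10) * 100
  vm[t >= 11] <- 20 # never repolarizes inside the window
  tr <- list(time = t, Vm = vm, stim = as.numeric(t >= 10 & t < 11))
  expect_equal(measure_apd(tr, 90)$status, "censored")
})

test_that("APD50 <= APD90 on a simulated action potential", {
  tr <- young_result()$trace
  a50 <- measure_apd(tr, 50)
  a90 <- measure_apd(tr, 90)
  expect_equal(a50$status, "ok")
  expect_lte(a50$apd, a90$apd)
})

test_that("young and aged conditions have the published composition", {
  y <- make_condition("young")
  expect_length(y$fibroblasts, 4)
  expect_true(all(vapply(y$fibroblasts, function(f) f$Cm_CF, 1) == 18))
  expect_true(all(y$g_gap == 20))
  expect_equal(y$myocyte$gNa_scale, 0.5)
  a <- make_condition("aged")
  expect_length(a$fibroblasts, 5)
  cms <- vapply(a$fibroblasts, function(f) f$Cm_CF, 1)
  expect_equal(sum(cms == 35), 1)
  expect_equal(sum(cms == 18), 4)
  expect_error(make_condition("old"), "arg")
})

test_that("a zero-conductance condition behaves as the uncoupled myocyte", {
  cfg <- make_condition("young", g_gap = 0)
  un <- coupled_config(myocyte_params(gNa_scale = 0.5))
  t1 <- integrate_coupled(cfg, stim_times = 0, t_end = 350, stim_amp = 45)
  t2 <- integrate_coupled(un, stim_times = 0, t_end = 350, stim_amp = 45)
  expect_identical(t1$Vm, t2$Vm)
})

test_that("S2 at the full S1 interval does not fail", {
  cfg <- make_condition("aged", gK1_scale = 0.73)
  res <- s1s2_failure_cl(cfg, s1s2_spec(n_s1 = 4, scan_start = 345,
                                        scan_stop = 330, scan_step = 5))
  expect_equal(res$status, "no_failure_in_range")
})

test_that("failure onset is bracketed, refined to 1 ms, and deterministic", {
  cfg <- make_condition("aged", gK1_scale = 0.73)
  spec <- s1s2_spec(n_s1 = 6, scan_step = 40)
  r1 <- s1s2_failure_cl(cfg, spec)
  expect_equal(r1$status, "ok")
  expect_lte(r1$bracket[["success"]] - r1$bracket[["fail"]], 1)
  expect_equal(r1$onset_cl, r1$bracket[["fail"]])
  r2 <- s1s2_failure_cl(cfg, spec)
  expect_identical(r1$onset_cl, r2$onset_cl) # bit-identical rerun
})

test_that("a single-cell failure map equals the direct onset call", {
  base <- coupled_config(myocyte_params(gNa_scale = 0.5),
                         list(fibroblast_spec("proliferating")), g_gap = 20)
  spec <- s1s2_spec(n_s1 = 5, scan_step = 40)
  fm <- sweep_failure_map(base, "gNa_scale", 0.5, 18, spec)
  direct <- s1s2_failure_cl(base, spec)
  expect_equal(unname(fm$values[1, 1]), direct$onset_cl)
})

test_that("APD sweep runs per cell and records failures without aborting", {
  base <- coupled_config(myocyte_params(gNa_scale = 0.5),
                         list(fibroblast_spec("proliferating")), g_gap = 20)
  sw <- sweep_apd_map(base, g_values = c(0.1, 1), Cm_values = c(10, 40),
                      pacing = pacing_spec(beats = 8, amp = 45))
  expect_equal(dim(sw$values), c(2L, 2L))
  expect_true(all(is.finite(sw$values)))
  # capacitance effect: every row non-decreasing
  expect_true(all(apply(sw$values, 1, function(r) all(diff(r) >= 0))))
})

test_that("stimulus threshold bisection brackets a firing amplitude", {
  cfg <- coupled_config(myocyte_params())
  th <- stim_threshold(cfg, CL = 350)
  expect_gt(th, 1)
  expect_lt(th, 60)
  # cached second call is instantaneous and identical
  expect_identical(th, stim_threshold(cfg, CL = 350))
})
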