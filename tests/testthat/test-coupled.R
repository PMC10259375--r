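test_that("gap current is ohmic and antisymmetric", {
  expect_identical(gap_current(-30, -30, 20), 0)
  expect_identical(gap_current(0, -100, 20), 2000)
  expect_identical(gap_current(-100, 0, 20), -gap_current(0, -100, 20))
  expect_error(gap_current(NA, 0, 20), "finite")
})

test_that("uncoupled and zero-conductance runs are bit-identical", {
  empty <- coupled_config(myocyte_params())
  zero <- coupled_config(myocyte_params(),
                         list(fibroblast_spec("proliferating")), g_gap = 0)
  t1 <- integrate_coupled(empty, stim_times = c(0, 400), t_end = 800,
                          stim_amp = 60)
  t2 <- integrate_coupled(zero, stim_times = c(0, 400), t_end = 800,
                          stim_amp = 60)
  expect_identical(t1$Vm, t2$Vm)
  expect_identical(t1$state_final, t2$state_final)
  expect_identical(max(abs(t2$I_gap)), 0)
})

test_that("coupled_rhs reduces to the uncoupled model at g_gap = 0", {
  cfg0 <- coupled_config(myocyte_params(),
                         list(fibroblast_spec("senescent")), g_gap = 0)
  s <- default_initial_state()
  r <- coupled_rhs(s, -50, cfg0, I_stim = 0)
  expect_identical(r$myocyte, myocyte_rhs(s, cfg0$myocyte, 0)$deriv)
})

test_that("passive fibroblast follows the closed-form RC response", {
  f <- fibroblast_spec("proliferating") # 18 pF
  g_gap <- 20
  # numerical slope conductance at E_rev (nS)
  h <- 1e-4
  g_slope <- (fibroblast_current(f$E_rev + h, f) -
                fibroblast_current(f$E_rev - h, f)) / (2 * h)
  tau <- f$Cm_CF / (g_gap + g_slope) # ms
  # clamp the myocyte side to a small square pulse around E_rev
  vm <- f$E_rev + 2
  vf <- f$E_rev
  dt <- 1e-4
  n <- round(5 * tau / dt)
  for (i in seq_len(n)) {
    vf <- vf + dt * (-fibroblast_current(vf, f) +
                       gap_current(vm, vf, g_gap)) / f$Cm_CF
  }
  # closed form: exponential approach to the divider potential
  vf_inf <- f$E_rev + 2 * g_gap / (g_gap + g_slope)
  expected <- vf_inf + (f$E_rev - vf_inf) * exp(-n * dt / tau)
  expect_lt(abs(vf - expected) / abs(vf_inf - f$E_rev), 0.01)
  # membrane time constant grows with capacitance
  f2 <- fibroblast_spec("senescent") # 35 pF, same curve
  expect_gt(f2$Cm_CF / (g_gap + g_slope), tau)
})

test_that("unstimulated coupled relaxation reaches a joint equilibrium", {
  cfg <- make_condition("aged")
  tr <- integrate_coupled(cfg, stim_times = numeric(0), t_end = 5000,
                          stim_amp = 0, record_dt = 10)
  nf <- length(cfg$fibroblasts)
  last <- length(tr$time)
  for (i in seq_len(nf)) {
    ig <- tr$I_gap[last, i]
    i_f <- fibroblast_current(tr$Vf[last, i], cfg$fibroblasts[[i]])
    # at equilibrium every gap current balances its membrane current
    expect_lt(abs(ig - i_f), 0.5) # pA
  }
})

test_that("total gap current equals the sum over connections", {
  tr <- aged_result()$trace
  expect_lt(max(abs(tr$I_gap_total - rowSums(tr$I_gap))), 1e-9)
})

test_that("halving the step cap shows first-order convergence of APD90", {
  cfg <- coupled_config(myocyte_params())
  apd_for <- function(theta) {
    tr <- integrate_coupled(cfg, stim_times = 0, t_end = 350, stim_amp = 60,
                            controller = step_controller(theta_mV = theta))
    measure_apd(tr, 90)$apd
  }
  a1 <- apd_for(0.4)
  a2 <- apd_for(0.2)
  a3 <- apd_for(0.1)
  expect_lte(abs(a3 - a2), abs(a2 - a1) + 0.05)
})

test_that("APD90 is non-decreasing in fibroblast capacitance at 20 nS", {
  apds <- vapply(c(5, 18, 35, 60), function(cm) {
    cfg <- coupled_config(myocyte_params(gNa_scale = 0.5),
                          list(fibroblast_spec("proliferating", Cm_CF = cm)),
                          g_gap = 20)
    run <- run_paced(cfg, pacing_spec(beats = 10, amp = 45))
    tail(run$apd_per_beat, 1)
  }, numeric(1))
  expect_true(all(diff(apds) >= 0))
})

test_that("aborted runs report the divergence", {
  cfg <- coupled_config(myocyte_params())
  expect_error(
    integrate_coupled(cfg, stim_times = 0, t_end = 50, stim_amp = 1000),
    "aborted run")
})
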