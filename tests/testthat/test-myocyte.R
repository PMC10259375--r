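test_that("published initial conditions are a quiescent operating point", {
  s <- default_initial_state()
  expect_identical(s, default_initial_state()) # deterministic constructor
  expect_true(all(s[2:17] >= 0 & s[2:17] <= 1)) # gates/occupancies
  r <- myocyte_rhs(s, myocyte_params(), 0)
  # fast variables essentially at rest; slow SR/Na redistribution only
  expect_lt(abs(r$deriv[["Vm"]]), 0.01)
  expect_lt(max(abs(r$deriv[2:17])), 1e-3)
  expect_lt(abs(r$currents[["I_ion"]]), 0.01)
})

test_that("unstimulated membrane potential drifts less than 1 mV in 10 s", {
  cfg <- coupled_config(myocyte_params())
  tr <- integrate_coupled(cfg, stim_times = numeric(0), t_end = 10000,
                          stim_amp = 0, record_dt = 10)
  expect_lt(max(abs(tr$Vm - tr$Vm[1])), 1)
})

test_that("I_K1 vanishes at the potassium Nernst potential", {
  s <- default_initial_state()
  s[["Vm"]] <- nernst_ek()
  r <- myocyte_rhs(s, myocyte_params())
  expect_equal(r$currents[["I_K1"]], 0, tolerance = 1e-12)
})

test_that("the current breakdown sums to the total at arbitrary states", {
  set.seed(7)
  s0 <- as.numeric(default_initial_state())
  for (i in 1:20) {
    s <- s0 * exp(rnorm(26, 0, 0.02))
    s[1] <- runif(1, -90, 40) # Vm is not positive
    r <- myocyte_rhs(s, myocyte_params(), 0)
    cb <- r$currents
    expect_lt(abs(cb[["I_ion"]] - sum(cb[names(cb) != "I_ion"])), 1e-10)
  }
})

test_that("conductance scalings act only on their own currents", {
  s <- default_initial_state()
  s[["Vm"]] <- -40
  a <- myocyte_rhs(s, myocyte_params(gNa_scale = 1, gK1_scale = 1))
  b <- myocyte_rhs(s, myocyte_params(gNa_scale = 0.5, gK1_scale = 1))
  d <- myocyte_rhs(s, myocyte_params(gNa_scale = 1, gK1_scale = 0.73))
  expect_identical(a$currents[["I_K1"]], b$currents[["I_K1"]])
  expect_identical(a$currents[["I_Na"]], d$currents[["I_Na"]])
  expect_equal(b$currents[["I_Na"]], 0.5 * a$currents[["I_Na"]])
  expect_equal(d$currents[["I_K1"]], 0.73 * a$currents[["I_K1"]])
})

test_that("gates stay in [0, 1] throughout a paced run", {
  cfg <- coupled_config(myocyte_params())
  st <- default_initial_state()
  for (b in 1:3) {
    tr <- integrate_coupled(cfg, stim_times = 0, t_end = 350, stim_amp = 60,
                            state0 = st)
    st <- tr$state_final
    expect_true(all(st[2:17] >= -1e-9 & st[2:17] <= 1 + 1e-9))
    expect_true(all(st[c("cp", "cs", "ci", "cj", "cjp", "nai")] > 0))
  }
})

test_that("adaptive pacing matches a fine fixed-step reference run", {
  cfg <- coupled_config(myocyte_params())
  ad <- integrate_coupled(cfg, stim_times = c(0, 400), t_end = 800,
                          stim_amp = 60)
  fx <- integrate_coupled(cfg, stim_times = c(0, 400), t_end = 800,
                          stim_amp = 60,
                          controller = step_controller(0.5, 0.5))
  a1 <- measure_apd(ad, 90, beat = 2)
  a2 <- measure_apd(fx, 90, beat = 2)
  expect_equal(a1$status, "ok")
  expect_lt(abs(a1$apd - a2$apd), 1)
  expect_lt(max(abs(ad$Vm - fx$Vm)), 2) # trajectories agree closely
})

test_that("invalid states are rejected with the offending variable named", {
  s <- default_initial_state()
  s[["cs"]] <- NaN
  expect_error(myocyte_rhs(s, myocyte_params()), "cs")
  expect_error(myocyte_rhs(default_initial_state(), myocyte_params(),
                           I_ext = Inf), "finite")
  expect_error(myocyte_params(gNa_scale = 0), "gNa_scale")
  expect_error(myocyte_params(gK1_scale = 3), "gK1_scale")
})
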