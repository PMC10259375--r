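make_trace <- function(steps, f_step, f_tail, protocol = clamp_protocol()) {
  do.call(rbind, lapply(steps, function(v) {
    t <- seq(0, protocol$duration_ms + 100, by = protocol$sampling_ms)
    data.frame(step_mV = v, time_ms = t,
               current_pA = ifelse(t < protocol$duration_ms,
                                   f_step(v), f_tail(v)))
  }))
}

test_that("tail-referenced extraction implements its definition", {
  pr <- clamp_protocol(steps_mV = c(-100, -50, 0, 40))
  # constant trace: amplitude zero
  rec <- make_trace(pr$steps_mV, function(v) 3.5, function(v) 3.5, pr)
  expect_equal(extract_iv(rec, pr)$amplitude_pA, rep(0, 4))
  # step current s, tail t: amplitude s - t
  rec2 <- make_trace(pr$steps_mV, function(v) 2 * v, function(v) -7, pr)
  expect_equal(extract_iv(rec2, pr)$amplitude_pA, 2 * pr$steps_mV + 7)
})

test_that("extraction is linear in the records", {
  pr <- clamp_protocol(steps_mV = c(-80, -20, 40))
  r1 <- make_trace(pr$steps_mV, function(v) v, function(v) 1, pr)
  r2 <- make_trace(pr$steps_mV, function(v) sin(v), function(v) -2, pr)
  rsum <- r1
  rsum$current_pA <- r1$current_pA + r2$current_pA
  expect_equal(extract_iv(rsum, pr)$amplitude_pA,
               extract_iv(r1, pr)$amplitude_pA +
                 extract_iv(r2, pr)$amplitude_pA)
})

test_that("truncated or mismatched records are rejected", {
  pr <- clamp_protocol(steps_mV = c(-80, -20, 40))
  rec <- make_trace(pr$steps_mV, function(v) v, function(v) 0, pr)
  short <- rec[rec$time_ms < pr$duration_ms - 500, ]
  expect_error(extract_iv(short, pr), "truncated")
  missing <- rec[rec$step_mV != -20, ]
  expect_error(extract_iv(missing, pr), "protocol mismatch")
})

test_that("window-averaged amplitudes stay within the noise bound", {
  pr <- clamp_protocol(steps_mV = seq(-100, 10, by = 10))
  rec <- gen_clamp_traces(clamp_generator_spec(noise_sd_pA = 5), pr,
                          seed = 21)
  pts <- extract_iv(rec, pr)
  # oracle: re-generate the same records without noise and extract
  rec0 <- gen_clamp_traces(clamp_generator_spec(noise_sd_pA = 0), pr,
                           seed = 21)
  pts0 <- extract_iv(rec0, pr)
  # each window holds 100 and 45 one-ms samples: the deviation of each
  # amplitude is Gaussian with sd sigma/sqrt(n_eff)
  n_eff <- 1 / (1 / 100 + 1 / 45)
  dev <- pts$amplitude_pA - pts0$amplitude_pA
  expect_lt(sqrt(mean(dev^2)), 2 * 5 / sqrt(n_eff))
  expect_lt(max(abs(dev)), 4 * 5 / sqrt(n_eff))
})

test_that("noiseless Boltzmann points are recovered to high precision", {
  v <- seq(-100, 40, 10)
  pts <- data.frame(V_mV = v,
                    amplitude_pA = 1 / (1 + exp((-15 - v) / 12)) - 0.2)
  fit <- fit_boltzmann(pts, normalize = FALSE)
  expect_lt(abs(fit$iv$A - 1), 1e-6)
  expect_lt(abs(fit$iv$V_half + 15), 1e-6)
  expect_lt(abs(fit$iv$k - 12), 1e-6)
  expect_lt(abs(fit$iv$C + 0.2), 1e-6)
  expect_false(fit$poorly_identified)
})

test_that("half-activation recovery under noise: median error below 2 mV", {
  v <- seq(-100, 40, 10)
  true_amp <- 1 / (1 + exp((-15 - v) / 12)) - 0.2
  set.seed(1234)
  errs <- replicate(200, {
    pts <- data.frame(V_mV = v,
                      amplitude_pA = true_amp + rnorm(length(v), 0, 0.02))
    fit_boltzmann(pts, normalize = FALSE)$iv$V_half - (-15)
  })
  expect_lt(median(abs(errs)), 2)
})

test_that("a strictly linear I-V is flagged as poorly identified", {
  pts <- data.frame(V_mV = seq(-100, 40, 10),
                    amplitude_pA = 0.01 * seq(-100, 40, 10))
  fit <- fit_boltzmann(pts, normalize = FALSE)
  expect_true(fit$poorly_identified)
})

test_that("normalization only rescales the fitted amplitude and offset", {
  v <- seq(-100, 40, 10)
  set.seed(5)
  pts <- data.frame(V_mV = v,
                    amplitude_pA = 800 / (1 + exp((-10 - v) / 14)) - 150 +
                      rnorm(length(v), 0, 4))
  fn <- fit_boltzmann(pts, normalize = TRUE)
  fu <- fit_boltzmann(pts, normalize = FALSE)
  expect_equal(fn$iv$A * fn$normalization, fu$iv$A, tolerance = 1e-4)
  expect_equal(fn$iv$C * fn$normalization, fu$iv$C, tolerance = 1e-4)
  expect_equal(fn$iv$V_half, fu$iv$V_half, tolerance = 1e-4)
  expect_equal(fn$iv$k, fu$iv$k, tolerance = 1e-4)
})

test_that("degenerate or under-determined point sets are rejected", {
  expect_error(fit_boltzmann(data.frame(V_mV = c(-60, -20, 40),
                                        amplitude_pA = 1:3)), "4")
  expect_error(fit_boltzmann(data.frame(V_mV = seq(-20, 20, 10),
                                        amplitude_pA = rep(1, 5))),
               "degenerate|span")
})

test_that("generator -> extraction -> fit -> shift recovers the true curve", {
  spec <- clamp_generator_spec(noise_sd_pA = 0.02 * 1150)
  rec <- gen_clamp_traces(spec, seed = 31)
  pts <- extract_iv(rec)
  fit <- fit_boltzmann(pts, normalize = TRUE)
  # compare the recovered tail-referenced curve against the noiseless one
  truth <- attr(rec, "ground_truth")$expected_amplitude
  fitted <- eval_iv(fit$iv, truth$V_mV) * fit$normalization
  amp <- max(abs(truth$amplitude_pA))
  expect_lt(max(abs(fitted - truth$amplitude_pA)) / amp, 0.05)
})
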