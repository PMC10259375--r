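test_that("Boltzmann curves evaluate to the closed form and shift correctly", {
  iv <- boltzmann_iv(A = 1, V_half = -20, k = 10, C = -0.3)
  v <- c(-80, -20, 40)
  expect_equal(eval_iv(iv, v), 1 / (1 + exp((-20 - v) / 10)) - 0.3)
  sh <- shift_to_reversal(iv, -50)
  expect_equal(sh$shift_mode, "horizontal")
  expect_lt(abs(eval_iv(sh, -50)), 1e-9)
  # no zero crossing available: falls back to a vertical offset
  iv2 <- boltzmann_iv(A = 1, V_half = -20, k = 10, C = 0.5)
  sh2 <- shift_to_reversal(iv2, -50)
  expect_equal(sh2$shift_mode, "vertical")
  expect_lt(abs(eval_iv(sh2, -50)), 1e-9)
  expect_error(boltzmann_iv(1, 0, 0), "k")
})

test_that("fibroblast current is passive, zero at E_rev, monotone", {
  f <- fibroblast_spec("proliferating")
  expect_equal(fibroblast_current(f$E_rev, f), 0, tolerance = 1e-7)
  f0 <- fibroblast_spec("proliferating", g_scale = 0)
  expect_identical(fibroblast_current(c(-100, 0, 40), f0), c(0, 0, 0))
  v <- seq(-100, 40, by = 0.5)
  expect_true(all(diff(fibroblast_current(v, f)) >= 0))
  # state-free: repeated evaluation is bit-identical
  expect_identical(fibroblast_current(17.3, f), fibroblast_current(17.3, f))
})

test_that("hand-specified fibroblast current matches direct evaluation", {
  iv <- boltzmann_iv(A = 1, V_half = -20, k = 10, C = -0.3)
  f <- fibroblast_spec("proliferating", iv = iv, g_scale = 5, E_rev = -50,
                       Cm_CF = 18)
  # reproduce the shift arithmetic independently: horizontal shift s solves
  # 1/(1+exp((-20 + s - (-50))/10)) = 0.3
  s <- 10 * log(1 / 0.3 - 1) - (-20 - (-50))
  expected <- 5 * 140 * (1 / (1 + exp((-20 + s - 40) / 10)) - 0.3)
  expect_equal(fibroblast_current(40, f), expected, tolerance = 1e-12)
})

test_that("spherical surface area follows the volume two-thirds law", {
  expect_equal(sphere_area_from_volume(4 * pi / 3), 4 * pi)
  v <- c(17, 1000, 35000)
  expect_equal(sphere_area_from_volume(2 * v),
               2^(2 / 3) * sphere_area_from_volume(v))
  expect_equal(sphere_area_from_volume(1000), (36 * pi)^(1 / 3) * 100)
  expect_error(sphere_area_from_volume(-1), "positive")
  expect_error(sphere_area_from_volume(0), "positive")
})

test_that("tissue capacitance extrapolation reproduces constructed ratios", {
  # identical tissue and culture volumes: in-vitro value passes through
  vol <- volumetric_summary(1000, 1000, 1000, 1000, 128.7, 138.4)
  expect_equal(unname(extrapolate_tissue_capacitance(vol)[1]), 128.7)
  # construct volumes with a chosen area ratio r: volume ratio r^(3/2)
  r <- 1.6180
  vol2 <- volumetric_summary(800, 800 * r^1.5, 9000, 9500, 100, 110)
  out <- extrapolate_tissue_capacitance(vol2)
  expect_equal(unname(out[2] / out[1]), r, tolerance = 1e-12)
  # scale equivariance: multiplying all volumes leaves outputs unchanged
  vol3 <- volumetric_summary(800 * 8, 800 * r^1.5 * 8, 9000 * 8, 9500 * 8,
                             100, 110)
  expect_equal(extrapolate_tissue_capacitance(vol3), out)
  expect_error(extrapolate_tissue_capacitance(list(a = 1)), "configuration")
})

test_that("reported tissue capacitances round to 18 and 35 pF", {
  caps <- capacitance_report(18, 1.95)
  expect_identical(unname(caps), c(18, 35))
})
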