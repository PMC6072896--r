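test_that("water diffusivity interpolation reproduces the reference points and printed constants", {
  # interpolation endpoints are the tabulated reference values
  expect_warning(d_lo <- water_diffusivity(298.15), "physiological")
  expect_warning(d_hi <- water_diffusivity(318.15), "physiological")
  expect_equal(d_lo, 2.30e-9)
  expect_equal(d_hi, 3.55e-9)
  # printed constants at 3 significant figures
  expect_equal(signif(water_diffusivity(310), 3), 3.04e-9)
  expect_equal(signif(water_diffusivity(308), 3), 2.92e-9)
  expect_equal(signif(water_diffusivity(312), 3), 3.17e-9)
  expect_equal(signif(water_diffusivity(309.5), 3), 3.01e-9)
  expect_equal(signif(water_diffusivity(310.5), 3), 3.07e-9)
  expect_equal(default_water_diffusivity(), 3.04e-3)
})

test_that("water diffusivity is strictly increasing and range-checked", {
  temps <- seq(306, 314, by = 0.5)
  d <- vapply(temps, water_diffusivity, 0)
  expect_true(all(diff(d) > 0))
  expect_error(water_diffusivity(272), "range")
  expect_error(water_diffusivity(400), "range")
  expect_warning(water_diffusivity(300), "physiological")
  expect_warning(water_diffusivity(320), "physiological")
  expect_silent(water_diffusivity(310))
})

test_that("f_UL ratio is clamped to [0,1] with correct flags", {
  # CSF-like voxel: ratio exactly 1, no clamp
  r <- compute_ful(3.04e-3, 3.04e-3)
  expect_equal(r$f_ul, 1)
  expect_false(r$clamped_high); expect_false(r$clamped_low)
  expect_equal(compute_ful(1.52e-3, 3.04e-3)$f_ul, 0.5)
  # above water diffusivity: clamped at 1
  r_hi <- compute_ful(4.0e-3, 3.04e-3)
  expect_equal(r_hi$f_ul, 1)
  expect_equal(r_hi$raw_ratio, 4.0 / 3.04, tolerance = 1e-12)
  expect_true(r_hi$clamped_high)
  # negative third eigenvalue from a noisy fit: clamped at 0
  r_lo <- compute_ful(-1e-4, 3.04e-3)
  expect_equal(r_lo$f_ul, 0)
  expect_true(r_lo$clamped_low)
  expect_lt(compute_ful(-1e-4, 3.04e-3, clamp_low = FALSE)$f_ul, 0)
  # totality: any finite lambda3 stays in [0,1]
  l3 <- c(-1, -1e-6, 0, 1e-3, 3.04e-3, 1, 100)
  expect_true(all(compute_ful(l3, 3.04e-3)$f_ul >= 0))
  expect_true(all(compute_ful(l3, 3.04e-3)$f_ul <= 1))
  expect_error(compute_ful(1e-3, 0), "positive")
  expect_error(compute_ful(1e-3, -1), "positive")
})

test_that("two-compartment mixing matches hand arithmetic and its limits", {
  dt <- diag(c(1.7, 0.4, 0.2)) * 1e-3
  expect_equal(mix_tensors(0, dt, 3.04e-3), dt)
  expect_equal(mix_tensors(1, dt, 3.04e-3), 3.04e-3 * diag(3))
  expect_equal(mix_tensors(0.3, dt, 3.04e-3),
               diag(c(2.102, 1.192, 1.052)) * 1e-3, tolerance = 1e-12)
})

test_that("per-axis solutions recover the true fraction from a constructed mixture", {
  set.seed(31)
  for (i in 1:20) {
    lt <- sort(runif(3, 0, 2.9e-3), decreasing = TRUE)  # tissue eigenframe diag
    f <- runif(1)
    lvox <- (1 - f) * lt + f * 3.04e-3
    expect_equal(per_axis_solutions(lvox, lt, 3.04e-3), rep(f, 3),
                 tolerance = 1e-10)
  }
  # tissue-free limit: reduces to the eigenvalue / D_W bounds
  expect_equal(per_axis_solutions(c(3e-3, 2e-3, 1e-3), c(0, 0, 0), 3.04e-3),
               c(3, 2, 1) * 1e-3 / 3.04e-3)
  # f = 0: all axes return 0
  lt <- c(1.7e-3, 0.4e-3, 0.2e-3)
  expect_equal(per_axis_solutions(lt, lt, 3.04e-3), c(0, 0, 0))
  # near-zero denominator flagged undefined
  expect_true(is.na(per_axis_solutions(c(3.04e-3, 1e-3, 0.5e-3),
                                       c(3.04e-3, 0, 0), 3.04e-3)[1]))
})

test_that("the bound chain has its minimum at the third eigenvalue", {
  bc <- bound_chain(c(3e-3, 2e-3, 1e-3), 3.04e-3)
  expect_equal(bc$bounds, c(3, 2, 1) * 1e-3 / 3.04e-3, tolerance = 1e-12)
  expect_equal(bc$f_ul, min(bc$bounds))
  iso <- bound_chain(rep(1.5e-3, 3), 3.04e-3)
  expect_true(all(iso$bounds == iso$bounds[1]))
  expect_error(bound_chain(c(1e-3, 2e-3, 3e-3), 3.04e-3), "sorted")
})

test_that("f_UL bounds the true fraction over randomized two-compartment specs", {
  set.seed(32)
  d_water <- default_water_diffusivity()
  n <- 2000
  worst_gap <- -Inf
  for (i in seq_len(n)) {
    tn <- random_psd_tensor(0, d_water)   # tissue eigenvalues <= D_W
    f <- runif(1)
    mixed <- mix_tensors(f, tn$m, d_water)
    l3 <- eigendecompose(mixed)$values[3]
    ful <- compute_ful(l3, d_water)$f_ul
    expect_gte(ful, f - 1e-12)
    # closed form: isotropic addition preserves eigenvectors
    expect_equal(ful, ful_closed_form(f, tn$eigenvalues[3], d_water),
                 tolerance = 1e-8)
    worst_gap <- max(worst_gap, f - ful)
  }
  expect_lte(worst_gap, 1e-12)
})

test_that("f_UL is monotone in f and in assumed temperature, and exact at f = 1", {
  d_water <- default_water_diffusivity()
  dt <- diag(c(1.7, 0.5, 0.5)) * 1e-3     # lambda3 < D_W
  f_grid <- seq(0, 1, by = 0.05)
  ful <- vapply(f_grid, function(f)
    compute_ful(eigendecompose(mix_tensors(f, dt, d_water))$values[3],
                d_water)$f_ul, 0)
  expect_true(all(diff(ful) > 0))
  # pure CSF: f_UL = 1 exactly regardless of tissue tensor
  set.seed(33)
  for (i in 1:5) {
    tn <- random_psd_tensor()
    l3 <- eigendecompose(mix_tensors(1, tn$m, d_water))$values[3]
    expect_equal(compute_ful(l3, d_water)$f_ul, 1)
  }
  # warmer assumed brain -> larger D_W -> smaller pre-clamp ratio
  l3 <- 1.2e-3
  temps <- seq(306, 314, by = 1)
  raw <- vapply(temps, function(t)
    compute_ful(l3, default_water_diffusivity(t))$raw_ratio, 0)
  expect_true(all(diff(raw) < 0))
})
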