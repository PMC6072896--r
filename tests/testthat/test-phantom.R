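test_that("the two mixing modes coincide at f = 0 and f = 1 and at b = 0", {
  sch <- default_scheme()
  dt <- diag(c(1.7, 0.4, 0.2)) * 1e-3
  for (f in c(0, 1)) {
    st <- simulate_signals(dt, f, 3.04e-3, sch, s0 = 800, mode = "tensor")
    ss <- simulate_signals(dt, f, 3.04e-3, sch, s0 = 800, mode = "signal")
    expect_equal(st, ss, tolerance = 1e-12)
    expect_true(all(st > 0))
  }
  # pure free water: every DW signal is s0 * exp(-b * D_W)
  s_csf <- simulate_signals(dt, 1, 3.04e-3, sch, s0 = 800)
  expect_equal(s_csf[-1], rep(800 * exp(-1000 * 3.04e-3), 15))
  # b0 volume always reads s0
  for (mode in c("tensor", "signal")) {
    s <- simulate_signals(dt, 0.4, 3.04e-3, sch, s0 = 800, mode = mode)
    expect_equal(s[1], 800)
  }
})

test_that("fitting noiseless tensor-mixing signals returns the mixed tensor", {
  sch <- default_scheme()
  dt <- diag(c(1.7, 0.4, 0.2)) * 1e-3
  s <- simulate_signals(dt, 0.3, 3.04e-3, sch, mode = "tensor")
  ft <- fit_tensor(s, sch)
  expect_equal(tensor_matrix(ft), mix_tensors(0.3, dt, 3.04e-3),
               tolerance = 1e-10)
})

test_that("Rician noise is identity at sigma 0, seed-deterministic, and has the analytic Rice bias", {
  s <- c(100, 500, 1000)
  expect_identical(add_rician_noise(s, 0), s)
  set.seed(7); a <- add_rician_noise(rep(1000, 100), 50)
  set.seed(7); b <- add_rician_noise(rep(1000, 100), 50)
  expect_identical(a, b)
  # analytic Rice mean (Laguerre form; cross-frozen against scipy's
  # rice.mean: 1001.2507842028608 for S = 1000, sigma = 50)
  expect_equal(rice_mean(1000, 50), 1001.2507842028608, tolerance = 1e-10)
  set.seed(8)
  noisy <- add_rician_noise(rep(1000, 10000), 50)
  expect_gt(mean(noisy), 1000)                      # Rician bias is positive
  expect_lt(abs(mean(noisy) - rice_mean(1000, 50)) / rice_mean(1000, 50), 0.01)
})

test_that("phantom construction is seed-reproducible and leaves the session RNG alone", {
  spec <- small_phantom_spec(noise_sigma = 20, seed = 99L)
  p1 <- build_phantom(spec)
  set.seed(1234); rng_before <- .Random.seed
  p2 <- build_phantom(spec)
  expect_identical(rng_before, .Random.seed)        # RNG state restored
  expect_identical(p1$dwi, p2$dwi)
  p3 <- build_phantom(small_phantom_spec(noise_sigma = 20, seed = 100L))
  expect_false(identical(p1$dwi, p3$dwi))
})

test_that("noiseless phantom satisfies the closed-form f_UL everywhere", {
  spec <- small_phantom_spec()
  ph <- build_phantom(spec)
  expect_true(all(ph$truth$f_map >= 0 & ph$truth$f_map <= 1))
  maps <- compute_maps(ph$dwi, ph$scheme, d_water = spec$d_water)
  l3t <- tensor_map_lambda3(ph$truth$tensor_map)
  cf <- ful_closed_form(as.vector(ph$truth$f_map), l3t, spec$d_water)
  expect_lt(max(abs(as.vector(maps$f_ul) - cf)), 1e-8)
  # measured bound >= truth; equality only at f = 1 (no zero-lambda3 tissue here)
  gap <- as.vector(maps$f_ul) - as.vector(ph$truth$f_map)
  expect_true(all(gap >= -1e-10))
  expect_true(all(gap[abs(gap) < 1e-10] >= 0 |
                    as.vector(ph$truth$f_map)[abs(gap) < 1e-10] == 1))
  # CSF voxels reach the clamp boundary (exact up to double roundoff)
  csf <- as.vector(ph$truth$labels) == 1L
  expect_equal(maps$f_ul[array(csf, dim(maps$f_ul))],
               rep(1, sum(csf)), tolerance = 1e-10)
  # prolate slab at f = 0.02 with tissue lambda3 = 0.5e-3
  white <- as.vector(ph$truth$labels) == 3L
  expect_equal(unique(round(as.vector(maps$f_ul)[white], 10)),
               round(ful_closed_form(0.02, 0.5e-3, spec$d_water), 10))
})

test_that("signal-mixing phantoms stay in [0,1] and keep CSF at 1", {
  spec <- small_phantom_spec(mixing_mode = "signal")
  ph <- build_phantom(spec)
  maps <- compute_maps(ph$dwi, ph$scheme, d_water = spec$d_water)
  expect_true(all(maps$f_ul >= 0 & maps$f_ul <= 1))
  csf <- array(as.vector(ph$truth$labels) == 1L, dim(maps$f_ul))
  expect_equal(maps$f_ul[csf], rep(1, sum(csf)), tolerance = 1e-10)
  # bi-exponential signals fitted with one tensor differ from tensor mixing
  pt <- build_phantom(small_phantom_spec(mixing_mode = "tensor"))
  mt <- compute_maps(pt$dwi, pt$scheme, d_water = spec$d_water)
  mid <- as.vector(ph$truth$f_map) > 0.2 & as.vector(ph$truth$f_map) < 0.8
  expect_gt(max(abs(maps$f_ul[array(mid, dim(maps$f_ul))] -
                      mt$f_ul[array(mid, dim(mt$f_ul))])), 1e-4)
})

test_that("moderate noise perturbs f_UL only modestly (regression guard)", {
  spec_clean <- small_phantom_spec()
  spec_noisy <- small_phantom_spec(noise_sigma = 0.02 * 1000, seed = 5L)
  m_clean <- compute_maps(build_phantom(spec_clean)$dwi, spec_clean$scheme,
                          d_water = spec_clean$d_water)
  m_noisy <- compute_maps(build_phantom(spec_noisy)$dwi, spec_noisy$scheme,
                          d_water = spec_noisy$d_water)
  expect_lt(median(abs(m_noisy$f_ul - m_clean$f_ul)), 0.05)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(noise_sigma = -1))
  expect_error(phantom_spec(s0 = 0))
  bad_mats <- default_materials()
  bad_mats$white$tensor <- diag(c(1, 1, -0.1)) * 1e-3
  expect_error(phantom_spec(materials = bad_mats), "semidefinite")
  bad_f <- default_materials()
  bad_f$gray$f <- 1.5
  expect_error(phantom_spec(materials = bad_f))
})
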