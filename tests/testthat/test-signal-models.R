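test_that("sphere boundary-condition roots match an independent bisection", {
  r <- sphere_gpd_roots(10)
  oracle <- oracle_j1prime_roots(10)
  expect_equal(r, oracle, tolerance = 1e-9)
  expect_equal(r[1:3], c(2.08158, 5.94037, 9.20584), tolerance = 1e-5)
  expect_true(all(diff(r) > 0))
  # spacing approaches pi for large index
  r50 <- sphere_gpd_roots(50)
  expect_equal(diff(r50)[49], pi, tolerance = 1e-3)
  expect_error(sphere_gpd_roots(0), ">= 1")
})

test_that("restricted-sphere attenuation has the right limits and bounds", {
  p <- two_dt_protocol()
  a <- restricted_sphere_attenuation(10, 1.0, p)
  expect_true(all(a > 0 & a <= 1))
  expect_identical(a[b0_indices(p)], c(1, 1))
  # motional-narrowing limit: tiny sphere barely attenuates
  expect_true(all(restricted_sphere_attenuation(0.1, 1.0, p) > 0.999))
  # monotonically non-increasing in G at fixed timing
  short <- p[p$Delta == 9.86, ]
  class(short) <- class(p)
  expect_true(all(diff(restricted_sphere_attenuation(8, 1.2, short)) <= 0))
})

test_that("GPD kernel agrees with an independently coded implementation", {
  p <- two_dt_protocol()
  s <- mm_signal(list(R = 10, Di = 1.0, De = 0.6, fi = 0.41), p)
  expect_equal(s, oracle_mm_signal(10, 1.0, 0.6, 0.41, p), tolerance = 1e-6)
  expect_length(s, 8L)
})

test_that("GPD attenuation matches the random-walk Monte Carlo oracle", {
  p <- two_dt_protocol()
  one <- p[4, ]; class(one) <- class(p)   # G=293, Delta=9.86
  gpd <- restricted_sphere_attenuation(10, 1.0, one)
  mc <- oracle_mc_attn(10, 1.0, 293, 4.65 - 0.245, 9.86)
  expect_lt(abs(gpd - mc), 0.02)
})

test_that("series truncation at 30 roots is converged", {
  p <- two_dt_protocol()
  a30 <- restricted_sphere_attenuation(18, 2.5, p, n_roots = 30)
  a40 <- restricted_sphere_attenuation(18, 2.5, p, n_roots = 40)
  expect_lt(max(abs(a30 - a40)), 1e-8)
})

test_that("trapezoid-integral and rectangular-equivalent GPD agree closely", {
  p <- two_dt_protocol()
  for (pars in list(c(5, 0.5), c(10, 1.0), c(10, 2.0))) {
    rect <- restricted_sphere_attenuation(pars[1], pars[2], p)
    trap <- restricted_sphere_attenuation(pars[1], pars[2], p,
                                          waveform = "trapezoid")
    expect_lt(max(abs(rect - trap)), 0.005)
  }
})

test_that("MM signal reduces to its compartments in the limits", {
  p <- two_dt_protocol()
  expect_equal(mm_signal(list(R = 10, Di = 1, De = 0.8, fi = 0), p),
               exp(-p$b * 1e-3 * 0.8))
  s <- mm_signal(list(R = 10, Di = 1, De = 0.8, fi = 1), p)
  expect_identical(s[b0_indices(p)], c(1, 1))
  # signals decrease monotonically with b at fixed Delta
  for (D in unique(p$Delta)) {
    sub <- s[p$Delta == D][order(p$b[p$Delta == D])]
    expect_true(all(diff(sub) < 0))
  }
})

test_that("TID signal is a pure b-value monoexponential", {
  p <- two_dt_protocol()
  s <- tid_signal(1.0, p)
  expect_identical(s[b0_indices(p)], c(1, 1))
  expect_equal(s[4], exp(-p$b[4] * 1e-3), tolerance = 1e-12)
  # identical signal wherever b is equal, regardless of Delta (b scales as
  # G^2 at fixed timing, so G2 below matches the b of G=200 at Delta=9.86)
  G2 <- 200 * sqrt(compute_b_value(200, 4.65, 9.86, 0.245) /
                   compute_b_value(200, 4.65, 15, 0.245))
  peq <- pgse_protocol(G = c(0, 200, G2), delta = 4.65,
                       Delta = c(9.86, 9.86, 15), rise = 0.245)
  seq_ <- tid_signal(1.3, peq)
  expect_equal(seq_[2], seq_[3], tolerance = 1e-10)
})

test_that("ADC signal is normalised to the b = 150 measurement", {
  p1 <- single_dt_protocol()
  s <- adc_signal(0.7, p1)
  expect_equal(s[1], 1)
  expect_equal(adc_signal(0.7, p1)[3], exp(-0.85 * 0.7), tolerance = 0.01)
  expect_equal(adc_signal(0.1, p1)[3], exp(-0.085), tolerance = 0.001)
  expect_error(adc_signal(0.7, two_dt_protocol()), "single-diffusion-time")
  pno <- pgse_protocol(G = c(250, 293), delta = 4.65, Delta = 9.86,
                       rise = 0.245, require_b0 = FALSE)
  expect_error(adc_signal(0.7, pno), "b near 150")
})

test_that("restriction lowers the long-diffusion-time apparent diffusivity", {
  p <- two_dt_protocol()
  fit_app <- function(sig, sub) {
    b <- p$b[sub] * 1e-3
    optimize(function(D) sum((sig[sub] - exp(-b * D))^2), c(0.05, 3))$minimum
  }
  for (R in c(5, 10, 15)) {
    s <- mm_signal(list(R = R, Di = 1.0, De = 0.6, fi = 0.5), p)
    d_short <- fit_app(s, which(p$Delta == 9.86))
    d_long <- fit_app(s, which(p$Delta == 40.0))
    expect_gte(d_short, d_long)
  }
})
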