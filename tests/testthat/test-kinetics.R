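test_that("Michaelis-Menten fit recovers noiseless parameters and the half-saturation identity", {
  d <- mm_test_points(kcat = 228, Km = 0.10)
  f <- fit_michaelis_menten(d, T = 298)
  expect_equal(f$kcat$value, 228, tolerance = 1e-6)
  expect_equal(f$Km$value, 0.10, tolerance = 1e-6)
  # fitted curve at S = Km gives half the saturating rate
  v_half <- f$kcat$value * 1e-6 * f$Km$value / (f$Km$value + f$Km$value)
  expect_equal(v_half, f$kcat$value * 1e-6 / 2)
})

test_that("Michaelis-Menten fit is invariant to joint rescaling of E0 and v", {
  d <- mm_test_points()
  f1 <- fit_michaelis_menten(d)
  d2 <- transform(d, E0 = E0 * 7, v = v * 7)
  f2 <- fit_michaelis_menten(d2)
  expect_equal(f2$kcat$value, f1$kcat$value, tolerance = 1e-8)
  expect_equal(f2$Km$value, f1$Km$value, tolerance = 1e-8)
})

test_that("Michaelis-Menten fit rejects degenerate designs", {
  d <- data.frame(S = rep(0.5, 6), v = rep(1e-4, 6), E0 = 1)
  expect_error(fit_michaelis_menten(d), "distinct")
  expect_error(fit_michaelis_menten(data.frame(S = c(-1, 1, 2, 3),
                                               v = 1:4, E0 = 1)),
               "positive")
})

test_that("median Km over noisy triplicate assays stays inside the reported band", {
  set.seed(1)
  km <- replicate(200, {
    d <- mm_test_points()
    d$v <- d$v * (1 + rnorm(nrow(d), 0, 0.03))
    fit_michaelis_menten(d)$Km$value
  })
  expect_lt(abs(median(km) - 0.10), 0.03)
})

test_that("Arrhenius regression matches the two-point closed form", {
  # line pinned by (298 K, 228 s^-1) and (318 K, 760 s^-1); third point on
  # the same line so the n >= 3 fit is exact
  Ea_closed <- 8.31446 * log(760 / 228) / (1 / 298 - 1 / 318) / 1000
  Tm <- 308
  k_mid <- exp(log(228) + (Ea_closed * 1000 / 8.31446) * (1 / 298 - 1 / Tm))
  f <- fit_arrhenius(c(298, Tm, 318), c(228, k_mid, 760))
  expect_equal(f$Ea$value, Ea_closed, tolerance = 1e-10)
  expect_equal(Ea_closed, 47.4, tolerance = 0.05 / 47.4)
})

test_that("Arrhenius regression recovers a noiseless synthetic series exactly", {
  T <- seq(283, 318, by = 5)
  k <- 228 * exp(-(49.1e3 / 8.31446) * (1 / T - 1 / 298))
  f <- fit_arrhenius(T, k)
  expect_equal(f$Ea$value, 49.1, tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # constant kcat: zero slope, zero activation energy
  f0 <- fit_arrhenius(T, rep(100, length(T)))
  expect_equal(f0$Ea$value, 0, tolerance = 1e-12)
  expect_true(is.finite(f0$Ea$se))
})

test_that("Arrhenius regression validates its inputs", {
  expect_error(fit_arrhenius(c(298, 308), c(1, 2)), "3 temperatures")
  expect_error(fit_arrhenius(c(298, 308, 318), c(1, -2, 3)), "positive")
})

test_that("Ea estimator is unbiased over many noisy series", {
  set.seed(1)
  T <- seq(283, 318, by = 5)
  ktrue <- 228 * exp(-(49.1e3 / 8.31446) * (1 / T - 1 / 298))
  ea <- replicate(500, fit_arrhenius(T, ktrue * (1 + rnorm(8, 0, 0.07)))$Ea$value)
  expect_lt(abs(mean(ea) - 49.1), 2 * sd(ea) / sqrt(length(ea)))
})

test_that("extrapolation reproduces the high-temperature turnover numbers", {
  ph_wt <- arrhenius_line(228, 49.1, 298)
  k318 <- extrapolate_kcat(ph_wt, 318)
  expect_equal(k318$value, 793, tolerance = 0.002)
  # within 5% of the measured 760 s^-1
  expect_lt(abs(k318$value - 760) / 760, 0.05)

  ph_mut <- arrhenius_line(211, 32.1, 298)
  k318_mut <- extrapolate_kcat(ph_mut, 318)
  expect_equal(k318_mut$value, 477, tolerance = 0.002)
  # rank order flips at high temperature: bridge-bearing variant is faster
  expect_lt(k318_mut$value, k318$value)
})

test_that("extrapolating a fitted line recovers its own noiseless points", {
  T <- seq(283, 318, by = 5)
  k <- 500 * exp(-(40e3 / 8.31446) * (1 / T - 1 / 298))
  f <- fit_arrhenius(T, k)
  for (i in seq_along(T))
    expect_equal(extrapolate_kcat(f, T[i])$value, k[i], tolerance = 1e-8)
  # refitting extrapolated data returns the same parameters (idempotence)
  k2 <- vapply(T, function(x) extrapolate_kcat(f, x)$value, 0)
  f2 <- fit_arrhenius(T, k2)
  expect_equal(f2$Ea$value, f$Ea$value, tolerance = 1e-8)
  expect_equal(f2$lnA$value, f$lnA$value, tolerance = 1e-8)
})

test_that("crossover temperature solves the two-line intersection and is symmetric", {
  a <- arrhenius_line(228, 49.1, 298)
  b <- arrhenius_line(211, 32.1, 298)
  Tx <- crossover_temperature(a, b)
  # independent check: the two lines predict the same rate at Tx
  expect_equal(extrapolate_kcat(a, Tx)$value, extrapolate_kcat(b, Tx)$value,
               tolerance = 1e-10)
  expect_equal(Tx, crossover_temperature(b, a))
  expect_equal(Tx, 294.7, tolerance = 0.1 / 294.7)

  # identical lines have no crossing; lines built to cross at 298 K do so exactly
  expect_true(is.na(crossover_temperature(a, a)))
  c298 <- arrhenius_line(228, 40.0, 298)
  d298 <- arrhenius_line(228, 55.0, 298)
  expect_equal(crossover_temperature(c298, d298), 298, tolerance = 1e-12)
})

test_that("kcat_series assembles per-temperature fits ready for Arrhenius work", {
  assay <- generate_assay_data("PhWT", noise_cv = 0, seed = 3)
  ser <- kcat_series(assay)
  expect_equal(ser$T, seq(283, 318, by = 5))
  f <- fit_arrhenius(ser$T, ser$kcat)
  expect_equal(f$Ea$value, 49.1, tolerance = 1e-6)
  expect_equal(ser$kcat[ser$T == 298], 228, tolerance = 1e-6)
})
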