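test_that("transition-state decomposition reproduces the published variant rows", {
  # salt-bridge-bearing thermophilic wild type
  a <- eyring_decompose(quantity(228, 15), quantity(49.1, 1.4), 298)
  expect_equal(a$dG$value, 59.5, tolerance = 0.05 / 59.5)
  expect_equal(a$dH$value, 46.6, tolerance = 0.05 / 46.6)
  expect_equal(a$TdS$value, -12.9, tolerance = 0.05 / 12.9)
  expect_equal(a$dS$value, -43, tolerance = 0.5 / 43)

  # bridge-free mesophilic pseudo-wild-type
  b <- eyring_decompose(quantity(1268, 100), quantity(29.5, 1.9), 298)
  expect_equal(b$dG$value, 55.3, tolerance = 0.05 / 55.3)
  expect_equal(b$dH$value, 27.0, tolerance = 0.05 / 27.0)
  expect_equal(b$TdS$value, -28.3, tolerance = 0.05 / 28.3)
  expect_equal(b$dS$value, -95, tolerance = 0.5 / 95)

  # dH error passes through; dG error is RT*se/kcat in kJ
  expect_equal(a$dH$se, 1.4)
  expect_equal(a$dG$se, 8.31446 * 298 / 1000 * 15 / 228)
})

test_that("kcat equal to kB*T/h gives exactly zero activation free energy", {
  cst <- physical_constants()
  a <- eyring_decompose(cst$kB * 298 / cst$h, 50, 298)
  expect_equal(a$dG$value, 0)
})

test_that("decomposition round-trips kcat and satisfies TdS = dH - dG", {
  cst <- physical_constants()
  kp <- kinetics_presets()
  for (i in seq_len(nrow(kp))) {
    a <- eyring_decompose(kp$kcat[i], kp$Ea[i], 298)
    k_back <- cst$kB * 298 / cst$h * exp(-1000 * a$dG$value /
                                           (cst$R * 298))
    expect_equal(k_back, kp$kcat[i], tolerance = 1e-10)
    expect_identical(a$TdS$value, a$dH$value - a$dG$value)
  }
})

test_that("invalid decomposition inputs fail with the offending field named", {
  expect_error(eyring_decompose(-1, 49.1), "kcat")
  expect_error(eyring_decompose(228, 49.1, T_ref = 0), "T_ref")
})

test_that("paired activation differences match the published delta columns", {
  wt <- eyring_decompose(quantity(228, 15), quantity(49.1, 1.4))
  mut <- eyring_decompose(quantity(211, 25), quantity(32.1, 1.7))
  dd <- delta_delta(mut, wt, "PhG91A", "PhWT")
  expect_equal(dd$ddH$value, -17.0, tolerance = 0.05 / 17)
  expect_equal(dd$ddH$se, sqrt(1.4^2 + 1.7^2))     # quadrature -> 2.2
  expect_equal(dd$TddS$value, -17.2, tolerance = 0.05 / 17.2)
  expect_equal(dd$ddG$value, 0.2, tolerance = 0.05 / 0.2)
  expect_identical(dd$ddG$value, dd$ddH$value - dd$TddS$value)

  hu_wt <- eyring_decompose(quantity(1214, 196), quantity(37.6, 3.1))
  hu_g99 <- eyring_decompose(quantity(1405, 225), quantity(52.5, 2.5))
  dd2 <- delta_delta(hu_wt, hu_g99)
  expect_equal(dd2$ddH$value, -14.9, tolerance = 0.05 / 14.9)
  expect_equal(dd2$TddS$value, -15.2, tolerance = 0.1 / 15.2)
  expect_equal(dd2$ddG$value, 0.4, tolerance = 0.05 / 0.4)
})

test_that("delta_delta is antisymmetric in values and symmetric in errors", {
  set.seed(11)
  for (rep in 1:10) {
    a <- eyring_decompose(quantity(runif(1, 50, 2000), runif(1, 5, 100)),
                          quantity(runif(1, 20, 60), runif(1, 1, 3)))
    b <- eyring_decompose(quantity(runif(1, 50, 2000), runif(1, 5, 100)),
                          quantity(runif(1, 20, 60), runif(1, 1, 3)))
    ab <- delta_delta(a, b)
    ba <- delta_delta(b, a)
    for (f in c("ddG", "ddH", "TddS", "ddS")) {
      expect_equal(ab[[f]]$value, -ba[[f]]$value)
      expect_identical(ab[[f]]$se, ba[[f]]$se)
    }
  }
  # self-difference: zero values, sqrt(2)-inflated errors
  self <- delta_delta(a, a)
  expect_identical(self$ddH$value, 0)
  expect_equal(self$ddH$se, sqrt(2) * a$dH$se)
})

test_that("delta_delta refuses mismatched reference temperatures", {
  a <- eyring_decompose(228, 49.1, 298)
  b <- eyring_decompose(228, 49.1, 310)
  expect_error(delta_delta(a, b), "temperature")
})

test_that("compensation curve crosses zero at ddH/ddS and is exact at T_ref", {
  wt <- eyring_decompose(quantity(228, 15), quantity(49.1, 1.4))
  mut <- eyring_decompose(quantity(211, 25), quantity(32.1, 1.7))
  dd <- delta_delta(mut, wt)
  cc <- compensation_curve(dd, T_grid = seq(280, 320, 1))
  # hand-derived: Tc = 298 * ddH / TddS for T-independent ddH, ddS
  expect_equal(cc$Tc, 298 * dd$ddH$value / dd$TddS$value, tolerance = 1e-12)
  expect_equal(cc$Tc, 294.5, tolerance = 0.2 / 294.5)
  # at the reference temperature the curve reproduces ddG = ddH - TddS
  at_ref <- compensation_curve(dd, T_grid = 298)$curve
  expect_equal(at_ref$ddG, dd$ddH$value - dd$TddS$value)
  expect_equal(at_ref$ddG, dd$ddG$value, tolerance = 1e-12)
})

test_that("compensation temperature equals T_ref when ddH = TddS, absent when ddS = 0", {
  mk <- function(ddH, TddS) {
    structure(list(label_a = "x", label_b = "y", T_ref = 298,
                   ddG = quantity(ddH - TddS), ddH = quantity(ddH),
                   TddS = quantity(TddS),
                   ddS = quantity(1000 * TddS / 298)),
              class = "delta_delta")
  }
  expect_equal(compensation_curve(mk(-17, -17))$Tc, 298)
  expect_true(is.na(compensation_curve(mk(-17, 0))$Tc))
})

test_that("entropic fold-change matches the Boltzmann factor and its symmetry", {
  f <- entropic_fold_change(20, 298)
  expect_equal(f, exp(20000 / (8.31446 * 298)), tolerance = 1e-12)
  expect_gte(f, 3000)
  expect_identical(entropic_fold_change(0, 310), 1)
  expect_equal(entropic_fold_change(-20, 298), 1 / f, tolerance = 1e-12)
  expect_error(entropic_fold_change(20, -5), "T")
})
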