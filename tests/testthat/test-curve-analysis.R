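test_that("Guinier fit inverts a constructed exponential exactly", {
  q <- seq(0.02, 1.2, length.out = 400)
  rg <- 4.92
  cv <- scattering_curve(q, 10 * exp(-q^2 * rg^2 / 3))
  gf <- guinier_fit(cv, 0.10, 0.22)
  expect_equal(gf$rg, rg, tolerance = 1e-6)
  expect_equal(gf$i0, 10, tolerance = 1e-6)
  expect_equal(gf$valid, 0.22 * rg <= 1.5)
  # constant curve: zero slope -> R_G = 0 (to numerical precision)
  cvc <- scattering_curve(q, rep(2, length(q)))
  expect_lt(guinier_fit(cvc, 0.10, 0.22)$rg, 1e-6)
  # rising curve: positive slope is non-physical
  cvr <- scattering_curve(q, exp(q^2))
  expect_error(guinier_fit(cvr, 0.10, 0.22), "non-physical")
  expect_error(guinier_fit(cv, 0.10, 0.105), "Fewer than 4")
})

test_that("cross-sectional fits invert constructed curves at the standard windows", {
  q <- seq(0.02, 1.2, length.out = 600)
  cv1 <- scattering_curve(q, (5 / q) * exp(-q^2 * 2.50^2 / 2))
  f1 <- cross_section_fit(cv1, which = "RXS1")
  expect_equal(f1$q_range, c(0.29, 0.52))
  expect_equal(f1$rxs, 2.50, tolerance = 1e-6)
  cv2 <- scattering_curve(q, (5 / q) * exp(-q^2 * 1.41^2 / 2))
  f2 <- cross_section_fit(cv2, which = "RXS2")
  expect_equal(f2$q_range, c(0.66, 1.05))
  expect_equal(f2$rxs, 1.41, tolerance = 1e-6)
  # pure 1/Q: zero cross-sectional radius (to numerical precision)
  cv0 <- scattering_curve(q, 5 / q)
  expect_lt(cross_section_fit(cv0, which = "RXS1")$rxs, 1e-6)
})

test_that("default Q windows match the standard antibody presets", {
  expect_equal(q_windows$rg_xray, c(0.10, 0.22))
  expect_equal(q_windows$rg_neutron, c(0.07, 0.27))
  expect_equal(q_windows$rxs1, c(0.29, 0.52))
  expect_equal(q_windows$rxs2, c(0.66, 1.05))
})

test_that("IFT recovers the sphere P(r), D_max consistency, and non-negativity", {
  r <- 3
  q <- seq(0, 1.5, length.out = 300)
  cv <- analytic_sphere_curve(r, q)
  pr <- ift_pr(cv, dmax = 6)
  pa <- analytic_sphere_pr(r, pr$r)
  expect_lt(max(abs(pr$p - pa)) / max(pa), 0.05)
  expect_lt(abs(pr$rg / (sqrt(3 / 5) * r) - 1), 0.02)
  expect_true(all(pr$p >= 0))
  expect_equal(pr$p[1], 0)
  expect_equal(pr$p[length(pr$p)], 0)
  area <- sum(pr$p) * (pr$r[2] - pr$r[1])
  expect_equal(area, 1, tolerance = 1e-9)
  # a dmax far below the true extent is rejected with advice
  expect_error(ift_pr(cv, dmax = 3), "larger")
})

test_that("IFT of a noiseless Guinier curve reproduces the Guinier R_G within 2%", {
  rg <- 4.9
  q <- seq(0, 0.8, length.out = 250)
  cv <- scattering_curve(q, exp(-q^2 * rg^2 / 3))
  pr <- ift_pr(cv, dmax = 16)
  expect_lt(abs(pr$rg / rg - 1), 0.02)
})

test_that("dmax scanning settles near the true maximum dimension", {
  q <- seq(0, 1.5, length.out = 200)
  cv <- analytic_sphere_curve(3, q)
  d <- estimate_dmax(cv, dmax_range = c(4, 10), step = 0.5, n_r = 61)
  expect_lt(abs(as.numeric(d) - 6), 1.0)
})

test_that("P(r) peak finding resolves two peaks, single peaks, and shoulders", {
  r <- seq(0, 15, by = 0.05)
  gauss <- function(mu, sd) exp(-(r - mu)^2 / (2 * sd^2))
  # two clear peaks at the antibody M1/M2 scale
  p2 <- 2 * gauss(4.5, 0.8) + 1 * gauss(7.3, 0.8)
  d2 <- distance_distribution(r, p2 / sum(p2) / 0.05, dmax = 15, rg = 5)
  pk <- find_pr_peaks(d2)
  expect_lt(abs(pk[["m1"]] - 4.5), 0.2)
  expect_lt(abs(pk[["m2"]] - 7.3), 0.2)
  # single Gaussian: no M2
  p1 <- gauss(4.5, 0.8)
  d1 <- distance_distribution(r, p1 / sum(p1) / 0.05, dmax = 15, rg = 5)
  expect_true(is.na(find_pr_peaks(d1)[["m2"]]))
  # weak second component appearing as a shoulder
  ps <- gauss(4.5, 0.9) + 0.15 * gauss(7.3, 0.7)
  ds <- distance_distribution(r, ps / sum(ps) / 0.05, dmax = 15, rg = 5)
  pks <- find_pr_peaks(ds)
  expect_false(is.na(pks[["m2"]]))
  expect_lt(abs(pks[["m2"]] - 7.3), 0.5)
})

test_that("normalized Kratky of a Guinier curve peaks at sqrt(3) with height 3/e", {
  q <- seq(0.01, 1.5, length.out = 500)
  rg <- 3
  cv <- scattering_curve(q, 7 * exp(-q^2 * rg^2 / 3))
  gf <- guinier_fit(cv, 0.05, 1.0 / rg)
  kr <- kratky_normalized(cv, gf)
  pk <- kratky_peaks(kr)
  expect_gte(nrow(pk), 1)
  expect_lt(abs(pk$x[1] - sqrt(3)), 0.02)
  expect_lt(abs(pk$y[1] - 3 / exp(1)), 0.01)
  # scaling I leaves the normalized transform unchanged
  cv2 <- scattering_curve(q, 35 * exp(-q^2 * rg^2 / 3))
  gf2 <- guinier_fit(cv2, 0.05, 1.0 / rg)
  kr2 <- kratky_normalized(cv2, gf2)
  expect_equal(kr2$y, kr$y, tolerance = 1e-9)
})

test_that("Kratky of the sphere curve peaks near sqrt(3)", {
  r <- 3
  rg <- sqrt(3 / 5) * r
  q <- seq(0.01, 2.2 / rg, length.out = 400)
  cv <- analytic_sphere_curve(r, q)
  gf <- guinier_fit(cv, 0.05, 1.0 / rg)
  kr <- kratky_normalized(cv, gf)
  expect_lt(abs(kratky_peaks(kr)$x[1] - 1.73), 0.1)
})

test_that("curve regularisation extends to Q = 0 on a uniform grid", {
  q <- seq(0.05, 1.6, length.out = 173)   # non-uniform start, no zero
  rg <- 4.9
  cv <- scattering_curve(q, 3 * exp(-q^2 * rg^2 / 3))
  gf <- guinier_fit(cv, 0.10, 0.22)
  reg <- regularize_curve(cv, n_points = 680, q_max = 1.5, fit = gf)
  expect_equal(nrow(reg), 680)
  expect_equal(reg$q[1], 0)
  expect_equal(diff(range(diff(reg$q))), 0, tolerance = 1e-12)
  expect_equal(reg$intensity[1], gf$i0, tolerance = 1e-6)
  # regularising an already-uniform curve reproduces it at shared Q
  q2 <- seq(0, 1.5, length.out = 680)
  cv2 <- scattering_curve(q2, 3 * exp(-q2^2 * rg^2 / 3))
  gf2 <- guinier_fit(cv2, 0.10, 0.22)
  reg2 <- regularize_curve(cv2, n_points = 680, q_max = 1.5, fit = gf2)
  expect_lt(max(abs(reg2$intensity - cv2$intensity) / cv2$intensity), 1e-6)
  expect_error(regularize_curve(cv, n_points = 100, q_max = 2, fit = gf),
               "beyond")
})

test_that("curve text round trip preserves data", {
  q <- seq(0.01, 1, length.out = 30)
  cv <- scattering_curve(q, exp(-q^2), sigma = rep(0.01, 30),
                         contrast = "neutron")
  tf <- tempfile(fileext = ".dat")
  write_curve(cv, tf)
  cv2 <- read_curve(tf, contrast = "neutron")
  expect_equal(cv2$q, cv$q, tolerance = 1e-8)
  expect_equal(cv2$intensity, cv$intensity, tolerance = 1e-8)
  expect_equal(cv2$sigma, cv$sigma, tolerance = 1e-8)
})
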