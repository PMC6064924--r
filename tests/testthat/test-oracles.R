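test_that("Reynolds number reproduces the blood-model value and scales linearly", {
  pr <- fluid_properties()
  expect_equal(round(reynolds_number(pr, 1, 0.00158)), 488)
  expect_equal(reynolds_number(pr, 1, 0.00158), 487.825, tolerance = 1e-6)
  expect_equal(reynolds_number(pr, 0, 0.00158), 0)
  expect_equal(reynolds_number(pr, 1, 2 * 0.00158),
               2 * reynolds_number(pr, 1, 0.00158))
  expect_error(reynolds_number(pr, 1, -1), "invalid physical parameter")
  expect_error(fluid_properties(-1, 0.004), "invalid physical parameter")
})

test_that("Womersley number matches hand arithmetic and its scalings", {
  pr <- fluid_properties()
  a <- womersley_number(0.00079, 2 * pi / 0.1, pr)
  expect_equal(a, 0.00079 * sqrt(62.8319 * 1235 / 0.004), tolerance = 1e-4)
  expect_equal(round(a, 2), 3.48)
  expect_lt(womersley_number(0.00079, 1e-9, pr), 1e-3)  # steady limit
  expect_equal(womersley_number(2 * 0.00079, 2 * pi / 0.1, pr), 2 * a)
})

test_that("steady Poiseuille wall shear formulas give the hand-computed values", {
  pr <- fluid_properties()
  expect_equal(poiseuille_tube_wss(pr, 0.1, 0.00079), 4 * 0.004 * 0.1 / 0.00079)
  expect_equal(round(poiseuille_tube_wss(pr, 0.1, 0.00079), 3), 2.025)
  expect_equal(round(plane_poiseuille_wss(pr, 0.1, 0.00158), 3), 1.519)
  expect_equal(poiseuille_tube_wss(pr, 0, 0.00079), 0)
  expect_equal(poiseuille_tube_wss(pr, 0.2, 0.00079),
               2 * poiseuille_tube_wss(pr, 0.1, 0.00079))
  expect_equal(plane_poiseuille_wss(pr, 0.1, 0.00158 / 2),
               2 * plane_poiseuille_wss(pr, 0.1, 0.00158))
  expect_error(plane_poiseuille_wss(pr, 0.1, 0), "invalid physical parameter")
})

test_that("dimensionless groups are invariant under a CGS unit change", {
  # SI: kg, m, s -> CGS: g, cm, s
  si <- fluid_properties(1235, 0.004)
  cgs <- fluid_properties(1235 / 1000, 0.004 * 10)  # g/cm^3, poise
  expect_equal(reynolds_number(si, 1, 0.00158),
               reynolds_number(cgs, 100, 0.158), tolerance = 1e-12)
  expect_equal(womersley_number(0.00079, 62.83, si),
               womersley_number(0.079, 62.83, cgs), tolerance = 1e-12)
})

test_that("Womersley tube series reduces to the steady and quasi-steady limits", {
  pr <- fluid_properties()
  R <- 0.00079
  # steady gradient only: constant tau = G R / 2
  g0 <- harmonic_pressure_gradient(100, numeric(), numeric(), 0.1)
  s0 <- womersley_wss_series(g0, R, pr, 32L)
  expect_equal(s0$tau_pa, rep(100 * R / 2, 32L), tolerance = 1e-14)
  # low alpha: tau(t) within 2% of the quasi-steady value G(t) R / 2
  Tslow <- 500
  expect_lt(womersley_number(R, 2 * pi / Tslow, pr), 0.3)
  g1 <- harmonic_pressure_gradient(100, 50, 0.3, Tslow)
  s1 <- womersley_wss_series(g1, R, pr, 64L)
  qs <- (100 + 50 * cos(2 * pi * s1$time_s / Tslow + 0.3)) * R / 2
  expect_lt(max(abs(s1$tau_pa - qs) / abs(qs)), 0.02)
})

test_that("tube series agrees with numerical differentiation of the velocity profile", {
  pr <- fluid_properties()
  R <- 0.00079
  g <- harmonic_pressure_gradient(80, c(60, 20), c(0.5, -1), 0.1)
  r <- seq(0, R, length.out = 4001L)
  tt <- seq(0, 0.1, length.out = 33L)[1:32]
  U <- womersley_tube_velocity(g, R, pr, r, tt)
  h <- r[2] - r[1]
  dudr <- (3 * U[4001L, ] - 4 * U[4000L, ] + U[3999L, ]) / (2 * h)
  tau_fd <- -pr$dynamic_viscosity_eta * dudr
  s <- womersley_wss_series(g, R, pr, 32L)
  expect_lt(max(abs(tau_fd - s$tau_pa)) / max(abs(s$tau_pa)), 1e-3)
})

test_that("series time-mean equals the steady component and scales linearly", {
  pr <- fluid_properties()
  R <- 0.00079
  g <- harmonic_pressure_gradient(120, c(90, 30, 10), c(0.2, 1.1, -0.4), 0.1)
  s <- womersley_wss_series(g, R, pr, 256L)
  expect_lt(abs(mean(s$tau_pa) - 120 * R / 2) / (120 * R / 2), 1e-3)
  # linearity in the driving amplitudes
  g2 <- harmonic_pressure_gradient(240, c(180, 60, 20), c(0.2, 1.1, -0.4), 0.1)
  s2 <- womersley_wss_series(g2, R, pr, 256L)
  expect_equal(s2$tau_pa, 2 * s$tau_pa, tolerance = 1e-12)
  # channel variant too
  sc <- womersley_channel_wss_series(g, 0.00158, pr, 256L)
  expect_lt(abs(mean(sc$tau_pa) - 120 * 0.00079) / (120 * 0.00079), 1e-3)
})

test_that("channel gradient conversion reproduces the target mean-velocity waveform", {
  pr <- fluid_properties()
  h <- 0.00158
  bw <- two_harmonic_waveform()
  g <- channel_gradient_for_waveform(bw, h, pr, 4L)
  y <- seq(-h / 2, h / 2, length.out = 4001L)
  tt <- seq(0, 0.1, length.out = 33L)[1:32]
  U <- womersley_channel_velocity(g, h, pr, y, tt)
  # Simpson weights for the cross-channel mean
  w <- c(1, rep(c(4, 2), 1999L), 4, 1); w <- w / sum(w)
  meanv <- as.numeric(w %*% U)
  expect_lt(max(abs(meanv - evaluate_waveform(bw, tt))), 2e-4 * 0.07)

  # tube conversion: recovered mean velocity matches too
  gt <- tube_gradient_for_waveform(bw, 0.00079, pr, 4L)
  r <- seq(0, 0.00079, length.out = 2001L)
  Ut <- womersley_tube_velocity(gt, 0.00079, pr, r, tt)
  wr <- r; wr[1] <- r[2] / 4  # area weights ~ r dr
  meant <- as.numeric((wr / sum(wr)) %*% Ut)
  expect_lt(max(abs(meant - evaluate_waveform(bw, tt))), 2e-3 * 0.07)
})

test_that("extreme Womersley numbers are rejected as out of range", {
  pr <- fluid_properties()
  g <- harmonic_pressure_gradient(10, 10, 0, 1e-5)  # very high frequency
  expect_error(womersley_wss_series(g, 0.01, pr, 16L), "out of supported range")
})

test_that("complex Bessel series matches base besselJ on the real axis", {
  z <- seq(0.1, 15, length.out = 40)
  jb <- aortashear:::bessel_j01_complex(z + 0i)
  expect_equal(Re(jb$j0), besselJ(z, 0), tolerance = 1e-10)
  expect_equal(Re(jb$j1), besselJ(z, 1), tolerance = 1e-10)
  expect_lt(max(abs(Im(jb$j0))), 1e-12)
})
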