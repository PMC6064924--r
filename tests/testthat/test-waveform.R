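test_that("fit recovers signals inside its own model class with zero residual", {
  T <- 0.1
  tt <- seq(0, T, length.out = 33L)[1:32]
  # periodic cubic on [0, T): p(0) = p(T) by construction
  u <- tt / T
  v <- 0.3 + u * (1 - u) * (0.8 - 0.5 * u)
  bw <- fit_bezier_waveform(sampled_waveform(tt, v, T), 1L)
  expect_lt(attr(bw, "rms_residual"), 1e-12)
  expect_equal(evaluate_waveform(bw, tt), v, tolerance = 1e-10)

  # constant waveform reproduced exactly everywhere
  bc <- fit_bezier_waveform(sampled_waveform(tt, rep(0.5, 32L), T), 3L)
  expect_lt(attr(bc, "rms_residual"), 1e-12)
  expect_equal(evaluate_waveform(bc, runif(20, 0, 10 * T)), rep(0.5, 20),
               tolerance = 1e-10)
})

test_that("noisy sinusoid fit tracks the true signal and a per-segment LS oracle", {
  set.seed(42)
  T <- 0.1
  tt <- seq(0, T, length.out = 65L)[1:64]
  truth <- sin(2 * pi * tt / T)
  v <- truth + rnorm(64L, sd = 0.01)
  bw <- fit_bezier_waveform(sampled_waveform(tt, v, T), 8L)
  td <- seq(0, T, length.out = 513L)[1:512]
  expect_lt(max(abs(evaluate_waveform(bw, td) - sin(2 * pi * td / T))), 0.05)

  # independent oracle: unconstrained dense cubic LS fit on each segment
  # (normal equations); the spline cannot beat it per segment but must be close
  for (k in 0:7) {
    seg <- tt >= k * T / 8 & tt < (k + 1) * T / 8
    x <- (tt[seg] - k * T / 8) / (T / 8)
    beta <- qr.solve(outer(x, 0:3, "^"), v[seg])
    xm <- seq(0.1, 0.9, by = 0.2)
    oracle <- outer(xm, 0:3, "^") %*% beta
    spl <- evaluate_waveform(bw, k * T / 8 + xm * T / 8)
    expect_lt(max(abs(spl - oracle)), 0.05)
  }
})

test_that("Bezier evaluation interpolates endpoints, is periodic, and matches Bernstein forms", {
  bw <- fit_bezier_waveform(default_mouse_waveform(), 8L)
  # segment endpoints equal the endpoint control velocities
  brk <- (0:7) * bw$period / 8
  expect_equal(evaluate_waveform(bw, brk), unname(bw$control[, "p0"]),
               tolerance = 1e-12)
  # T-periodicity
  t0 <- runif(50, 0, bw$period)
  expect_equal(evaluate_waveform(bw, t0), evaluate_waveform(bw, t0 + bw$period),
               tolerance = 1e-12)
  # hand-evaluated Bernstein midpoint for control velocities (0, 1, 1, 0)
  w <- bw
  w$control <- matrix(c(0, 1, 1, 0), 1L, dimnames = list(NULL, c("p0", "p1", "p2", "p3")))
  w$n_segments <- 1L
  expect_equal(evaluate_waveform(w, w$period / 2), 0.75, tolerance = 1e-14)
})

test_that("periodic closure holds to machine precision", {
  bw <- fit_bezier_waveform(default_mouse_waveform(), 10L)
  eps <- 1e-12 * bw$period
  gap <- abs(evaluate_waveform(bw, 0) - evaluate_waveform(bw, bw$period - eps))
  expect_lt(gap, 1e-9 * max(abs(bw$control)))
})

test_that("scaling is exact, linear at every t, and preserves times", {
  bw <- fit_bezier_waveform(default_mouse_waveform(), 8L)
  expect_equal(scale_waveform(bw, 1), bw)
  s <- scale_waveform(bw, 0.8)
  tt <- seq(0, bw$period, length.out = 257L)[1:256]
  expect_equal(evaluate_waveform(s, tt), 0.8 * evaluate_waveform(bw, tt),
               tolerance = 1e-13)
  expect_equal(max(evaluate_waveform(s, tt)), 0.8 * max(evaluate_waveform(bw, tt)))
  # mean scales by the factor (dense quadrature both sides)
  expect_equal(mean(evaluate_waveform(s, tt)), 0.8 * mean(evaluate_waveform(bw, tt)),
               tolerance = 1e-13)
})

test_that("fit residual is non-increasing over nested segment refinements", {
  sw <- default_mouse_waveform()
  res <- sapply(c(2L, 4L, 8L, 16L), function(n)
    attr(fit_bezier_waveform(sw, n), "rms_residual"))
  expect_true(all(diff(res) <= 1e-12))
})

test_that("invalid waveforms and fits are rejected", {
  expect_error(sampled_waveform(c(0, 0.02, 0.01, 0.03), rep(1, 4), 0.1),
               "strictly increasing")
  expect_error(sampled_waveform(c(0, 0.01, 0.02), rep(1, 3), 0.1), "at least 4")
  expect_error(sampled_waveform(c(0, 0.05, 0.1, 0.15), rep(1, 4), 0.1), "\\[0, period\\)")
  sw <- sampled_waveform(c(0, 0.02, 0.04, 0.06, 0.08), rep(1, 5), 0.1)
  expect_error(fit_bezier_waveform(sw, 4L), "under-determined")
  bw <- fit_bezier_waveform(default_mouse_waveform(), 4L)
  expect_error(scale_waveform(bw, 0), "invalid scaling")
  expect_error(scale_waveform(bw, -1), "invalid scaling")
})

test_that("waveform CSV and Bezier JSON round-trips preserve the data", {
  sw <- default_mouse_waveform()
  f <- tempfile(fileext = ".csv")
  write_waveform_csv(sw, f)
  back <- read_waveform_csv(f)
  expect_equal(back$velocities, sw$velocities, tolerance = 1e-12)
  expect_equal(back$period, sw$period)
  bw <- fit_bezier_waveform(sw, 6L)
  j <- tempfile(fileext = ".json")
  write_bezier_json(bw, j)
  obj <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(obj$period_s, 0.1)
  expect_length(obj$segments$control_points, 6L)
  unlink(c(f, j))
})
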