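uniform_times <- function(n, T = 0.1) (0:(n - 1L)) * T / n

test_that("mean vector, TAWSS and OSI give closed-form values on analytic signals", {
  T <- 0.1
  tt <- uniform_times(256L, T)
  # constant vector
  rc <- wss_record(tt, T, cbind(2, 0, 0)[rep(1, 256L), ], c(0, 0, 1))
  expect_equal(as.numeric(mean_wss_vector(rc)), c(2, 0, 0))
  expect_equal(tawss(rc), 2)
  expect_equal(osi(rc), 0)
  # zero-mean sinusoid: mean vanishes
  rs <- wss_record(tt, T, cbind(sin(2 * pi * tt / T), 0, 0), c(0, 0, 1))
  expect_lt(max(abs(mean_wss_vector(rs))), 1e-12)
  expect_equal(osi(rs), 0.5)
  # A = pi/2 sinusoid: TAWSS = A * 2/pi = 1 (mean of |sin|)
  ra <- wss_record(uniform_times(1024L, T), T,
                   cbind(pi / 2 * sin(2 * pi * uniform_times(1024L, T) / T), 0, 0),
                   c(0, 0, 1))
  expect_equal(tawss(ra), 1.0, tolerance = 1e-5)
  # offset sinusoid without reversal: OSI exactly 0
  ro <- wss_record(uniform_times(1024L, T), T,
                   cbind(1 + 0.5 * sin(2 * pi * uniform_times(1024L, T) / T), 0, 0),
                   c(0, 0, 1))
  expect_equal(osi(ro), 0, tolerance = 1e-14)
})

test_that("transWSS gives closed-form values, flags degenerate directions, rejects 2-D", {
  T <- 0.1
  tt <- uniform_times(1024L, T)
  # transverse sinusoid of amplitude pi/2 about an axial mean: transWSS = 1
  rt <- wss_record(tt, T, cbind(1, pi / 2 * sin(2 * pi * tt / T), 0), c(0, 0, 1))
  expect_equal(as.numeric(transwss(rt)), 1.0, tolerance = 1e-5)
  # all tau parallel to one direction: no transverse component
  rp <- wss_record(tt, T, cbind(1 + 0.3 * cos(2 * pi * tt / T), 0, 0), c(0, 0, 1))
  expect_equal(as.numeric(transwss(rp)), 0, tolerance = 1e-14)
  # rotating vector of constant magnitude: zero mean -> 0 with degeneracy flag
  rr <- wss_record(tt, T, cbind(cos(2 * pi * tt / T), sin(2 * pi * tt / T), 0),
                   c(0, 0, 1))
  tw <- transwss(rr)
  expect_equal(as.numeric(tw), 0)
  expect_true(attr(tw, "degenerate"))
  # 2-D records are metric-undefined
  r2 <- wss_record(tt, T, cbind(1 + 0.1 * sin(2 * pi * tt / T), 0), c(0, 1))
  expect_error(transwss(r2), "metric-undefined")
  expect_true(is.na(compute_metrics(r2)$transwss_pa))
})

test_that("metrics match the brute-force oracle and bounds on seeded random records", {
  set.seed(101)
  for (i in 1:300) {
    r <- random_wss_record(n_times = 48L)
    rec <- wss_record(r$times, r$period, r$tau, r$normal)
    o <- oracle_point_metrics(r$tau, r$normal)
    ta <- tawss(rec); os <- osi(rec); tw <- as.numeric(transwss(rec))
    expect_equal(ta, o$tawss, tolerance = 1e-9)
    expect_equal(os, o$osi, tolerance = 1e-9)
    expect_equal(tw, o$transwss, tolerance = 1e-9)
    # invariants
    expect_gte(os, 0); expect_lte(os, 0.5)
    expect_gte(tw, 0); expect_lte(tw, ta + 1e-12)
    expect_lte(sqrt(sum(mean_wss_vector(rec)^2)), ta + 1e-12)
  }
})

test_that("metrics agree with fine integration of the formulas for piecewise-linear signals", {
  set.seed(7)
  T <- 0.1
  for (i in 1:5) {
    n <- stats::rnorm(3); n <- n / sqrt(sum(n^2))
    ref <- if (abs(n[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
    e1 <- ref - n * sum(ref * n); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
            n[1] * e1[2] - n[2] * e1[1])
    # periodic piecewise-linear coefficients on 16 knots
    ka <- stats::rnorm(16L, sd = 2); kb <- stats::rnorm(16L)
    plin <- function(k, x) {  # periodic linear interpolation on [0, 1)
      xi <- x * 16; i0 <- floor(xi) %% 16; w <- xi - floor(xi)
      k[i0 + 1L] * (1 - w) + k[(i0 + 1L) %% 16 + 1L] * w
    }
    # package path: the PL signal sampled on the record grid
    ns <- 4096L
    x <- (0:(ns - 1L)) / ns
    tau <- outer(plin(ka, x), e1) + outer(plin(kb, x), e2)
    rec <- wss_record(x * T, T, tau, n)
    # oracle: much finer direct integration of the same PL functions
    xf <- (0:(2^16 - 1L)) / 2^16
    a <- plin(ka, xf); b <- plin(kb, xf)
    taw_f <- mean(sqrt(a^2 + b^2))
    mvec_f <- colMeans(outer(a, e1) + outer(b, e2))
    osi_f <- 0.5 * (1 - sqrt(sum(mvec_f^2)) / taw_f)
    mh <- mvec_f / sqrt(sum(mvec_f^2))
    dv <- c(n[2] * mh[3] - n[3] * mh[2], n[3] * mh[1] - n[1] * mh[3],
            n[1] * mh[2] - n[2] * mh[1])
    tw_f <- mean(abs(a * sum(e1 * dv) + b * sum(e2 * dv)))
    expect_equal(tawss(rec), taw_f, tolerance = 1e-5)
    expect_equal(osi(rec), osi_f, tolerance = 1e-5)
    expect_equal(as.numeric(transwss(rec)), tw_f, tolerance = 1e-5)
  }
})

test_that("quadrature refinement changes metrics by less than 1e-4 relative", {
  T <- 0.1
  f <- function(nt) {
    tt <- uniform_times(nt, T)
    wss_record(tt, T, cbind(1 + 0.8 * sin(2 * pi * tt / T),
                            0.5 * cos(2 * pi * tt / T) + 0.2 * sin(4 * pi * tt / T),
                            0), c(0, 0, 1))
  }
  lo <- f(256L); hi <- f(2048L)
  expect_lt(abs(tawss(lo) - tawss(hi)) / tawss(hi), 1e-4)
  expect_lt(abs(osi(lo) - osi(hi)) / max(osi(hi), 1e-6), 1e-4)
  expect_lt(abs(as.numeric(transwss(lo)) - as.numeric(transwss(hi))) /
              as.numeric(transwss(hi)), 1e-4)
})

test_that("metrics are equivariant under rigid rotations", {
  set.seed(11)
  r <- random_wss_record(64L)
  rec <- wss_record(r$times, r$period, r$tau, r$normal)
  rot <- rotate_record_set(rec, axis = rnorm(3), angle = 1.234)
  expect_equal(tawss(rot), tawss(rec), tolerance = 1e-9)
  expect_equal(osi(rot), osi(rec), tolerance = 1e-9)
  expect_equal(as.numeric(transwss(rot)), as.numeric(transwss(rec)),
               tolerance = 1e-9)
})

test_that("record invariants are enforced at construction", {
  T <- 0.1
  tt <- uniform_times(16L, T)
  tau3 <- cbind(rep(1, 16L), 0, 0)
  expect_error(wss_record(tt, T, tau3, c(0, 0, 2)), "unit length")
  expect_error(wss_record(tt[1:7], T, tau3[1:7, ], c(0, 0, 1)), "at least 8")
  expect_error(wss_record(tt^1.1, T, tau3, c(0, 0, 1)), "uniform")
  # non-tangential 3-D tau rejected
  expect_error(wss_record(tt, T, cbind(rep(1, 16L), 0, 0.5), c(0, 0, 1)), "tangential")
})

test_that("regional summaries give hand-computed mean and SEM and the weighted-mean identity", {
  df <- data.frame(region = c("a", "a", "a", "b", "b"),
                   tawss_pa = c(1, 2, 3, 10, 20),
                   osi = c(0.1, 0.1, 0.1, 0.2, 0.2),
                   transwss_pa = NA_real_)
  s <- summarize_regions(df)
  sa <- s[s$region == "a" & s$metric == "tawss_pa", ]
  expect_equal(sa$mean, 2)
  expect_equal(sa$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(sa$n, 3L)
  # all-identical values: SEM 0
  s0 <- summarize_regions(data.frame(region = "z", tawss_pa = rep(5, 4)))
  expect_equal(s0$mean, 5); expect_equal(s0$sem, 0)
  # n-weighted average of region means recovers the global mean
  st <- s[s$metric == "tawss_pa", ]
  expect_equal(sum(st$mean * st$n) / sum(st$n), mean(df$tawss_pa))
  # single-value region reports NA SEM
  s1 <- summarize_regions(data.frame(region = c("a", "b"), tawss_pa = c(1, 2)))
  expect_true(all(is.na(s1$sem)))
})

test_that("wall shear CSV round-trip preserves records and metrics", {
  set.seed(5)
  fs <- synthetic_field_spec(n_points = 12L, n_times = 16L, seed = 9L)
  rec <- generate_wss_field(fs)
  f <- tempfile(fileext = ".csv")
  write_wss_csv(rec, f)
  back <- read_wss_csv(f)
  expect_equal(back$period, rec$period)
  expect_equal(back$tau_x, rec$tau_x, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tawss(back), tawss(rec), tolerance = 1e-12)
  expect_equal(back$region, rec$region)
  unlink(f)
})
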