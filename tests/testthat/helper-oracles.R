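# Independent brute-force implementations used as oracles: plain loops over
# time samples applying the metric definitions directly, kept deliberately
# separate from the vectorized package code paths.

oracle_point_metrics <- function(tau, normal) {
  nt <- nrow(tau)
  d <- ncol(tau)
  mvec <- rep(0, d)
  taw <- 0
  for (k in seq_len(nt)) {
    mvec <- mvec + tau[k, ]
    taw <- taw + sqrt(sum(tau[k, ]^2))
  }
  mvec <- mvec / nt
  taw <- taw / nt
  mg <- sqrt(sum(mvec^2))
  osi_val <- if (taw < 1e-12) 0 else 0.5 * (1 - mg / taw)
  tw <- NA_real_
  if (d == 3L) {
    if (mg < 1e-12) tw <- 0 else {
      mh <- mvec / mg
      dvec <- c(normal[2] * mh[3] - normal[3] * mh[2],
                normal[3] * mh[1] - normal[1] * mh[3],
                normal[1] * mh[2] - normal[2] * mh[1])
      s <- 0
      for (k in seq_len(nt)) s <- s + abs(sum(tau[k, ] * dvec))
      tw <- s / nt
    }
  }
  list(tawss = taw, osi = osi_val, transwss = tw, mean = mvec)
}

# Random tangential 3-D wall shear record: band-limited Fourier series in
# the tangent plane of a random unit normal.
random_wss_record <- function(n_times = 64L, period = 0.1, n_harm = 4L) {
  n <- stats::rnorm(3); n <- n / sqrt(sum(n^2))
  ref <- if (abs(n[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
  e1 <- ref - n * sum(ref * n); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  th <- 2 * pi * (0:(n_times - 1L)) / n_times
  comp <- function() {
    x <- rep(stats::rnorm(1, sd = 2), n_times)
    for (k in seq_len(n_harm))
      x <- x + stats::rnorm(1) * cos(k * th) + stats::rnorm(1) * sin(k * th)
    x
  }
  a <- comp(); b <- comp()
  tau <- outer(a, e1) + outer(b, e2)
  list(times = th * period / (2 * pi), period = period, tau = tau, normal = n)
}

# Rigid rotation of a record set (tau vectors and normals) about a random axis.
rotate_record_set <- function(rec, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3L, 3L, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  tx <- rec$tau_x * R[1, 1] + rec$tau_y * R[1, 2] + rec$tau_z * R[1, 3]
  ty <- rec$tau_x * R[2, 1] + rec$tau_y * R[2, 2] + rec$tau_z * R[2, 3]
  tz <- rec$tau_x * R[3, 1] + rec$tau_y * R[3, 2] + rec$tau_z * R[3, 3]
  wss_record_set(rec$times, rec$period, tx, ty, tz,
                 normal = rec$normal %*% t(R),
                 point_id = rec$point_id, region = rec$region)
}

# Small fixed-amplitude fluid constants used across solver tests.
blood <- fluid_properties()
channel_h <- 0.00158

constant_waveform <- function(u = 0.1, period = 0.1) {
  tt <- seq(0, period, length.out = 17L)[1:16]
  fit_bezier_waveform(sampled_waveform(tt, rep(u, 16L), period), 1L)
}

two_harmonic_waveform <- function(u0 = 0.04, u1 = 0.03, period = 0.1) {
  tt <- seq(0, period, length.out = 65L)[1:64]
  fit_bezier_waveform(sampled_waveform(tt, u0 + u1 * cos(2 * pi * tt / period),
                                       period), 8L)
}

# Shared scratch space for results reused across acceptance tests.
.acc_cache <- new.env(parent = emptyenv())
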