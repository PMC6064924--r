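test_that("default waveform peaks exactly at the requested value and stays non-negative", {
  w <- default_mouse_waveform()
  expect_equal(max(w$velocities), 1.0)
  expect_true(all(w$velocities >= 0))
  expect_equal(w$period, 0.1)
  w2 <- default_mouse_waveform(period_T = 0.12, peak = 0.8)
  expect_equal(max(w2$velocities), 0.8)
  # time-mean approximately peak x systolic duty factor (raised cosine over
  # 3/8 of the cycle averages to half its height over the window)
  duty <- 3 / 8 / 2
  expect_equal(mean(w$velocities), 0.02 + (1 - 0.02) * duty, tolerance = 0.01)
})

test_that("generated fields satisfy record invariants and are seed-reproducible", {
  fs <- synthetic_field_spec(n_points = 36L, n_times = 32L, seed = 7L)
  a <- generate_wss_field(fs)
  b <- generate_wss_field(fs)
  expect_identical(a, b)
  c2 <- generate_wss_field(synthetic_field_spec(n_points = 36L, n_times = 32L, seed = 8L))
  expect_false(identical(a, c2))
  # construction already enforces tangency/unit normals; confirm directly
  expect_lt(max(abs(sqrt(rowSums(a$normal^2)) - 1)), 1e-9)
  dot <- a$tau_x * a$normal[, 1] + a$tau_y * a$normal[, 2] + a$tau_z * a$normal[, 3]
  mag <- sqrt(a$tau_x^2 + a$tau_y^2 + a$tau_z^2)
  expect_lt(max(abs(dot) / pmax(mag, 1e-12)), 1e-6)
  expect_equal(as.integer(table(a$region)), rep(9L, 4L))
})

test_that("degenerate spec (no oscillation, no noise) gives zero OSI and transWSS", {
  fs <- synthetic_field_spec(n_points = 12L, n_times = 16L, oscillatory_frac = 0,
                             transverse_frac = 0, noise_sd = 0, seed = 3L)
  rec <- generate_wss_field(fs)
  expect_lt(max(osi(rec)), 1e-12)
  expect_lt(max(as.numeric(transwss(rec))), 1e-12)
  # constant per-point tau
  expect_lt(max(apply(rec$tau_x, 1, stats::sd)), 1e-12)
})

test_that("strong-reversal spec matches the closed-form OSI of an offset sinusoid", {
  # tau_axial(t) = m (1 + 2 sin th): OSI = (1 - 1/mean|1 + 2 sin|)/2 with
  # mean|1 + 2 sin| = 1 + (2 sqrt(3) - 2 pi/3)/pi  (sign change at sin = -1/2)
  mabs <- 1 + (2 * sqrt(3) - 2 * pi / 3) / pi
  osi_cf <- 0.5 * (1 - 1 / mabs)
  fs <- synthetic_field_spec(n_points = 24L, n_times = 512L, oscillatory_frac = 2,
                             transverse_frac = 0, noise_sd = 0, point_sdlog = 0,
                             seed = 5L)
  rec <- generate_wss_field(fs)
  expect_lt(max(abs(osi(rec) - osi_cf)), 1e-3)
})

test_that("sample moments of generated magnitudes converge to the spec parameters", {
  fs <- synthetic_field_spec(n_points = 2400L, n_times = 8L, oscillatory_frac = 0,
                             transverse_frac = 0, noise_sd = 0, seed = 21L)
  rec <- generate_wss_field(fs)
  ta <- tawss(rec)
  for (q in names(fs$region_means)) {
    v <- ta[rec$region == q]
    mc_se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - fs$region_means[[q]]), 3 * mc_se + 1e-9)
  }
})

test_that("cohorts have deterministic per-subject seeds and group-scaled metrics", {
  cs <- cohort_spec(n_subjects = 4L, base_seed = 11L,
                    field = synthetic_field_spec(n_points = 24L, n_times = 32L))
  co <- generate_cohort(cs)
  expect_length(co, 8L)
  expect_identical(cohort_summaries(co), cohort_summaries(generate_cohort(cs)))
  s <- cohort_summaries(co)
  expect_setequal(unique(s$group), c("control", "dha"))
  # reduced-amplitude group has lower TAWSS, OSI and transWSS region means
  agg <- stats::aggregate(s[c("tawss_pa", "osi", "transwss_pa")],
                          by = list(group = s$group), FUN = mean)
  ctrl <- agg[agg$group == "control", -1]; trt <- agg[agg$group == "dha", -1]
  expect_true(all(trt < ctrl))
  # n = 1 per group: pipeline completes, comparison reports not-available
  c1 <- generate_cohort(cohort_spec(n_subjects = 1L, base_seed = 2L,
                                    field = synthetic_field_spec(n_points = 12L,
                                                                 n_times = 16L)))
  s1 <- cohort_summaries(c1)
  cmp <- compare_groups(s1$tawss_pa[s1$group == "control"][1],
                        s1$tawss_pa[s1$group == "dha"][1])
  expect_false(cmp$available)
  expect_true(is.na(cmp$p_value))
})

test_that("fixture writer emits a readable waveform, field and config", {
  d <- file.path(tempdir(), "fixtures-test")
  write_fixture_set(d, seed = 4L)
  expect_true(file.exists(file.path(d, "waveform.csv")))
  w <- read_waveform_csv(file.path(d, "waveform.csv"))
  expect_equal(max(w$velocities), 1.0)
  rec <- read_wss_csv(file.path(d, "wss_field.csv"))
  expect_s3_class(rec, "wss_record_set")
  cfg <- yaml::read_yaml(file.path(d, "config.yaml"))
  expect_equal(cfg$mode, "synthetic")
  unlink(d, recursive = TRUE)
})
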