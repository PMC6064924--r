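# Synthetic inputs: a canonical murine inlet waveform, per-point wall shear
# vector time series with controlled oscillatory/transverse structure, and
# two-group cohorts for the control vs treated comparison.

# Run code with a local, restorable RNG stream.
with_seed <- function(seed, code) {
  if (!is.finite(seed) || seed != round(seed) || abs(seed) >= 2^31)
    stop("`seed` must be a 32-bit integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Canonical murine-like inlet velocity waveform
#'
#' A smooth, strictly non-negative systolic-pulse waveform: a raised-cosine
#' systolic peak spanning the first 3/8 of the cycle over a low diastolic
#' plateau. Defaults give a 0.1 s cycle (about 600 bpm, a typical mouse
#' heart rate) with a 1 m/s systolic peak, the typical maximum aortic-root
#' flow speed. Sampled at `n_samples` uniform times; the sample count is a
#' multiple of 16 so a sample falls exactly on the systolic peak.
#'
#' @param period_T Cycle time in seconds.
#' @param peak Peak velocity in m/s (the maximum of the samples, exactly).
#' @param n_samples Number of uniform samples (multiple of 16, >= 32).
#' @param diastolic Diastolic plateau as a fraction of `peak`.
#' @return A [sampled_waveform()].
#' @examples
#' w <- default_mouse_waveform()
#' max(w$velocities)  # exactly 1
#' @export
default_mouse_waveform <- function(period_T = 0.1, peak = 1.0,
                                   n_samples = 128L, diastolic = 0.02) {
  check_positive(period_T, "period_T")
  check_positive(peak, "peak")
  n_samples <- as.integer(n_samples)
  if (n_samples < 32L || n_samples %% 16L != 0L)
    stop("`n_samples` must be a multiple of 16 and at least 32", call. = FALSE)
  k <- 0:(n_samples - 1L)
  n_sys <- 3L * n_samples / 8L  # systole over 3/8 of the cycle; peak at k = n_sys/2
  base <- diastolic * peak
  v <- rep(base, n_samples)
  ks <- k[k < n_sys]
  v[seq_along(ks)] <- base + (peak - base) * 0.5 * (1 - cos(2 * pi * ks / n_sys))
  sampled_waveform(k * period_T / n_samples, v, period_T)
}

#' Specification of a synthetic wall shear field
#'
#' Statistical description of a per-point 3-D WSS vector time series field:
#' each point gets an axial mean direction with magnitude drawn around its
#' region's mean (lognormal, `point_sdlog`), a zero-mean oscillatory axial
#' sinusoid of amplitude `oscillatory_frac` times the point mean, a
#' quarter-period phase-shifted transverse sinusoid of amplitude
#' `transverse_frac` times the point mean, and tangential Gaussian noise.
#' Points are distributed evenly over 12 ostia grouped into the four
#' quadrants (`left_upper`, `right_upper`, `left_lower`, `right_lower`).
#'
#' @param n_points Number of surface points (multiple of 12 recommended).
#' @param period_T Cycle time in seconds.
#' @param n_times Time samples per cycle (>= 8).
#' @param region_means Named mean shear magnitudes (Pa) for the four
#'   quadrants.
#' @param oscillatory_frac Oscillatory axial amplitude as a fraction of the
#'   point mean (>= 0; values > 1 produce flow reversal).
#' @param transverse_frac Transverse amplitude fraction (>= 0).
#' @param noise_sd Tangential Gaussian noise standard deviation in Pa.
#' @param point_sdlog Lognormal sdlog of point magnitudes about the
#'   regional mean (mean-corrected so the expectation equals the regional
#'   mean).
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `synthetic_field_spec`.
#' @export
synthetic_field_spec <- function(n_points = 60L, period_T = 0.1, n_times = 64L,
                                 region_means = c(left_upper = 25, right_upper = 24,
                                                  left_lower = 23.5, right_lower = 22.5),
                                 oscillatory_frac = 0.3, transverse_frac = 0.12,
                                 noise_sd = 0.02, point_sdlog = 0.10, seed = 1L) {
  check_positive(period_T, "period_T")
  if (as.integer(n_times) < 8L) stop("`n_times` must be >= 8", call. = FALSE)
  if (n_points < 12L) stop("`n_points` must be at least 12", call. = FALSE)
  if (oscillatory_frac < 0 || transverse_frac < 0 || noise_sd < 0 || point_sdlog < 0)
    stop("fractions and noise must be non-negative", call. = FALSE)
  quad <- c("left_upper", "right_upper", "left_lower", "right_lower")
  if (!all(quad %in% names(region_means)))
    stop("`region_means` must name all four quadrants", call. = FALSE)
  if (any(region_means <= 0)) stop("region means must be positive", call. = FALSE)
  structure(list(n_points = as.integer(n_points), period_T = period_T,
                 n_times = as.integer(n_times), region_means = region_means,
                 oscillatory_frac = oscillatory_frac,
                 transverse_frac = transverse_frac,
                 noise_sd = noise_sd, point_sdlog = point_sdlog,
                 seed = as.integer(seed)),
            class = "synthetic_field_spec")
}

# Quadrant of ostium o (1..12): 6 axial pairs, odd = left wall, even =
# right; pairs 1-3 proximal (upper), 4-6 distal (lower).
ostium_quadrant <- function(o) {
  paste(ifelse(o %% 2L == 1L, "left", "right"),
        ifelse(ceiling(o / 2) <= 3L, "upper", "lower"), sep = "_")
}

#' Generate a synthetic wall shear vector field
#'
#' Draws the per-point WSS time series described by a
#' [synthetic_field_spec()]: random unit normals, orthonormal tangent bases,
#' lognormal point magnitudes, fundamental-frequency oscillatory and
#' transverse sinusoids, and tangential noise. Tangency to each point's
#' normal holds exactly by construction, and the output is fully
#' reproducible from the spec seed.
#'
#' @param spec A [synthetic_field_spec()].
#' @return A 3-D [wss_record_set()] with quadrant region labels and ostium
#'   ids in `point_id`.
#' @export
generate_wss_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  with_seed(spec$seed, {
    np <- spec$n_points; nt <- spec$n_times
    ost <- rep(1:12, length.out = np)
    quad <- ostium_quadrant(ost)
    m_reg <- spec$region_means[quad]
    m <- unname(m_reg) * exp(spec$point_sdlog * stats::rnorm(np) - spec$point_sdlog^2 / 2)

    n <- matrix(stats::rnorm(3L * np), np, 3L)
    n <- n / sqrt(rowSums(n^2))
    # axial tangent e1: a reference vector projected off the normal
    ref <- matrix(rep(c(1, 0, 0), each = np), np, 3L)
    flip <- abs(n[, 1L]) > 0.9
    ref[flip, ] <- matrix(rep(c(0, 1, 0), each = sum(flip)), sum(flip), 3L)
    e1 <- ref - n * rowSums(ref * n)
    e1 <- e1 / sqrt(rowSums(e1^2))
    e2 <- cbind(n[, 2L] * e1[, 3L] - n[, 3L] * e1[, 2L],
                n[, 3L] * e1[, 1L] - n[, 1L] * e1[, 3L],
                n[, 1L] * e1[, 2L] - n[, 2L] * e1[, 1L])

    th <- 2 * pi * (0:(nt - 1L)) / nt
    ax <- outer(m, rep(1, nt)) * (1 + spec$oscillatory_frac * outer(rep(1, np), sin(th)))
    tr <- outer(m * spec$transverse_frac, cos(th))
    if (spec$noise_sd > 0) {
      ax <- ax + matrix(stats::rnorm(np * nt, sd = spec$noise_sd), np, nt)
      tr <- tr + matrix(stats::rnorm(np * nt, sd = spec$noise_sd), np, nt)
    }
    times <- (0:(nt - 1L)) * spec$period_T / nt
    wss_record_set(times, spec$period_T,
                   tau_x = ax * e1[, 1L] + tr * e2[, 1L],
                   tau_y = ax * e1[, 2L] + tr * e2[, 2L],
                   tau_z = ax * e1[, 3L] + tr * e2[, 3L],
                   normal = n,
                   point_id = sprintf("ostium_%02d_p%03d", ost, seq_len(np)),
                   region = quad)
  })
}

#' Specification of a two-group synthetic cohort
#'
#' Defines exactly two groups of simulated subjects. Each subject is one
#' [generate_wss_field()] draw whose parameters are the base field spec
#' adjusted by the group's multipliers (`mean_scale` on regional mean shear,
#' `oscillatory_scale` and `transverse_scale` on the amplitude fractions)
#' and by a per-subject lognormal magnitude factor (`subject_sdlog`,
#' between-subject variability). Per-subject seeds are derived
#' deterministically from `base_seed` by counter offsets
#' (`(base_seed * 100003 + 1000 * group_index + subject_index) mod 2^31 - 1`,
#' so different base seeds give disjoint subject streams).
#'
#' The default treated-group adjustment scales mean shear by 0.8 — matching
#' the treated/control TAWSS ratio of about 0.78 — and the oscillatory and
#' transverse fractions by 0.9, so all three metrics are reduced.
#'
#' @param groups Named list of exactly two groups, each a list of
#'   multipliers (`mean_scale`, `oscillatory_scale`, `transverse_scale`;
#'   missing entries default to 1).
#' @param n_subjects Subjects per group (single value or per-group vector).
#' @param base_seed Integer base seed.
#' @param field A [synthetic_field_spec()] shared by all subjects.
#' @param subject_sdlog Between-subject lognormal sdlog (default 0.05).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = list(control = list(),
                                      dha = list(mean_scale = 0.8,
                                                 oscillatory_scale = 0.9,
                                                 transverse_scale = 0.9)),
                        n_subjects = 12L, base_seed = 1L,
                        field = synthetic_field_spec(),
                        subject_sdlog = 0.05) {
  if (length(groups) != 2L || is.null(names(groups)))
    stop("the cohort design has exactly 2 named groups", call. = FALSE)
  n_subjects <- rep_len(as.integer(n_subjects), 2L)
  if (any(n_subjects < 1L)) stop("`n_subjects` must be >= 1", call. = FALSE)
  stopifnot(inherits(field, "synthetic_field_spec"))
  structure(list(groups = groups, n_subjects = n_subjects,
                 base_seed = as.integer(base_seed), field = field,
                 subject_sdlog = subject_sdlog),
            class = "cohort_spec")
}

#' Generate a two-group cohort of synthetic subjects
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `wss_cohort`: one element per subject with
#'   `group`, `subject` (id), and `records` (a 3-D [wss_record_set()]).
#' @seealso [cohort_summaries()] for subject-level regional means.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- list()
  for (gi in seq_along(spec$groups)) {
    gname <- names(spec$groups)[gi]
    adj <- spec$groups[[gi]]
    ms <- if (is.null(adj$mean_scale)) 1 else adj$mean_scale
    os <- if (is.null(adj$oscillatory_scale)) 1 else adj$oscillatory_scale
    ts <- if (is.null(adj$transverse_scale)) 1 else adj$transverse_scale
    for (s in seq_len(spec$n_subjects[gi])) {
      sseed <- (as.numeric(spec$base_seed) * 100003 + 1000 * gi + s) %% 2147483647
      smult <- with_seed((as.numeric(sseed) * 7919) %% 2147483647,
                         exp(spec$subject_sdlog * stats::rnorm(1L) -
                               spec$subject_sdlog^2 / 2))
      fs <- spec$field
      fs$region_means <- fs$region_means * ms * smult
      fs$oscillatory_frac <- fs$oscillatory_frac * os
      fs$transverse_frac <- fs$transverse_frac * ts
      fs$seed <- sseed
      out[[length(out) + 1L]] <- list(group = gname,
                                      subject = sprintf("%s_%02d", gname, s),
                                      records = generate_wss_field(fs))
    }
  }
  structure(out, class = "wss_cohort")
}

#' Subject-level regional metric summaries for a cohort
#'
#' Computes per-point TAWSS/OSI/transWSS for every subject and averages them
#' within each region, giving one value per subject x region x metric — the
#' unit of analysis for the group comparison (avoiding pseudo-replication
#' over wall points).
#'
#' @param cohort A `wss_cohort` from [generate_cohort()].
#' @return Data frame with columns `subject`, `group`, `region`,
#'   `tawss_pa`, `osi`, `transwss_pa`.
#' @export
cohort_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "wss_cohort"))
  do.call(rbind, lapply(cohort, function(subj) {
    met <- compute_metrics(subj$records)
    agg <- stats::aggregate(met[c("tawss_pa", "osi", "transwss_pa")],
                            by = list(region = met$region), FUN = mean)
    data.frame(subject = subj$subject, group = subj$group, agg,
               stringsAsFactors = FALSE)
  }))
}

#' Write a small plain-text fixture set
#'
#' Writes the inputs a pipeline run needs into a directory: the default
#' waveform as CSV, a small synthetic wall shear field as long-format CSV,
#' and a ready-to-run synthetic-mode config as YAML.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed for the synthetic field.
#' @return The directory path, invisibly.
#' @export
write_fixture_set <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_waveform_csv(default_mouse_waveform(), file.path(dir, "waveform.csv"))
  fs <- synthetic_field_spec(n_points = 24L, n_times = 32L, seed = seed)
  write_wss_csv(generate_wss_field(fs), file.path(dir, "wss_field.csv"))
  cfg <- list(mode = "synthetic", seed = as.integer(seed),
              cohort = list(n_subjects = 3L, n_points = 24L, n_times = 32L),
              output = list(dir = "out"))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
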