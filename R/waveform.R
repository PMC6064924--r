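#' Sampled periodic inlet velocity waveform
#'
#' Container for a velocity-vs-time signal sampled over one cardiac cycle.
#' The waveform is treated as periodic with period `period`: a sample at
#' time `t` also describes the signal at `t + k * period` for any integer
#' `k`. This is the raw form of the Dirichlet inlet boundary condition;
#' [fit_bezier_waveform()] turns it into a smooth periodic spline.
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing, all within `[0, period)`.
#' @param velocities Numeric vector of velocities in m/s, same length as
#'   `times`, all finite.
#' @param period Cycle time T in seconds (single positive number).
#'
#' @return An object of class `sampled_waveform`: a list with elements
#'   `times`, `velocities` and `period`.
#' @examples
#' w <- sampled_waveform(seq(0, 0.09, by = 0.01), sin(2 * pi * (0:9) / 10), 0.1)
#' @seealso [fit_bezier_waveform()], [default_mouse_waveform()]
#' @export
sampled_waveform <- function(times, velocities, period) {
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) || period <= 0)
    stop("`period` must be a single positive number (seconds)", call. = FALSE)
  if (length(times) != length(velocities))
    stop("`times` and `velocities` must have the same length", call. = FALSE)
  if (length(times) < 4L)
    stop("a sampled waveform needs at least 4 samples", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(velocities)))
    stop("waveform samples must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("invalid waveform: `times` must be strictly increasing", call. = FALSE)
  if (times[1L] < 0 || times[length(times)] >= period)
    stop("all sample times must lie in [0, period)", call. = FALSE)
  structure(list(times = as.numeric(times),
                 velocities = as.numeric(velocities),
                 period = as.numeric(period)),
            class = "sampled_waveform")
}

#' @export
print.sampled_waveform <- function(x, ...) {
  cat(sprintf("<sampled_waveform> %d samples over T = %g s, velocity range [%.4g, %.4g] m/s\n",
              length(x$times), x$period, min(x$velocities), max(x$velocities)))
  invisible(x)
}

# Cubic Bernstein basis at parameter u in [0, 1]; returns length-4 rows.
bernstein3 <- function(u) {
  cbind((1 - u)^3, 3 * u * (1 - u)^2, 3 * u^2 * (1 - u), u^3)
}

#' Fit a periodic cubic Bezier spline to a sampled waveform
#'
#' Least-squares fit of an ordered chain of `n_segments` cubic (third-order)
#' Bezier segments to the samples, with uniform breakpoints in time, C0
#' continuity at the joins, and periodic closure (the last segment ends where
#' the first begins, so that v(0) = v(T)). Only value continuity is enforced
#' at the joins; slopes are free, which is the weakest reading of a
#' "third-order Bezier spline" and leaves the least-squares problem linear.
#'
#' The unknowns are the shared join values plus two interior control
#' velocities per segment (3 * `n_segments` in total); the fit is solved by
#' dense QR. The root-mean-square residual of the fit is attached to the
#' result as attribute `"rms_residual"`.
#'
#' @param samples A [sampled_waveform()].
#' @param n_segments Number of cubic segments (>= 1). The breakpoints are
#'   uniform: segment k spans `[(k-1) T / n, k T / n)`.
#'
#' @return An object of class `bezier_waveform`: list with `control`
#'   (a `n_segments x 4` matrix of control velocities), `period`, and
#'   `n_segments`; control-point times are implicit (uniform thirds of each
#'   segment). Attribute `rms_residual` holds the fit residual in m/s.
#' @examples
#' sw <- default_mouse_waveform()
#' bw <- fit_bezier_waveform(sw, n_segments = 8)
#' attr(bw, "rms_residual")
#' @export
fit_bezier_waveform <- function(samples, n_segments) {
  stopifnot(inherits(samples, "sampled_waveform"))
  n_segments <- as.integer(n_segments)
  if (length(n_segments) != 1L || is.na(n_segments) || n_segments < 1L)
    stop("`n_segments` must be a positive integer", call. = FALSE)
  m <- length(samples$times)
  n_par <- 3L * n_segments
  if (m < n_par)
    stop(sprintf(paste("under-determined fit: %d samples cannot constrain %d",
                       "segments (%d parameters); reduce `n_segments`"),
                 m, n_segments, n_par), call. = FALSE)

  T <- samples$period
  dseg <- T / n_segments
  seg <- pmin(floor(samples$times / dseg), n_segments - 1)  # 0-based segment
  u <- samples$times / dseg - seg
  B <- bernstein3(u)

  # Parameter layout: join values e_1..e_n, then (c1, c2) per segment.
  A <- matrix(0, nrow = m, ncol = n_par)
  idx <- seq_len(m)
  e0 <- seg + 1L                       # join at segment start
  e1 <- (seg + 1L) %% n_segments + 1L  # join at segment end (wraps: closure)
  A[cbind(idx, e0)] <- A[cbind(idx, e0)] + B[, 1L]
  A[cbind(idx, e1)] <- A[cbind(idx, e1)] + B[, 4L]
  A[cbind(idx, n_segments + 2L * seg + 1L)] <- B[, 2L]
  A[cbind(idx, n_segments + 2L * seg + 2L)] <- B[, 3L]

  fit <- qr(A)
  if (fit$rank < n_par)
    stop("under-determined fit: sample placement leaves the spline rank-deficient",
         call. = FALSE)
  theta <- qr.coef(fit, samples$velocities)
  resid <- samples$velocities - as.numeric(A %*% theta)

  e <- theta[seq_len(n_segments)]
  cc <- matrix(theta[-seq_len(n_segments)], ncol = 2L, byrow = TRUE)
  control <- cbind(e, cc[, 1L], cc[, 2L], e[c(seq_len(n_segments)[-1L], 1L)])
  colnames(control) <- c("p0", "p1", "p2", "p3")

  structure(list(control = control, period = T, n_segments = n_segments),
            class = "bezier_waveform",
            rms_residual = sqrt(mean(resid^2)))
}

#' @export
print.bezier_waveform <- function(x, ...) {
  r <- attr(x, "rms_residual")
  cat(sprintf("<bezier_waveform> %d cubic segments, T = %g s%s\n",
              x$n_segments, x$period,
              if (is.null(r)) "" else sprintf(", fit RMS residual %.3g m/s", r)))
  invisible(x)
}

#' Evaluate a periodic Bezier waveform
#'
#' Evaluates the spline at arbitrary times; times are wrapped modulo the
#' period, so the result is exactly T-periodic. Uses the closed-form cubic
#' Bernstein expression per segment.
#'
#' @param w A `bezier_waveform` from [fit_bezier_waveform()].
#' @param t Numeric vector of times in seconds (any real values).
#' @return Numeric vector of velocities (m/s), same length as `t`.
#' @examples
#' bw <- fit_bezier_waveform(default_mouse_waveform(), 8)
#' evaluate_waveform(bw, c(0, 0.025, 0.1))
#' @export
evaluate_waveform <- function(w, t) {
  stopifnot(inherits(w, "bezier_waveform"))
  tm <- t %% w$period
  dseg <- w$period / w$n_segments
  seg <- pmin(floor(tm / dseg), w$n_segments - 1)
  u <- tm / dseg - seg
  B <- bernstein3(u)
  P <- w$control[seg + 1L, , drop = FALSE]
  rowSums(B * P)
}

#' Scale a Bezier waveform by a positive factor
#'
#' Multiplies every control-point velocity by `factor`; the time axis is
#' unchanged. Used to build inlet conditions that differ only in amplitude
#' (e.g. a reduced-peak-velocity group versus a control group).
#'
#' @param w A `bezier_waveform`.
#' @param factor Positive scale factor (dimensionless).
#' @return A `bezier_waveform` with scaled control velocities.
#' @export
scale_waveform <- function(w, factor) {
  stopifnot(inherits(w, "bezier_waveform"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0)
    stop("invalid scaling: `factor` must be a single positive number", call. = FALSE)
  w$control <- w$control * factor
  w
}

#' Read waveform samples from a two-column CSV
#'
#' Expects a header row and columns `time_s`, `velocity_m_s`. The period is
#' either passed explicitly or read from an optional final metadata row with
#' `time_s == "period_s"`.
#'
#' @param path CSV file path.
#' @param period Cycle time in seconds; if `NULL`, taken from the metadata row.
#' @return A [sampled_waveform()].
#' @export
read_waveform_csv <- function(path, period = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "velocity_m_s") %in% names(df)))
    stop("waveform CSV must have columns `time_s` and `velocity_m_s`", call. = FALSE)
  meta <- df$time_s == "period_s"
  if (any(meta)) {
    if (is.null(period)) period <- as.numeric(df$velocity_m_s[meta][1L])
    df <- df[!meta, , drop = FALSE]
  }
  if (is.null(period))
    stop("no period given and no `period_s` metadata row present", call. = FALSE)
  sampled_waveform(as.numeric(df$time_s), as.numeric(df$velocity_m_s), period)
}

#' Write waveform samples to CSV
#'
#' Inverse of [read_waveform_csv()]; appends a `period_s` metadata row.
#'
#' @param w A [sampled_waveform()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "sampled_waveform"))
  df <- data.frame(time_s = c(format(w$times, digits = 15), "period_s"),
                   velocity_m_s = c(w$velocities, w$period))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted Bezier waveform to JSON
#'
#' Writes the spline as a list of segments (four `(time, velocity)` control
#' points each) plus the period, so it can be consumed outside R.
#'
#' @param w A `bezier_waveform`.
#' @param path Output JSON path; if `NULL`, the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
write_bezier_json <- function(w, path = NULL) {
  stopifnot(inherits(w, "bezier_waveform"))
  dseg <- w$period / w$n_segments
  segs <- lapply(seq_len(w$n_segments), function(k) {
    t0 <- (k - 1) * dseg
    list(control_points = lapply(0:3, function(j)
      list(time_s = t0 + j * dseg / 3, velocity_m_s = unname(w$control[k, j + 1L]))))
  })
  obj <- list(period_s = w$period, segments = segs)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
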