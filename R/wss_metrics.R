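#' Wall shear stress vector time series at surface points
#'
#' Container for per-point wall shear stress (WSS) vector time series over
#' one cardiac cycle, together with each point's outward unit normal and an
#' ostium-region label. All points share one uniform, endpoint-exclusive
#' time grid spanning `[0, period)`; with `n` samples the grid spacing is
#' exactly `period / n`, so periodic trapezoidal quadrature reduces to the
#' arithmetic mean over samples.
#'
#' Records may be 2-D (`tau_z = NULL`, e.g. from the plane-channel solver)
#' or 3-D. For 3-D records tangency to the wall is enforced:
#' `|tau . n| < 1e-6 |tau|` at every time.
#'
#' @param times Sample times in seconds: uniform grid `0, dt, ..., (n-1) dt`
#'   with `n >= 8` and `n * dt = period`.
#' @param period Cycle time T in seconds.
#' @param tau_x,tau_y,tau_z Matrices of WSS components in Pa, one row per
#'   point, one column per time sample. `tau_z` may be `NULL` for 2-D data.
#' @param normal Matrix of outward unit normals (one row per point, 2 or 3
#'   columns matching the tau dimensionality).
#' @param position Optional matrix of point coordinates in m.
#' @param point_id Optional point identifiers (default `1..n_points`).
#' @param region Optional region labels (default `"non-ostial"`).
#'
#' @return An object of class `wss_record_set`.
#' @seealso [tawss()], [osi()], [transwss()], [compute_metrics()]
#' @export
wss_record_set <- function(times, period, tau_x, tau_y, tau_z = NULL,
                           normal, position = NULL, point_id = NULL,
                           region = NULL) {
  times <- as.numeric(times)
  n_t <- length(times)
  if (n_t < 8L) stop("invalid record: need at least 8 time samples", call. = FALSE)
  check_positive(period, "period")
  dt <- period / n_t
  expected <- (seq_len(n_t) - 1) * dt
  if (max(abs(times - expected)) > 1e-9 * period)
    stop("invalid record: times must be the uniform endpoint-exclusive grid ",
         "0, T/n, ..., (n-1) T/n", call. = FALSE)
  tau_x <- rbind(tau_x); tau_y <- rbind(tau_y)
  n_p <- nrow(tau_x)
  if (!all(dim(tau_y) == dim(tau_x)))
    stop("tau component matrices must share dimensions", call. = FALSE)
  if (ncol(tau_x) != n_t)
    stop("tau matrices must have one column per time sample", call. = FALSE)
  dim3 <- !is.null(tau_z)
  if (dim3) {
    tau_z <- rbind(tau_z)
    if (!all(dim(tau_z) == dim(tau_x)))
      stop("tau component matrices must share dimensions", call. = FALSE)
  }
  normal <- rbind(normal)
  if (nrow(normal) == 1L && n_p > 1L)
    normal <- normal[rep(1L, n_p), , drop = FALSE]
  if (nrow(normal) != n_p || ncol(normal) != (2L + dim3))
    stop("`normal` must be one unit vector per point, matching tau dimensionality",
         call. = FALSE)
  nlen <- sqrt(rowSums(normal^2))
  if (any(abs(nlen - 1) > 1e-9))
    stop("invalid record: normals must have unit length (|n| - 1| < 1e-9)",
         call. = FALSE)
  if (any(!is.finite(tau_x)) || any(!is.finite(tau_y)) ||
      (dim3 && any(!is.finite(tau_z))))
    stop("invalid record: tau values must be finite", call. = FALSE)
  if (dim3) {
    dot <- abs(tau_x * normal[, 1L] + tau_y * normal[, 2L] + tau_z * normal[, 3L])
    mag <- sqrt(tau_x^2 + tau_y^2 + tau_z^2)
    if (any(dot > 1e-6 * pmax(mag, .Machine$double.xmin)))
      stop("invalid record: tau vectors must be tangential (|tau.n| < 1e-6 |tau|)",
           call. = FALSE)
  }
  if (is.null(point_id)) point_id <- seq_len(n_p)
  if (is.null(region)) region <- rep("non-ostial", n_p)
  region <- rep_len(as.character(region), n_p)
  if (!is.null(position)) {
    position <- rbind(position)
    stopifnot(nrow(position) == n_p)
  }
  structure(list(times = times, period = as.numeric(period),
                 tau_x = tau_x, tau_y = tau_y, tau_z = tau_z,
                 normal = normal, position = position,
                 point_id = point_id, region = region),
            class = "wss_record_set")
}

#' Single-point wall shear record
#'
#' Convenience wrapper building a one-point [wss_record_set()] from vectors.
#'
#' @param times,period As in [wss_record_set()].
#' @param tau Matrix with one row per time sample and 2 or 3 columns
#'   (tau components in Pa).
#' @param normal Outward unit normal (length 2 or 3).
#' @param region Region label.
#' @return A `wss_record_set` with one point.
#' @export
wss_record <- function(times, period, tau, normal, region = "non-ostial") {
  tau <- as.matrix(tau)
  stopifnot(ncol(tau) %in% c(2L, 3L))
  wss_record_set(times, period,
                 tau_x = matrix(tau[, 1L], nrow = 1L),
                 tau_y = matrix(tau[, 2L], nrow = 1L),
                 tau_z = if (ncol(tau) == 3L) matrix(tau[, 3L], nrow = 1L),
                 normal = matrix(normal, nrow = 1L), region = region)
}

#' @export
print.wss_record_set <- function(x, ...) {
  cat(sprintf("<wss_record_set> %d point(s) x %d times, %s, T = %g s\n",
              nrow(x$tau_x), length(x$times),
              if (is.null(x$tau_z)) "2-D" else "3-D", x$period))
  invisible(x)
}

n_points <- function(rec) nrow(rec$tau_x)
is_3d <- function(rec) !is.null(rec$tau_z)

tau_magnitude <- function(rec) {
  if (is_3d(rec)) sqrt(rec$tau_x^2 + rec$tau_y^2 + rec$tau_z^2)
  else sqrt(rec$tau_x^2 + rec$tau_y^2)
}

#' Cycle-mean wall shear stress vector
#'
#' Component-wise time average of the WSS vector over the period, by
#' periodic trapezoidal quadrature (the arithmetic mean on the uniform
#' periodic grid): `tau_mean = (1/T) integral_0^T tau dt`.
#'
#' @param rec A [wss_record_set()].
#' @return Matrix with one row per point and one column per tau component (Pa).
#' @export
mean_wss_vector <- function(rec) {
  stopifnot(inherits(rec, "wss_record_set"))
  m <- cbind(x = rowMeans(rec$tau_x), y = rowMeans(rec$tau_y))
  if (is_3d(rec)) m <- cbind(m, z = rowMeans(rec$tau_z))
  m
}

#' Time-averaged wall shear stress magnitude (TAWSS)
#'
#' `TAWSS = (1/T) integral_0^T |tau(t)| dt`, the cycle average of the WSS
#' vector magnitude, by periodic trapezoidal quadrature. Note the average
#' of the magnitude, not the magnitude of the average: the two differ
#' whenever the WSS direction varies, and their ratio is what OSI measures.
#'
#' @param rec A [wss_record_set()].
#' @return Numeric vector, one non-negative value in Pa per point.
#' @export
tawss <- function(rec) {
  stopifnot(inherits(rec, "wss_record_set"))
  rowMeans(tau_magnitude(rec))
}

#' Oscillatory shear index (OSI)
#'
#' `OSI = 0.5 (1 - |tau_mean| / TAWSS)`, in `[0, 0.5]`: 0 for perfectly
#' unidirectional shear, 0.5 for pure oscillation with zero cycle mean.
#' Points with `TAWSS < 1e-12` Pa (quiescent wall) return 0. The result is
#' clamped to `[0, 0.5]` against floating-point rounding.
#'
#' @param rec A [wss_record_set()].
#' @return Numeric vector of dimensionless OSI values, one per point.
#' @export
osi <- function(rec) {
  stopifnot(inherits(rec, "wss_record_set"))
  ta <- tawss(rec)
  mg <- sqrt(rowSums(mean_wss_vector(rec)^2))
  out <- ifelse(ta < 1e-12, 0, 0.5 * (1 - mg / ta))
  pmin(pmax(out, 0), 0.5)
}

#' Transverse wall shear stress (transWSS)
#'
#' Cycle average of the absolute WSS component perpendicular to the mean WSS
#' direction within the wall tangent plane:
#' `transWSS = (1/T) integral |tau(t) . (n x tau_mean / |tau_mean|)| dt`.
#' It captures multidirectional near-wall flow that OSI (a pure
#' reversal measure) misses, and satisfies `0 <= transWSS <= TAWSS`.
#'
#' Defined only for 3-D records: the transverse direction is the cross
#' product of the outward normal with the unit mean-WSS vector, which for
#' in-plane 2-D data has no tangential component; 2-D records signal an
#' error. Points whose mean WSS vector is (numerically) zero have no
#' defined transverse direction; they return 0 and are flagged in the
#' `"degenerate"` attribute.
#'
#' @param rec A 3-D [wss_record_set()].
#' @return Numeric vector of transWSS values in Pa, one per point, with a
#'   logical attribute `"degenerate"` marking zero-mean-vector points.
#' @export
transwss <- function(rec) {
  stopifnot(inherits(rec, "wss_record_set"))
  if (!is_3d(rec))
    stop("metric-undefined: transWSS requires 3-D wall shear records ",
         "(the in-plane cross product of a 2-D record has no tangential ",
         "transverse direction)", call. = FALSE)
  m <- mean_wss_vector(rec)
  mg <- sqrt(rowSums(m^2))
  degenerate <- mg < 1e-12
  mhat <- m / ifelse(mg > 0, mg, 1)
  n <- rec$normal
  # d = n x mhat (unit transverse direction in the tangent plane)
  dx <- n[, 2L] * mhat[, 3L] - n[, 3L] * mhat[, 2L]
  dy <- n[, 3L] * mhat[, 1L] - n[, 1L] * mhat[, 3L]
  dz <- n[, 1L] * mhat[, 2L] - n[, 2L] * mhat[, 1L]
  out <- rowMeans(abs(rec$tau_x * dx + rec$tau_y * dy + rec$tau_z * dz))
  out[degenerate] <- 0
  structure(out, degenerate = degenerate)
}

#' Per-point hemodynamic metric table
#'
#' Computes TAWSS, OSI and transWSS for every point of a record set. For
#' 2-D records (plane-channel solver output) transWSS is undefined and
#' reported as `NA`.
#'
#' @param rec A [wss_record_set()].
#' @return A data frame with columns `point_id`, `region`, `tawss_pa`,
#'   `osi`, `transwss_pa`, `degenerate_flag`.
#' @export
compute_metrics <- function(rec) {
  stopifnot(inherits(rec, "wss_record_set"))
  if (is_3d(rec)) {
    tw <- transwss(rec)
    deg <- attr(tw, "degenerate")
  } else {
    tw <- rep(NA_real_, n_points(rec))
    deg <- rep(NA, n_points(rec))
  }
  data.frame(point_id = rec$point_id, region = rec$region,
             tawss_pa = tawss(rec), osi = osi(rec),
             transwss_pa = as.numeric(tw), degenerate_flag = deg,
             stringsAsFactors = FALSE)
}

#' Regional mean and standard error of hemodynamic metrics
#'
#' Summarizes a per-point (or per-subject) metric table by region:
#' arithmetic mean, standard error of the mean (`sd / sqrt(n)`), and n for
#' each metric. Regions with a single value report `NA` for the SEM;
#' non-ostial points form their own region. Values that are `NA` (e.g.
#' transWSS of 2-D records) are dropped per metric.
#'
#' @param metrics A data frame from [compute_metrics()] (needs a `region`
#'   column plus the metric columns).
#' @param metric_cols Metric columns to summarize.
#' @return A data frame with columns `region`, `metric`, `mean`, `sem`, `n`.
#' @export
summarize_regions <- function(metrics,
                              metric_cols = c("tawss_pa", "osi", "transwss_pa")) {
  stopifnot(is.data.frame(metrics), "region" %in% names(metrics))
  metric_cols <- intersect(metric_cols, names(metrics))
  out <- list()
  for (mc in metric_cols) {
    v <- metrics[[mc]]
    keep <- !is.na(v)
    if (!any(keep)) next
    sp <- split(v[keep], metrics$region[keep])
    sp <- sp[lengths(sp) > 0L]
    out[[mc]] <- data.frame(
      region = names(sp), metric = mc,
      mean = vapply(sp, mean, 0),
      sem = vapply(sp, function(x) if (length(x) < 2L) NA_real_
                   else stats::sd(x) / sqrt(length(x)), 0),
      n = vapply(sp, length, 0L),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Read and write wall shear record sets as long-format CSV
#'
#' One row per (point, time): `point_id`, `region`, position (`x`, `y`[,
#' `z`]), normal components (`nx`, `ny`[, `nz`]), `time_s`, and tau
#' components (`tau_x`, `tau_y`[, `tau_z`]). The period is recovered on
#' read as `n_times * dt` of the uniform endpoint-exclusive grid.
#'
#' @param rec A [wss_record_set()].
#' @param path CSV file path.
#' @return `write_wss_csv` returns `path` invisibly; `read_wss_csv` returns
#'   a `wss_record_set`.
#' @export
write_wss_csv <- function(rec, path) {
  stopifnot(inherits(rec, "wss_record_set"))
  np <- n_points(rec); nt <- length(rec$times)
  pos <- if (is.null(rec$position)) matrix(NA_real_, np, ncol(rec$normal)) else rec$position
  df <- data.frame(
    point_id = rep(rec$point_id, each = nt),
    region = rep(rec$region, each = nt),
    x = rep(pos[, 1L], each = nt), y = rep(pos[, 2L], each = nt),
    nx = rep(rec$normal[, 1L], each = nt), ny = rep(rec$normal[, 2L], each = nt),
    time_s = rep(rec$times, np),
    tau_x = as.vector(t(rec$tau_x)), tau_y = as.vector(t(rec$tau_y)))
  if (is_3d(rec)) {
    df$z <- rep(pos[, 3L], each = nt)
    df$nz <- rep(rec$normal[, 3L], each = nt)
    df$tau_z <- as.vector(t(rec$tau_z))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wss_csv
#' @export
read_wss_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$point_id)
  nt <- sum(df$point_id == ids[1L])
  times <- df$time_s[seq_len(nt)]
  dt <- times[2L] - times[1L]
  period <- nt * dt
  first <- match(ids, df$point_id)
  d3 <- "tau_z" %in% names(df)
  shape <- function(col) matrix(df[[col]], nrow = length(ids), ncol = nt, byrow = TRUE)
  normal <- cbind(df$nx[first], df$ny[first])
  pos <- cbind(df$x[first], df$y[first])
  if (d3) {
    normal <- cbind(normal, df$nz[first])
    pos <- cbind(pos, df$z[first])
  }
  wss_record_set(times, period,
                 tau_x = shape("tau_x"), tau_y = shape("tau_y"),
                 tau_z = if (d3) shape("tau_z"),
                 normal = normal,
                 position = if (!anyNA(pos)) pos,
                 point_id = ids, region = df$region[first])
}
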