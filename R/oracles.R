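#' Fluid properties of the blood model
#'
#' Density and dynamic viscosity of the Newtonian blood model. Defaults are
#' the constants used throughout the pipeline: rho = 1235 kg/m^3 and
#' eta = 0.004 Pa s, a standard Newtonian approximation for murine blood.
#'
#' @param density_rho Density in kg/m^3 (> 0).
#' @param dynamic_viscosity_eta Dynamic viscosity in Pa s (> 0).
#' @return An object of class `fluid_properties`.
#' @examples
#' fluid_properties()           # blood-model defaults
#' fluid_properties(1000, 1e-3) # water-like
#' @export
fluid_properties <- function(density_rho = 1235, dynamic_viscosity_eta = 0.004) {
  if (!is.numeric(density_rho) || length(density_rho) != 1L ||
      !is.finite(density_rho) || density_rho <= 0)
    stop("invalid physical parameter: `density_rho` must be a positive number",
         call. = FALSE)
  if (!is.numeric(dynamic_viscosity_eta) || length(dynamic_viscosity_eta) != 1L ||
      !is.finite(dynamic_viscosity_eta) || dynamic_viscosity_eta <= 0)
    stop("invalid physical parameter: `dynamic_viscosity_eta` must be a positive number",
         call. = FALSE)
  structure(list(density_rho = density_rho,
                 dynamic_viscosity_eta = dynamic_viscosity_eta),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("<fluid_properties> rho = %g kg/m^3, eta = %g Pa s\n",
              x$density_rho, x$dynamic_viscosity_eta))
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("invalid physical parameter: `%s` must be a positive number", name),
         call. = FALSE)
  x
}

#' Reynolds number
#'
#' `Re = rho V D / eta` for characteristic speed `V` and length `D`.
#' With the blood-model defaults, V = 1 m/s and the aortic-root hydraulic
#' diameter D = 1.58 mm, this evaluates to 487.8 (rounds to 488), well
#' inside the laminar regime.
#'
#' @param props A [fluid_properties()].
#' @param speed_V Characteristic speed in m/s (>= 0).
#' @param diameter_D Characteristic length in m (> 0).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(props, speed_V, diameter_D) {
  stopifnot(inherits(props, "fluid_properties"))
  if (!is.numeric(speed_V) || length(speed_V) != 1L || !is.finite(speed_V) || speed_V < 0)
    stop("invalid physical parameter: `speed_V` must be a non-negative number",
         call. = FALSE)
  check_positive(diameter_D, "diameter_D")
  props$density_rho * speed_V * diameter_D / props$dynamic_viscosity_eta
}

#' Womersley number
#'
#' `alpha = R sqrt(omega rho / eta)`, the ratio of pulsatile inertia to
#' viscous effects; it controls the shape and phase lag of pulsatile
#' velocity profiles. `alpha << 1` is quasi-steady; the murine-aorta
#' defaults (R = 0.79 mm, T = 0.1 s) give alpha of about 3.5.
#'
#' @param radius_R Tube radius (or channel half-height) in m.
#' @param angular_freq_omega Angular frequency 2 pi / T in rad/s.
#' @param props A [fluid_properties()].
#' @return Dimensionless Womersley number.
#' @export
womersley_number <- function(radius_R, angular_freq_omega, props) {
  stopifnot(inherits(props, "fluid_properties"))
  check_positive(radius_R, "radius_R")
  check_positive(angular_freq_omega, "angular_freq_omega")
  radius_R * sqrt(angular_freq_omega * props$density_rho / props$dynamic_viscosity_eta)
}

#' Steady wall shear stress oracles
#'
#' Fully developed laminar steady solutions: `poiseuille_tube_wss` gives
#' `4 eta U / R` for a circular tube at mean velocity `U`;
#' `plane_poiseuille_wss` gives `6 eta U / h` for a plane channel of height
#' `h`. Both are exact limits used to validate the unsteady solver and the
#' Womersley series.
#'
#' @param props A [fluid_properties()].
#' @param mean_velocity_U Cross-section mean velocity in m/s (may be 0).
#' @param radius_R Tube radius in m.
#' @return Wall shear stress magnitude in Pa.
#' @export
poiseuille_tube_wss <- function(props, mean_velocity_U, radius_R) {
  stopifnot(inherits(props, "fluid_properties"), is.numeric(mean_velocity_U))
  check_positive(radius_R, "radius_R")
  4 * props$dynamic_viscosity_eta * mean_velocity_U / radius_R
}

#' @rdname poiseuille_tube_wss
#' @param height_h Channel height in m.
#' @export
plane_poiseuille_wss <- function(props, mean_velocity_U, height_h) {
  stopifnot(inherits(props, "fluid_properties"), is.numeric(mean_velocity_U))
  check_positive(height_h, "height_h")
  6 * props$dynamic_viscosity_eta * mean_velocity_U / height_h
}

#' Harmonic decomposition of a driving pressure gradient
#'
#' Represents the axial driving gradient `G(t) = -dp/dx` as a mean component
#' plus cosine harmonics of the fundamental angular frequency
#' `omega = 2 pi / period_T`:
#' `G(t) = mean + sum_k amplitude_k cos(k omega t + phase_k)`.
#' This is the driving term of the Womersley oracles; use
#' [channel_gradient_for_waveform()] or [tube_gradient_for_waveform()] to
#' obtain the gradient equivalent to a target mean-velocity waveform.
#'
#' @param mean_component Mean gradient in Pa/m.
#' @param amplitudes Amplitudes of harmonics 1, 2, ... in Pa/m (may be empty).
#' @param phases Phases in radians, same length as `amplitudes`.
#' @param period_T Fundamental period in seconds.
#' @return An object of class `harmonic_pressure_gradient`.
#' @export
harmonic_pressure_gradient <- function(mean_component, amplitudes = numeric(),
                                       phases = numeric(), period_T) {
  check_positive(period_T, "period_T")
  if (length(amplitudes) != length(phases))
    stop("`amplitudes` and `phases` must have the same length", call. = FALSE)
  if (any(!is.finite(amplitudes)) || any(!is.finite(phases)) || !is.finite(mean_component))
    stop("gradient components must be finite", call. = FALSE)
  structure(list(mean_component = mean_component,
                 amplitudes = as.numeric(amplitudes),
                 phases = as.numeric(phases),
                 period_T = period_T),
            class = "harmonic_pressure_gradient")
}

# Power-series J0 and J1 for complex argument. Base R's besselJ is
# real-only; the series is accurate to ~1e-12 for |z| <= 20, which covers
# Womersley numbers up to ~14 (far above the physiological range here).
bessel_j01_complex <- function(z) {
  if (any(Mod(z) > 20))
    stop("parameter out of supported range: Bessel series needs |z| <= 20 ",
         "(Womersley number too large)", call. = FALSE)
  q <- -(z * z) / 4
  term0 <- rep(1 + 0i, length(z))
  term1 <- rep(1 + 0i, length(z))
  j0 <- term0
  j1 <- term1
  for (k in 1:60) {
    term0 <- term0 * q / (k * k)
    term1 <- term1 * q / (k * (k + 1))
    j0 <- j0 + term0
    j1 <- j1 + term1
  }
  list(j0 = j0, j1 = (z / 2) * j1)
}

# Complex amplitudes G_k e^{i phase_k} for harmonics k = 1..K.
gradient_phasors <- function(grad) {
  grad$amplitudes * exp(1i * grad$phases)
}

#' Womersley pulsatile velocity profiles
#'
#' Exact velocity of fully developed laminar pulsatile flow driven by a
#' [harmonic_pressure_gradient()]. `womersley_tube_velocity` is the classical
#' circular-tube solution (complex Bessel J0 form); `womersley_channel_velocity`
#' is the plane-channel analogue (cosh form, `y` measured from the
#' centerline). Each harmonic is superposed on the steady Poiseuille
#' component of the mean gradient.
#'
#' @param grad A [harmonic_pressure_gradient()].
#' @param radius_R Tube radius in m.
#' @param props A [fluid_properties()].
#' @param r Radial positions in `[0, radius_R]` (tube) at which to evaluate.
#' @param times Times in seconds.
#' @return Matrix of axial velocity (m/s), `length(r)` (or `length(y)`) rows
#'   by `length(times)` columns.
#' @export
womersley_tube_velocity <- function(grad, radius_R, props, r, times) {
  stopifnot(inherits(grad, "harmonic_pressure_gradient"),
            inherits(props, "fluid_properties"))
  check_positive(radius_R, "radius_R")
  nu <- props$dynamic_viscosity_eta / props$density_rho
  omega <- 2 * pi / grad$period_T
  # Steady Poiseuille component: u = G (R^2 - r^2) / (4 eta)
  u <- outer(grad$mean_component * (radius_R^2 - r^2) / (4 * props$dynamic_viscosity_eta),
             rep(1, length(times)))
  Gk <- gradient_phasors(grad)
  for (k in seq_along(Gk)) {
    Om <- k * omega
    beta <- sqrt(Om / nu) * exp(-1i * pi / 4)  # beta^2 = -i Om / nu
    jw <- bessel_j01_complex(beta * radius_R)$j0
    prof <- (Gk[k] / (1i * props$density_rho * Om)) *
      (1 - bessel_j01_complex(beta * r)$j0 / jw)
    u <- u + Re(outer(prof, exp(1i * Om * times)))
  }
  u
}

#' @rdname womersley_tube_velocity
#' @param height_h Channel height in m (walls at `y = -h/2` and `y = +h/2`).
#' @param y Cross-channel positions measured from the centerline, in
#'   `[-h/2, h/2]`.
#' @export
womersley_channel_velocity <- function(grad, height_h, props, y, times) {
  stopifnot(inherits(grad, "harmonic_pressure_gradient"),
            inherits(props, "fluid_properties"))
  check_positive(height_h, "height_h")
  H <- height_h / 2
  nu <- props$dynamic_viscosity_eta / props$density_rho
  omega <- 2 * pi / grad$period_T
  u <- outer(grad$mean_component * (H^2 - y^2) / (2 * props$dynamic_viscosity_eta),
             rep(1, length(times)))
  Gk <- gradient_phasors(grad)
  for (k in seq_along(Gk)) {
    Om <- k * omega
    kappa <- sqrt(Om / nu) * exp(1i * pi / 4)  # kappa^2 = i Om / nu
    if (Mod(kappa * H) > 350)
      stop("parameter out of supported range: cosh overflow", call. = FALSE)
    prof <- (Gk[k] / (1i * props$density_rho * Om)) *
      (1 - cosh(kappa * y) / cosh(kappa * H))
    u <- u + Re(outer(prof, exp(1i * Om * times)))
  }
  u
}

womersley_series_times <- function(period_T, n_times) {
  n_times <- as.integer(n_times)
  if (is.na(n_times) || n_times < 8L)
    stop("`n_times` must be at least 8", call. = FALSE)
  seq(0, period_T, length.out = n_times + 1L)[seq_len(n_times)]
}

#' Womersley wall shear stress time series
#'
#' Exact wall shear stress `tau(t) = -eta du/dr` at `r = R` (tube) or
#' `tau(t) = eta du/dy` at the wall (channel) for pulsatile laminar flow
#' driven by a [harmonic_pressure_gradient()], evaluated at `n_times`
#' uniform, endpoint-exclusive times spanning one period. The sign
#' convention makes tau positive for forward flow. With no harmonics the
#' series is the constant steady value `G R / 2` (tube) or `G h / 2`
#' (channel).
#'
#' @inheritParams womersley_tube_velocity
#' @param n_times Number of uniform time samples (>= 8).
#' @return A data frame with columns `time_s` and `tau_pa`.
#' @export
womersley_wss_series <- function(grad, radius_R, props, n_times) {
  stopifnot(inherits(grad, "harmonic_pressure_gradient"),
            inherits(props, "fluid_properties"))
  check_positive(radius_R, "radius_R")
  times <- womersley_series_times(grad$period_T, n_times)
  nu <- props$dynamic_viscosity_eta / props$density_rho
  omega <- 2 * pi / grad$period_T
  tau <- rep(grad$mean_component * radius_R / 2, length(times))
  Gk <- gradient_phasors(grad)
  for (k in seq_along(Gk)) {
    Om <- k * omega
    beta <- sqrt(Om / nu) * exp(-1i * pi / 4)
    jb <- bessel_j01_complex(beta * radius_R)
    tau_hat <- -props$dynamic_viscosity_eta * (Gk[k] / (1i * props$density_rho * Om)) *
      beta * jb$j1 / jb$j0
    tau <- tau + Re(tau_hat * exp(1i * Om * times))
  }
  data.frame(time_s = times, tau_pa = tau)
}

#' @rdname womersley_wss_series
#' @export
womersley_channel_wss_series <- function(grad, height_h, props, n_times) {
  stopifnot(inherits(grad, "harmonic_pressure_gradient"),
            inherits(props, "fluid_properties"))
  check_positive(height_h, "height_h")
  H <- height_h / 2
  times <- womersley_series_times(grad$period_T, n_times)
  nu <- props$dynamic_viscosity_eta / props$density_rho
  omega <- 2 * pi / grad$period_T
  tau <- rep(grad$mean_component * H, length(times))
  Gk <- gradient_phasors(grad)
  for (k in seq_along(Gk)) {
    Om <- k * omega
    kappa <- sqrt(Om / nu) * exp(1i * pi / 4)
    tau_hat <- props$dynamic_viscosity_eta * (Gk[k] / (1i * props$density_rho * Om)) *
      kappa * tanh(kappa * H)
    tau <- tau + Re(tau_hat * exp(1i * Om * times))
  }
  data.frame(time_s = times, tau_pa = tau)
}

# Fourier coefficients of a periodic bezier waveform evaluated on a dense
# grid: returns mean and complex phasors U_k for e^{i k omega t}, k = 1..K.
waveform_phasors <- function(w, n_harmonics, n_fft = 2048L) {
  tt <- seq(0, w$period, length.out = n_fft + 1L)[seq_len(n_fft)]
  x <- evaluate_waveform(w, tt)
  X <- stats::fft(x) / n_fft
  list(mean = Re(X[1L]), phasors = 2 * X[1L + seq_len(n_harmonics)])
}

#' Convert a target mean-velocity waveform to an equivalent pressure gradient
#'
#' Inverts the analytic flow-rate/gradient transfer function per harmonic so
#' that fully developed Womersley flow driven by the returned gradient has
#' exactly the given cross-section mean-velocity waveform. For the plane
#' channel the mean-velocity response to a unit cosine gradient harmonic is
#' `(1 - tanh(kH)/(kH)) / (i rho Omega)` with `k^2 = i Omega / nu`; for the
#' tube it is `(1 - 2 J1(bR)/(bR J0(bR))) / (i rho Omega)` with
#' `b^2 = -i Omega / nu`. The steady components invert the Poiseuille
#' relations `U = G h^2 / (12 eta)` and `U = G R^2 / (8 eta)`.
#'
#' @param w A `bezier_waveform` giving the mean velocity over one cycle (m/s).
#' @param height_h Channel height in m.
#' @param props A [fluid_properties()].
#' @param n_harmonics Number of Fourier harmonics to keep.
#' @return A [harmonic_pressure_gradient()].
#' @export
channel_gradient_for_waveform <- function(w, height_h, props, n_harmonics = 8L) {
  stopifnot(inherits(w, "bezier_waveform"), inherits(props, "fluid_properties"))
  check_positive(height_h, "height_h")
  H <- height_h / 2
  nu <- props$dynamic_viscosity_eta / props$density_rho
  omega <- 2 * pi / w$period
  ph <- waveform_phasors(w, n_harmonics)
  G0 <- 12 * props$dynamic_viscosity_eta * ph$mean / height_h^2
  Gk <- complex(length.out = n_harmonics)
  for (k in seq_len(n_harmonics)) {
    Om <- k * omega
    kappa <- sqrt(Om / nu) * exp(1i * pi / 4)
    transfer <- (1 - tanh(kappa * H) / (kappa * H)) / (1i * props$density_rho * Om)
    Gk[k] <- ph$phasors[k] / transfer
  }
  harmonic_pressure_gradient(G0, Mod(Gk), Arg(Gk), w$period)
}

#' @rdname channel_gradient_for_waveform
#' @param radius_R Tube radius in m.
#' @export
tube_gradient_for_waveform <- function(w, radius_R, props, n_harmonics = 8L) {
  stopifnot(inherits(w, "bezier_waveform"), inherits(props, "fluid_properties"))
  check_positive(radius_R, "radius_R")
  nu <- props$dynamic_viscosity_eta / props$density_rho
  omega <- 2 * pi / w$period
  ph <- waveform_phasors(w, n_harmonics)
  G0 <- 8 * props$dynamic_viscosity_eta * ph$mean / radius_R^2
  Gk <- complex(length.out = n_harmonics)
  for (k in seq_len(n_harmonics)) {
    Om <- k * omega
    beta <- sqrt(Om / nu) * exp(-1i * pi / 4)
    jb <- bessel_j01_complex(beta * radius_R)
    transfer <- (1 - 2 * jb$j1 / (beta * radius_R * jb$j0)) /
      (1i * props$density_rho * Om)
    Gk[k] <- ph$phasors[k] / transfer
  }
  harmonic_pressure_gradient(G0, Mod(Gk), Arg(Gk), w$period)
}
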