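# From per-frame shape fits to the characteristic viscous sintering time.
#
# The squared Hopper parameter m^2(t) falls (nearly linearly over the pure
# initial sintering step) while the filaments coalesce. Matching the measured
# slope dm^2/dt against the dimensionless theoretical rate
# (dm^2/d(t/t_vs)) = f(m^2) of the master curve gives
#   t_vs = f(m2_ref) / (dm^2/dt)_experimental .

#' Assemble the per-frame sintering trajectory
#'
#' Combines per-frame Booth fits into one table: time, size (absolute and
#' normalized to the first valid frame), shape parameter B, Hopper parameter
#' m and m^2, and fit residual. Flagged (failed) frames keep their row with
#' `NA` values and `status = "failed"`.
#'
#' @param fits List of `"booth_fit"` objects (see [fit_sequence()]).
#' @param times Acquisition times in seconds, one per fit.
#' @param pixel_scale Pixels per millimetre (metadata).
#' @param temperature_c Set-point temperature in Celsius (metadata).
#' @return A data frame of class `"sinter_trajectory"` with columns
#'   `time_s`, `L_max_px`, `L_max_ratio`, `a_px`, `B`, `m`, `m_squared`,
#'   `residual_rms`, `status`.
#' @export
build_trajectory <- function(fits, times, pixel_scale = NA_real_,
                             temperature_c = NA_real_) {
  stopifnot(length(fits) > 0L, length(fits) == length(times))
  a <- vapply(fits, function(f) f$a, numeric(1))
  B <- vapply(fits, function(f) f$B, numeric(1))
  res <- vapply(fits, function(f) f$residual_rms, numeric(1))
  ok <- is.finite(B)
  if (!any(ok)) stop("no frame produced a valid fit", call. = FALSE)
  m <- ifelse(ok, (1 - B) / (1 + B), NA_real_)
  lmax <- 2 * a
  l0 <- lmax[which(ok)[1]]
  out <- data.frame(
    time_s = times,
    L_max_px = lmax,
    L_max_ratio = lmax / l0,
    a_px = a,
    B = B,
    m = m,
    m_squared = m^2,
    residual_rms = res,
    status = ifelse(ok, "ok", "failed"))
  structure(out, class = c("sinter_trajectory", "data.frame"),
            pixel_scale = pixel_scale, temperature_c = temperature_c)
}

#' Experimental slope of m^2 against time
#'
#' Ordinary least-squares slope of `m_squared` on `time_s` over the frames
#' inside the analysis window (the pure initial sintering step, once the
#' filament surface has reached the molten steady state).
#'
#' @param traj A [build_trajectory()] table.
#' @param window Numeric `c(t_start, t_end)` in seconds (inclusive).
#' @return List with `slope` (1/s), `se` (its standard error), `n`,
#'   `window`, and `m2_mean` (mean m^2 inside the window, the natural
#'   reference point for the master-curve coefficient).
#' @export
experimental_slope <- function(traj, window = c(20, 60)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  sel <- traj$status == "ok" & traj$time_s >= window[1] &
    traj$time_s <= window[2]
  if (sum(sel) < 3L)
    stop(sprintf("need >= 3 valid frames in window [%g, %g] s (found %d)",
                 window[1], window[2], sum(sel)), call. = FALSE)
  fit <- stats::lm(m_squared ~ time_s, data = traj[sel, ])
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["time_s", "Estimate"]),
       se = unname(sm["time_s", "Std. Error"]),
       n = sum(sel), window = window,
       m2_mean = mean(traj$m_squared[sel]))
}

#' Theoretical coefficient from the master curve
#'
#' Evaluates the master curve's polynomial at the reference \eqn{m^2},
#' giving the dimensionless rate \eqn{(dm^2/d(t/t_{vs}))_{theoretical}}.
#' Requests outside the tabulated span are an error (no extrapolation).
#'
#' @param curve A [master_curve()] object.
#' @param m2_ref Reference \eqn{m^2} inside the curve's span.
#' @return The (negative) dimensionless theoretical coefficient.
#' @examples
#' master_coefficient(default_master_curve(), 0.3)  # about -0.473
#' @export
master_coefficient <- function(curve, m2_ref) {
  stopifnot(inherits(curve, "master_curve"), length(m2_ref) == 1L)
  predict(curve, m2_ref)
}

#' Characteristic viscous sintering time
#'
#' \eqn{t_{vs} = (dm^2/d\tau)_{theoretical} / (dm^2/dt)_{experimental}}.
#' The uncertainty is propagated to first order from the slope's standard
#' error only: \eqn{\Delta t_{vs} = t_{vs} \Delta s / |s|} (the theoretical
#' coefficient is treated as exact).
#'
#' @param slope Experimental slope \eqn{dm^2/dt} in 1/s, negative.
#' @param theoretical_coefficient Master-curve value, negative.
#' @param slope_se Standard error of the slope (optional).
#' @return List with `t_vs` (s) and `t_vs_se` (s, `NA` without `slope_se`).
#' @examples
#' characteristic_time(-0.0060, -0.4727, 0.0024)  # t_vs = 78.8 s
#' @export
characteristic_time <- function(slope, theoretical_coefficient,
                                slope_se = NA_real_) {
  if (!is.finite(slope) || slope >= 0)
    stop("experimental slope must be negative (no coalescence signal)",
         call. = FALSE)
  if (!is.finite(theoretical_coefficient) || theoretical_coefficient >= 0)
    stop("theoretical coefficient must be negative", call. = FALSE)
  t_vs <- theoretical_coefficient / slope
  list(t_vs = t_vs,
       t_vs_se = if (is.finite(slope_se)) t_vs * slope_se / abs(slope)
                 else NA_real_)
}

#' Viscosity-to-surface-tension ratio
#'
#' From \eqn{t_{vs} = R_i \mu / \Gamma}: \eqn{\mu/\Gamma = t_{vs}/R_i},
#' in seconds per metre (Pa s per N/m).
#'
#' @param t_vs Characteristic viscous sintering time (s), positive.
#' @param R_i Initial filament radius (m), positive.
#' @return \eqn{\mu/\Gamma} in s/m.
#' @export
capillary_ratio <- function(t_vs, R_i) {
  if (!is.finite(t_vs) || t_vs <= 0) stop("t_vs must be positive",
                                          call. = FALSE)
  if (!is.finite(R_i) || R_i <= 0) stop("R_i must be positive",
                                        call. = FALSE)
  t_vs / R_i
}

#' Per-frame bonding neck length and bonding angle
#'
#' Derives the classical neck-growth observables from the fitted shapes:
#' \eqn{x_{neck} = 2 a B} and \eqn{\theta = \arcsin(x_{neck}/d)} with
#' \eqn{d = 2 R_i}. Frames where the neck exceeds the filament diameter
#' (late-stage coalescence, the angle is no longer defined) carry `NA`.
#'
#' @param traj A [build_trajectory()] table.
#' @param R_i_px Initial filament radius in pixels.
#' @return `traj` with columns `x_neck_px` and `theta_rad` appended.
#' @export
neck_angle_series <- function(traj, R_i_px) {
  stopifnot(is.finite(R_i_px), R_i_px > 0)
  x_neck <- 2 * traj$a_px * traj$B
  traj$x_neck_px <- x_neck
  traj$theta_rad <- bonding_angle(x_neck, 2 * R_i_px)
  traj
}

#' Sintering kinetics from a trajectory
#'
#' Runs the kinetic analysis on a per-frame trajectory: OLS slope of m^2
#' over the analysis window, master-curve coefficient at the reference m^2,
#' and the characteristic viscous sintering time with propagated
#' uncertainty.
#'
#' @param traj A [build_trajectory()] table.
#' @param window Analysis window `c(t_start, t_end)` in seconds; default
#'   `c(20, 60)`, the pure initial sintering step after the ~20 s thermal
#'   warm-up.
#' @param curve A [master_curve()]; default the packaged Hopper curve.
#' @param m2_ref Reference \eqn{m^2} at which the theoretical coefficient is
#'   taken. Default `NULL` uses the mean observed m^2 inside the window,
#'   matching the OLS slope's averaging of the curved decay; supply a number
#'   (e.g. 0.3) to fix it.
#' @return Object of class `"sinter_kinetics"`: list with `slope`,
#'   `slope_se`, `window`, `m2_ref`, `theoretical_coefficient`, `t_vs`,
#'   `t_vs_se`, `n`.
#' @export
sinter_kinetics <- function(traj, window = c(20, 60),
                            curve = default_master_curve(), m2_ref = NULL) {
  sl <- experimental_slope(traj, window)
  if (is.null(m2_ref)) m2_ref <- sl$m2_mean
  coeff <- master_coefficient(curve, m2_ref)
  ct <- characteristic_time(sl$slope, coeff, sl$se)
  structure(list(slope = sl$slope, slope_se = sl$se, window = window,
                 m2_ref = m2_ref, theoretical_coefficient = coeff,
                 t_vs = ct$t_vs, t_vs_se = ct$t_vs_se, n = sl$n),
            class = "sinter_kinetics")
}

#' @export
print.sinter_kinetics <- function(x, ...) {
  cat(sprintf(
    paste0("Viscous sintering kinetics\n",
           "  window: [%g, %g] s (%d frames)\n",
           "  dm2/dt (experimental): %.3e +/- %.1e 1/s\n",
           "  theoretical coefficient f(m2 = %.3f): %.4f\n",
           "  t_vs = %.1f +/- %.1f s\n"),
    x$window[1], x$window[2], x$n, x$slope, x$slope_se, x$m2_ref,
    x$theoretical_coefficient, x$t_vs, x$t_vs_se))
  invisible(x)
}
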