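# Closed-form geometry of lemniscates of Booth ("inverted ellipses") and
# their equivalent description by Hopper's coalescence parameter m.
#
# Conventions used throughout the package:
#   * phi is the polar angle from the positive x axis; the two filaments lie
#     along x, so the bonding-neck plane is x = 0 and the waist sits at
#     phi = +/- pi/2. Angles are accepted unrestricted (the curve has period
#     pi) and reduced internally.
#   * B is the dimensionless shape parameter, B = 1 for a circle, B -> 0 for
#     two tangent circles. It is clamped to (1e-6, 1] to avoid degenerate
#     zero-radius rays.
#   * m is Hopper's parameter, m = 0 circle, m -> 1 tangent circles;
#     B = (1 - m)/(1 + m).
#   * R0 is the radius of the fully coalesced circle; with two initial
#     filaments of radius R_i and conserved cross-section area,
#     R0 = sqrt(2) * R_i.

.B_MIN <- 1e-6

#' Lemniscate of Booth
#'
#' Construct a lemniscate of Booth in its polar form
#' \eqn{r(\varphi) = a \sqrt{\cos^2\varphi + B^2 \sin^2\varphi}}, the
#' one-parameter family of "inverted ellipses" through which the silhouette of
#' two coalescing cylinders evolves: two tangent circles as \eqn{B \to 0}, a
#' single circle of radius \eqn{a} at \eqn{B = 1}.
#'
#' @param a Size coefficient (length units, e.g. pixels): the half-extent of
#'   the curve along its long axis.
#' @param B Shape parameter in (0, 1].
#' @return An object of class `"booth"`, a list with elements `a` and `B`.
#' @examples
#' booth(a = 1.28, B = 0.47)
#' @export
booth <- function(a, B) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0)
  check_B(B)
  structure(list(a = a, B = max(B, .B_MIN)), class = "booth")
}

#' @export
print.booth <- function(x, ...) {
  cat(sprintf("Lemniscate of Booth: a = %.6g, B = %.6g (m = %.6g)\n",
              x$a, x$B, m_from_b(x$B)))
  invisible(x)
}

check_B <- function(B) {
  if (!is.numeric(B) || any(!is.finite(B)) || any(B <= 0) || any(B > 1))
    stop("shape parameter B must lie in (0, 1]", call. = FALSE)
  invisible(B)
}

check_m <- function(m) {
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0) || any(m >= 1))
    stop("Hopper parameter m must lie in [0, 1)", call. = FALSE)
  invisible(m)
}

#' Polar radius of a lemniscate of Booth
#'
#' Evaluates \eqn{r(\varphi) = a \sqrt{\cos^2\varphi + B^2 \sin^2\varphi}}.
#' The radius has period \eqn{\pi}, maximum \eqn{a} at \eqn{\varphi = 0}
#' (filament axis) and minimum \eqn{aB} at \eqn{\varphi = \pi/2} (bonding
#' neck).
#'
#' @param shape A [booth()] object, or a size coefficient `a` if `B` is given.
#' @param phi Polar angle(s) in radians, unrestricted.
#' @param B Shape parameter, only when `shape` is given as a plain number.
#' @return Numeric vector of radii, same length as `phi`.
#' @examples
#' booth_radius(booth(1, 0.5), c(0, pi / 2))  # 1.0, 0.5
#' @export
booth_radius <- function(shape, phi, B = NULL) {
  if (inherits(shape, "booth")) {
    a <- shape$a
    b <- shape$B
  } else {
    a <- shape
    b <- B
    stopifnot(is.numeric(a), a > 0)
    check_B(b)
  }
  a * sqrt(cos(phi)^2 + b^2 * sin(phi)^2)
}

#' Convert between the shape parameter B and Hopper's parameter m
#'
#' The two one-parameter descriptions of the coalescence stage are linked by
#' \eqn{B = (1 - m)/(1 + m)}, a strictly decreasing involution-like pair:
#' `m_from_b()` is the exact inverse of `b_from_m()`.
#'
#' @param m Hopper parameter(s) in [0, 1).
#' @param B Shape parameter(s) in (0, 1].
#' @return `b_from_m()` returns B in (0, 1]; `m_from_b()` returns m in [0, 1).
#' @examples
#' b_from_m(0.64)   # 0.2195
#' m_from_b(0.19)   # 0.6807
#' @export
b_from_m <- function(m) {
  check_m(m)
  (1 - m) / (1 + m)
}

#' @rdname b_from_m
#' @export
m_from_b <- function(B) {
  check_B(B)
  (1 - B) / (1 + B)
}

#' Constant-area size coefficient
#'
#' The area enclosed by the polar lemniscate is \eqn{\pi a^2 (1 + B^2) / 2}.
#' Two coalescing cylinders conserve their cross-section area
#' \eqn{\pi R_0^2} (with \eqn{R_0 = \sqrt{2} R_i}), which pins the size
#' coefficient to \eqn{a = R_0 \sqrt{2 / (1 + B^2)}}: \eqn{\sqrt{2} R_0} for
#' two tangent circles down to \eqn{R_0} for the final circle.
#'
#' @param B Shape parameter(s) in (0, 1].
#' @param R0 Equivalent final radius (length units), positive.
#' @return Size coefficient(s) `a` in the units of `R0`.
#' @examples
#' a_constant_area(0.47, 1)  # 1.28
#' a_constant_area(0.75, 1)  # 1.13
#' @export
a_constant_area <- function(B, R0) {
  check_B(B)
  if (!is.numeric(R0) || any(!is.finite(R0)) || any(R0 <= 0))
    stop("R0 must be positive", call. = FALSE)
  R0 * sqrt(2 / (1 + B^2))
}

#' Enclosed area of a lemniscate of Booth
#'
#' Closed form \eqn{\frac{1}{2}\oint r(\varphi)^2 d\varphi =
#' \pi a^2 (1 + B^2)/2}.
#'
#' @inheritParams booth_radius
#' @return Enclosed area (length^2 units).
#' @export
booth_area <- function(shape, B = NULL) {
  if (inherits(shape, "booth")) {
    a <- shape$a
    b <- shape$B
  } else {
    a <- shape
    b <- B
    stopifnot(is.numeric(a), all(a > 0))
    check_B(b)
  }
  pi * a^2 * (1 + b^2) / 2
}

#' Boundary points of the coalescing-cylinder profile (Hopper form)
#'
#' Samples the Cartesian parametric boundary of the constant-area profile for
#' Hopper parameter `m`:
#' \deqn{x(\alpha) = \frac{R_0 (1 - m^2)(1 - m) \sin\alpha}
#'   {\sqrt{1 + m^2}\,(1 + 2m\cos 2\alpha + m^2)}, \quad
#'   y(\alpha) = \frac{R_0 (1 - m^2)(1 + m) \cos\alpha}
#'   {\sqrt{1 + m^2}\,(1 + 2m\cos 2\alpha + m^2)}}
#' with \eqn{\alpha \in [0, 2\pi)}. This is the bounded, area-consistent
#' pairing of the \eqn{(1 \pm m)} factors (see the methods vignette); the
#' curve coincides with the polar lemniscate of [booth_radius()] under
#' \eqn{B = (1-m)/(1+m)}, \eqn{a = R_0 (1+m)/\sqrt{1+m^2}} and
#' \eqn{\varphi = \alpha - \pi/2}. Here the long axis lies along x
#' (horizontal filament layout), so \eqn{\alpha = \pi/2} maps to the point
#' \eqn{(a, 0)}.
#'
#' @param m Hopper parameter in [0, 1).
#' @param R0 Equivalent final radius (length units).
#' @param n_points Number of boundary points (at least 4), equally spaced
#'   in \eqn{\alpha}.
#' @param alpha Optional explicit vector of curve parameters, overriding
#'   `n_points`.
#' @return A two-column matrix with columns `x` and `y`.
#' @examples
#' xy <- sample_curve(0.36, R0 = 1, n_points = 8)
#' @export
sample_curve <- function(m, R0 = 1, n_points = 360L, alpha = NULL) {
  check_m(m)
  stopifnot(R0 > 0)
  if (is.null(alpha)) {
    if (n_points < 4L) stop("n_points must be at least 4", call. = FALSE)
    alpha <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  }
  den <- sqrt(1 + m^2) * (1 + 2 * m * cos(2 * alpha) + m^2)
  x <- R0 * (1 - m^2) * (1 - m) * sin(alpha) / den
  y <- R0 * (1 - m^2) * (1 + m) * cos(alpha) / den
  cbind(x = x, y = y)
}

#' Bonding-neck length of the coalescence profile
#'
#' Full thickness of the waist at the symmetry plane,
#' \eqn{x_{neck} = 2 a B = 2 R_0 (1 - m)/\sqrt{1 + m^2}} under area
#' conservation: zero for tangent circles, \eqn{2 R_0} (the full diameter)
#' once coalescence completes.
#'
#' @inheritParams sample_curve
#' @return Neck length in the units of `R0`.
#' @export
neck_length <- function(m, R0 = 1) {
  check_m(m)
  stopifnot(R0 > 0)
  2 * R0 * (1 - m) / sqrt(1 + m^2)
}

#' Bonding angle between two coalescing round parts
#'
#' \eqn{\theta = \arcsin(x_{neck} / d)}, the classical neck-growth observable
#' for two parts of diameter `d`. The formula is only meaningful while the
#' neck is no wider than the part diameter; later frames (late-stage
#' coalescence) return `NA` rather than an angle.
#'
#' @param x_neck Bonding-neck length(s), same units as `d`, nonnegative.
#' @param d Part (filament) diameter, positive.
#' @return Angle(s) in radians in [0, pi/2]; `NA` where `x_neck > d`.
#' @examples
#' bonding_angle(1, 2)  # pi/6
#' @export
bonding_angle <- function(x_neck, d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("diameter d must be a positive number", call. = FALSE)
  if (any(x_neck < 0, na.rm = TRUE))
    stop("neck length must be nonnegative", call. = FALSE)
  out <- rep(NA_real_, length(x_neck))
  ok <- !is.na(x_neck) & x_neck <= d
  out[ok] <- asin(x_neck[ok] / d)
  out
}
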