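# Per-frame estimation of the Booth shape parameter B.
#
# The size coefficient is fixed from the measurement, a = L_max / 2, and B is
# the single free parameter, found by derivative-free simplex descent
# (Nelder-Mead, the fminsearch family) on the radial least-squares objective
#   SS(B) = sum_i ( r_i - a * sqrt(cos^2(phi_i) + B^2 sin^2(phi_i)) )^2 .
# The radial residual matches the polar formulation of the curve and is
# robust for a one-parameter search; points with r < 2 px are dropped
# because phi is numerically unstable near the origin.

#' Fit a lemniscate of Booth to a contour point set
#'
#' Estimates the shape parameter B of
#' \eqn{r(\varphi) = a\sqrt{\cos^2\varphi + B^2\sin^2\varphi}} by
#' least squares on the radial residuals, with the size coefficient held
#' fixed (by default at `L_max / 2` taken from the contour's attributes).
#' The optimum is located by Nelder-Mead simplex descent and clamped to
#' (1e-6, 1].
#'
#' @param contour A `"sinter_contour"` data frame (columns `r`, `phi`), e.g.
#'   from [frame_contour()], or any data frame with those columns.
#' @param a Fixed size coefficient in pixels; default `attr(contour,
#'   "L_max") / 2`.
#' @param b_init Starting value for B (default 0.5).
#' @param r_min Points with radius below this (pixels) are excluded
#'   (default 2).
#' @param edge_offset_px Radial offset added to the contour radii before
#'   fitting. Morphological contour pixels are the outermost foreground
#'   pixels, whose centres sit about half a pixel inside the continuous
#'   silhouette boundary, whereas the fixed size coefficient
#'   `a = L_max / 2` (extent convention `max - min + 1`) measures to the
#'   outer pixel edge; the offset reconciles the two conventions. Default
#'   `NULL`: 0.5 for pixel contours (class `"sinter_contour"`), 0 for plain
#'   data frames (e.g. analytically sampled curves).
#' @param control Optimizer settings: `maxit` (default 500), `reltol`
#'   parameter tolerance (default 1e-6), `abstol` objective tolerance
#'   (default 1e-9).
#' @return An object of class `"booth_fit"`: list with `a`, `B`, `m`,
#'   `residual_rms`, `n_points`, `converged`, `objective`, and the retained
#'   contour (`contour`).
#' @examples
#' phi <- seq(-pi, pi, length.out = 100)
#' ctr <- data.frame(r = booth_radius(booth(100, 0.4), phi), phi = phi)
#' fit <- fit_booth(ctr, a = 100)
#' coef(fit)["B"]  # 0.4
#' @export
fit_booth <- function(contour, a = NULL, b_init = 0.5, r_min = 2,
                      edge_offset_px = NULL, control = list()) {
  if (is.null(edge_offset_px))
    edge_offset_px <- if (inherits(contour, "sinter_contour")) 0.5 else 0
  if (is.null(a)) {
    lmax <- attr(contour, "L_max")
    if (is.null(lmax)) stop("no fixed 'a' given and contour has no L_max",
                            call. = FALSE)
    a <- lmax / 2
  }
  stopifnot(is.numeric(a), length(a) == 1L, a > 0)
  keep <- is.finite(contour$r) & is.finite(contour$phi) & contour$r >= r_min
  r <- contour$r[keep] + edge_offset_px
  phi <- contour$phi[keep]
  if (length(r) < 8L)
    stop("need at least 8 usable contour points", call. = FALSE)
  if (all(r == 0)) stop("degenerate contour: all radii zero", call. = FALSE)
  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-6, abstol = 1e-9),
                           control)
  cos2 <- cos(phi)^2
  sin2 <- sin(phi)^2
  obj <- function(B) {
    if (B <= .B_MIN || B > 1) {
      # quadratic penalty pulls the simplex back into the admissible range
      Bc <- min(max(B, .B_MIN), 1)
      return(obj_val(Bc) + 1e6 * (B - Bc)^2)
    }
    obj_val(B)
  }
  obj_val <- function(B) sum((r - a * sqrt(cos2 + B^2 * sin2))^2)
  opt <- suppressWarnings(stats::optim(
    par = min(max(b_init, .B_MIN), 1), fn = obj, method = "Nelder-Mead",
    control = list(maxit = ctl$maxit, reltol = ctl$reltol,
                   abstol = ctl$abstol, warn.1d.NelderMead = FALSE)))
  B <- min(max(opt$par, .B_MIN), 1)
  if (1 - B < 1e-7) B <- 1      # snap the boundary optimum (circle)
  ss <- obj_val(B)
  structure(list(a = a, B = B, m = m_from_b(B),
                 residual_rms = sqrt(ss / length(r)),
                 n_points = length(r),
                 converged = opt$convergence == 0L,
                 objective = ss,
                 edge_offset_px = edge_offset_px,
                 contour = data.frame(r = r, phi = phi)),
            class = "booth_fit")
}

#' @export
print.booth_fit <- function(x, ...) {
  cat(sprintf(
    "Booth fit: a = %.2f px (fixed), B = %.4f (m = %.4f)\n%s%d contour points, residual RMS = %.3f px\n",
    x$a, x$B, x$m, if (x$converged) "" else "[not converged] ", x$n_points,
    x$residual_rms))
  invisible(x)
}

#' @export
coef.booth_fit <- function(object, ...) {
  c(a = object$a, B = object$B, m = object$m)
}

#' Predicted lemniscate radius at given polar angles
#'
#' @param object A `"booth_fit"`.
#' @param phi Polar angles (radians); default: the fitted contour's angles.
#' @param ... Unused.
#' @return Predicted radii (pixels).
#' @export
predict.booth_fit <- function(object, phi = object$contour$phi, ...) {
  booth_radius(object$a, phi, B = object$B)
}

#' @export
residuals.booth_fit <- function(object, ...) {
  object$contour$r - predict(object)
}

#' @export
fitted.booth_fit <- function(object, ...) predict(object)

#' Plot a fitted lemniscate over its contour
#'
#' Draws the contour points and the fitted Booth lemniscate in centered
#' Cartesian coordinates.
#'
#' @param x A `"booth_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.booth_fit <- function(x, ...) {
  ctr <- x$contour
  phi <- seq(-pi, pi, length.out = 361L)
  rr <- predict(x, phi)
  plot(ctr$r * cos(ctr$phi), ctr$r * sin(ctr$phi), pch = ".", asp = 1,
       xlab = "x (px)", ylab = "y (px)",
       main = sprintf("B = %.3f, a = %.1f px", x$B, x$a), ...)
  graphics::lines(rr * cos(phi), rr * sin(phi), col = "red", lwd = 2)
  invisible(x)
}

#' Fit a sequence of contours with warm starts
#'
#' Fits each frame's contour in time order; each fit starts from the
#' previous frame's estimate (the shape changes slowly between frames),
#' the first from `b_init`. A frame whose fit fails is flagged and does not
#' interrupt the sequence.
#'
#' @param contours List of `"sinter_contour"` objects (see
#'   [frame_contour()]), in time order.
#' @param b_init Starting B for the first frame (default 0.5).
#' @param a Optional vector of fixed size coefficients (default: each
#'   contour's `L_max / 2`).
#' @param ... Passed to [fit_booth()].
#' @return List of `"booth_fit"` objects; failed frames hold a `"booth_fit"`
#'   with `NA` parameters, `converged = FALSE` and the error message in
#'   `$error`.
#' @export
fit_sequence <- function(contours, b_init = 0.5, a = NULL, ...) {
  if (!length(contours)) stop("empty contour list", call. = FALSE)
  fits <- vector("list", length(contours))
  b_prev <- b_init
  for (i in seq_along(contours)) {
    ai <- if (is.null(a)) NULL else a[i]
    fit <- tryCatch(fit_booth(contours[[i]], a = ai, b_init = b_prev, ...),
                    error = function(e) {
                      structure(list(a = NA_real_, B = NA_real_, m = NA_real_,
                                     residual_rms = NA_real_, n_points = 0L,
                                     converged = FALSE, objective = NA_real_,
                                     error = conditionMessage(e)),
                                class = "booth_fit")
                    })
    if (is.finite(fit$B)) b_prev <- fit$B
    fits[[i]] <- fit
  }
  fits
}
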