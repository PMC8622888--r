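# Hopper's dimensionless coalescence master curve.
#
# For plane Stokes flow driven by capillarity, the profile of two coalescing
# equal cylinders stays inside the Booth-lemniscate family and the shape
# parameter m(t) obeys an exact evolution law. In the dimensionless time
# tau = t / t_vs with t_vs = R_i * mu / Gamma, the squared parameter decays as
#
#   dm^2/dtau = -(2 sqrt(2) / pi) * m^2 * sqrt(1 + m^2) * E(k = (1-m)/(1+m))
#
# where E is the complete elliptic integral of the second kind (modulus
# convention: parameter = k^2 = B^2). The package ships this law tabulated at
# 45 knots over m^2 in [0.05, 0.9] (inst/extdata/hopper_master_curve.csv)
# together with a polynomial fit, mirroring the abacus-plus-polynomial
# workflow used in practice; users may substitute their own digitization.

#' Exact Hopper coalescence rate
#'
#' Closed-form dimensionless rate \eqn{dm^2/d\tau} of Hopper's plane-flow
#' solution for two coalescing equal cylinders, as a function of \eqn{m^2}
#' (\eqn{\tau = t/t_{vs}}, \eqn{t_{vs} = R_i \mu / \Gamma}). Negative over
#' \eqn{m^2 \in (0, 1)}: capillarity only drives the shape toward the circle.
#'
#' @param m2 Squared Hopper parameter(s) in [0, 1).
#' @return \eqn{dm^2/d\tau}, dimensionless and nonpositive.
#' @examples
#' hopper_rate(0.3)  # -0.4732
#' @export
hopper_rate <- function(m2) {
  if (any(!is.finite(m2)) || any(m2 < 0) || any(m2 >= 1))
    stop("m2 must lie in [0, 1)", call. = FALSE)
  m <- sqrt(m2)
  B <- (1 - m) / (1 + m)
  E <- vapply(B^2, function(p) pracma::ellipke(p)$e, numeric(1))
  -(2 * sqrt(2) / pi) * m2 * sqrt(1 + m2) * E
}

#' Tabulate the Hopper master curve
#'
#' Evaluates [hopper_rate()] on an equally spaced grid of \eqn{m^2} knots,
#' giving a master-curve table in the same layout as the packaged CSV.
#'
#' @param n Number of knots.
#' @param span Numeric length-2, the \eqn{m^2} range covered.
#' @return A data frame with columns `m_squared` and `dm2_dtau`.
#' @export
hopper_master_table <- function(n = 45L, span = c(0.05, 0.9)) {
  stopifnot(n >= 5L, length(span) == 2L, span[1] > 0, span[2] < 1,
            span[1] < span[2])
  m2 <- seq(span[1], span[2], length.out = n)
  data.frame(m_squared = m2, dm2_dtau = hopper_rate(m2))
}

#' Master curve of viscous coalescence kinetics
#'
#' Builds a `master_curve` object from a table of
#' \eqn{(m^2, dm^2/d\tau)} knots: either a data frame or the path of a CSV
#' file with columns `m_squared` and `dm2_dtau`. A polynomial of the given
#' degree is fitted by least squares with \eqn{1/f^2} weights (relative-error
#' weighting, so small rates near full coalescence are not swamped by the
#' large early-stage rates); the fit is the curve's working representation
#' for coefficient extraction via [master_coefficient()].
#'
#' @param x Data frame or CSV path with columns `m_squared`, `dm2_dtau`.
#' @param degree Polynomial degree (default 3).
#' @return An object of class `"master_curve"`: list with `table`,
#'   `coefficients` (ascending powers), `degree`, `span`.
#' @seealso [default_master_curve()] for the packaged Hopper tabulation.
#' @export
master_curve <- function(x, degree = 3L) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("master-curve file not found: ", x, call. = FALSE)
    x <- utils::read.csv(x)
  }
  if (!is.data.frame(x) || !all(c("m_squared", "dm2_dtau") %in% names(x)))
    stop("master curve needs columns 'm_squared' and 'dm2_dtau'", call. = FALSE)
  tab <- x[order(x$m_squared), c("m_squared", "dm2_dtau")]
  if (nrow(tab) < degree + 2L)
    stop("too few knots for a degree-", degree, " fit", call. = FALSE)
  if (any(tab$dm2_dtau >= 0))
    stop("dm2_dtau must be negative over the table (coalescence only shrinks m)",
         call. = FALSE)
  fit <- stats::lm(dm2_dtau ~ stats::poly(m_squared, degree, raw = TRUE),
                   data = tab, weights = 1 / tab$dm2_dtau^2)
  structure(list(table = tab,
                 coefficients = unname(stats::coef(fit)),
                 degree = as.integer(degree),
                 span = range(tab$m_squared)),
            class = "master_curve")
}

#' @export
print.master_curve <- function(x, ...) {
  cat(sprintf(
    "Coalescence master curve: %d knots over m^2 in [%.3g, %.3g], degree-%d fit\n",
    nrow(x$table), x$span[1], x$span[2], x$degree))
  invisible(x)
}

#' Evaluate the master-curve polynomial
#'
#' @param object A [master_curve()] object.
#' @param m2 Values of \eqn{m^2} inside the tabulated span.
#' @param ... Unused.
#' @return \eqn{dm^2/d\tau} at `m2`.
#' @export
predict.master_curve <- function(object, m2, ...) {
  if (any(m2 < object$span[1] - 1e-12) || any(m2 > object$span[2] + 1e-12))
    stop(sprintf("m2 outside the tabulated span [%.3g, %.3g]",
                 object$span[1], object$span[2]), call. = FALSE)
  drop(outer(m2, 0:object$degree, `^`) %*% object$coefficients)
}

#' Packaged Hopper master curve
#'
#' The master curve shipped with the package: Hopper's exact plane-flow
#' coalescence rate tabulated at 45 knots over \eqn{m^2 \in [0.05, 0.9]}
#' (see [hopper_rate()]), with a degree-3 polynomial fit.
#'
#' @param degree Polynomial degree for the fit (default 3).
#' @return A `"master_curve"` object.
#' @examples
#' mc <- default_master_curve()
#' master_coefficient(mc, 0.3)  # about -0.473
#' @export
default_master_curve <- function(degree = 3L) {
  path <- system.file("extdata", "hopper_master_curve.csv",
                      package = "sinterfit", mustWork = TRUE)
  master_curve(path, degree = degree)
}

# rate function for trajectory integration: polynomial inside the span,
# linear-to-origin below it (the exact rate vanishes ~ linearly in m^2)
curve_rate_fun <- function(curve) {
  lo <- curve$span[1]
  f_lo <- predict(curve, lo)
  function(m2) {
    if (m2 <= 0) return(0)
    if (m2 < lo) return(f_lo * m2 / lo)
    predict(curve, m2)
  }
}
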