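# End-to-end analysis: frames -> contours -> Booth fits -> trajectory ->
# sintering kinetics, with optional CSV/JSON/overlay outputs.

#' Analysis configuration
#'
#' Free parameters of the image pipeline and kinetic analysis. A YAML file
#' with any subset of these keys can seed the configuration; explicit
#' arguments win over file values.
#'
#' @param threshold Grey-level threshold in [0, 255]; `NULL` for the
#'   automatic bimodal fallback (a fixed visually-chosen value is the
#'   recommended workflow).
#' @param polarity `"dark_object"` (backlit acquisition, default) or
#'   `"bright_object"`.
#' @param roi Optional crop `c(row_min, row_max, col_min, col_max)`.
#' @param base_rows_excluded Bottom rows excluded from contours (oven base).
#' @param pixel_scale Pixels per millimetre (metadata).
#' @param frame_interval_s Seconds between frames when times are implicit.
#' @param window Kinetic analysis window `c(t_start, t_end)` s.
#' @param m2_ref Reference m^2 for the master-curve coefficient; `NULL`
#'   (default) uses the window mean.
#' @param master_curve_path Path of a master-curve CSV; `NULL` for the
#'   packaged Hopper curve.
#' @param output_dir Where [analyze_sequence()] writes its outputs; `NULL`
#'   disables writing.
#' @param overlays Write per-frame overlay PNGs (contour and fitted curve
#'   drawn over the source frame)?
#' @param file Optional YAML config file supplying defaults.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(threshold = NULL,
                            polarity = c("dark_object", "bright_object"),
                            roi = NULL, base_rows_excluded = 0L,
                            pixel_scale = NA_real_, frame_interval_s = 1,
                            window = c(20, 60), m2_ref = NULL,
                            master_curve_path = NULL, output_dir = NULL,
                            overlays = FALSE, file = NULL) {
  cfg <- list(threshold = threshold, polarity = match.arg(polarity),
              roi = roi, base_rows_excluded = as.integer(base_rows_excluded),
              pixel_scale = pixel_scale,
              frame_interval_s = frame_interval_s, window = window,
              m2_ref = m2_ref, master_curve_path = master_curve_path,
              output_dir = output_dir, overlays = isTRUE(overlays))
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file,
                                 call. = FALSE)
    from_file <- yaml::read_yaml(file)
    unknown <- setdiff(names(from_file), names(cfg))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    supplied <- setdiff(names(as.list(match.call())[-1]), "file")
    for (k in setdiff(names(from_file), supplied)) cfg[[k]] <- from_file[[k]]
    cfg$window <- as.numeric(unlist(cfg$window))
    if (!is.null(cfg$roi)) cfg$roi <- as.integer(unlist(cfg$roi))
    cfg$base_rows_excluded <- as.integer(cfg$base_rows_excluded)
  }
  if (!is.null(cfg$threshold) &&
      (cfg$threshold < 0 || cfg$threshold > 255))
    stop("threshold must lie in [0, 255]", call. = FALSE)
  if (length(cfg$window) != 2L || cfg$window[1] >= cfg$window[2])
    stop("window must be c(t_start, t_end) with t_start < t_end",
         call. = FALSE)
  structure(cfg, class = "analysis_config")
}

#' Analyze a sintering image sequence
#'
#' Runs the full pipeline on a sequence: crop, segment, erosion contour,
#' centering and polar conversion, warm-started Booth fits, trajectory
#' assembly and kinetic analysis. A frame that fails any stage is flagged
#' and the run continues; the kinetics section is marked not-computable when
#' fewer than 3 valid frames fall inside the window.
#'
#' @param input A directory of frames, a manifest CSV path, or a list of
#'   [sinter_frame()] objects.
#' @param config An [analysis_config()].
#' @return An object of class `"sinter_analysis"`: list with `trajectory`
#'   (the per-frame [build_trajectory()] table), `kinetics` (a
#'   [sinter_kinetics()] or `NULL` with the reason in `kinetics_error`),
#'   `fits`, `config`, `n_frames`. If `config$output_dir` is set, writes
#'   `trajectory.csv`, `summary.json` and (optionally) `overlay_*.png`
#'   there.
#' @export
analyze_sequence <- function(input, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  frames <- if (is.character(input))
    read_sequence(input, config$frame_interval_s, config$pixel_scale)
  else input
  if (!length(frames)) stop("no frames to analyze", call. = FALSE)
  times <- vapply(frames, function(f) f$time_s, numeric(1))
  if (all(is.na(times)))
    times <- (seq_along(frames) - 1) * config$frame_interval_s
  contours <- lapply(frames, function(fr) {
    tryCatch(frame_contour(fr, threshold = config$threshold,
                           polarity = config$polarity, roi = config$roi,
                           base_rows_excluded = config$base_rows_excluded),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "contour_error"))
  })
  a_fixed <- vapply(contours, function(ct) {
    if (inherits(ct, "contour_error")) NA_real_ else attr(ct, "L_max") / 2
  }, numeric(1))
  ok_ct <- !is.na(a_fixed)
  fits <- vector("list", length(frames))
  fits[ok_ct] <- fit_sequence(contours[ok_ct], a = a_fixed[ok_ct])
  failed <- structure(list(a = NA_real_, B = NA_real_, m = NA_real_,
                           residual_rms = NA_real_, n_points = 0L,
                           converged = FALSE, objective = NA_real_),
                      class = "booth_fit")
  fits[!ok_ct] <- lapply(contours[!ok_ct],
                         function(ct) { f <- failed; f$error <- ct$error; f })
  if (!any(vapply(fits, function(f) is.finite(f$B), logical(1))))
    stop("all frames failed to segment or fit", call. = FALSE)
  traj <- build_trajectory(fits, times, pixel_scale = config$pixel_scale)
  curve <- if (is.null(config$master_curve_path)) default_master_curve()
           else master_curve(config$master_curve_path)
  kin <- tryCatch(sinter_kinetics(traj, window = config$window,
                                  curve = curve, m2_ref = config$m2_ref),
                  error = function(e) e)
  kin_err <- if (inherits(kin, "error")) conditionMessage(kin) else NULL
  if (inherits(kin, "error")) kin <- NULL
  res <- structure(list(trajectory = traj, kinetics = kin,
                        kinetics_error = kin_err, fits = fits,
                        config = config, n_frames = length(frames)),
                   class = "sinter_analysis")
  if (!is.null(config$output_dir))
    write_analysis(res, frames, contours, config$output_dir)
  res
}

write_analysis <- function(res, frames, contours, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$trajectory, file.path(out_dir, "trajectory.csv"),
                   row.names = FALSE)
  summ <- analysis_summary(res)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (res$config$overlays) {
    for (i in seq_along(frames)) {
      if (inherits(contours[[i]], "contour_error")) next
      ov <- overlay_frame(frames[[i]], contours[[i]], res$fits[[i]])
      png::writePNG(ov, file.path(out_dir, sprintf("overlay_%04d.png", i)))
    }
  }
  invisible(out_dir)
}

analysis_summary <- function(res) {
  k <- res$kinetics
  list(
    n_frames = res$n_frames,
    n_fitted = sum(res$trajectory$status == "ok"),
    threshold = res$config$threshold,
    window = res$config$window,
    m2_ref = if (is.null(k)) NULL else k$m2_ref,
    master_curve = if (is.null(res$config$master_curve_path)) "packaged"
                   else res$config$master_curve_path,
    slope = if (is.null(k)) NULL else k$slope,
    slope_se = if (is.null(k)) NULL else k$slope_se,
    theoretical_coefficient = if (is.null(k)) NULL
                              else k$theoretical_coefficient,
    t_vs = if (is.null(k)) NULL else k$t_vs,
    t_vs_uncertainty = if (is.null(k)) NULL else k$t_vs_se,
    kinetics_error = res$kinetics_error)
}

# contour pixels in green, fitted lemniscate in red, over the grey frame
overlay_frame <- function(frame, contour, fit) {
  g <- frame$pixels / 255
  rgb <- array(g, dim = c(nrow(g), ncol(g), 3L))
  cen <- attr(contour, "center")
  ctr_rows <- round(cen["row"] - contour$y)
  ctr_cols <- round(contour$x + cen["col"])
  ok <- ctr_rows >= 1 & ctr_rows <= nrow(g) & ctr_cols >= 1 &
    ctr_cols <= ncol(g)
  rgb[cbind(ctr_rows[ok], ctr_cols[ok], 1L)] <- 0
  rgb[cbind(ctr_rows[ok], ctr_cols[ok], 2L)] <- 1
  rgb[cbind(ctr_rows[ok], ctr_cols[ok], 3L)] <- 0
  if (is.finite(fit$B)) {
    phi <- seq(0, 2 * pi, length.out = 1440L)
    rr <- booth_radius(fit$a, phi, B = fit$B)
    fr_rows <- round(cen["row"] - rr * sin(phi))
    fr_cols <- round(rr * cos(phi) + cen["col"])
    ok <- fr_rows >= 1 & fr_rows <= nrow(g) & fr_cols >= 1 &
      fr_cols <= ncol(g)
    rgb[cbind(fr_rows[ok], fr_cols[ok], 1L)] <- 1
    rgb[cbind(fr_rows[ok], fr_cols[ok], 2L)] <- 0
    rgb[cbind(fr_rows[ok], fr_cols[ok], 3L)] <- 0
  }
  rgb
}

#' @export
print.sinter_analysis <- function(x, ...) {
  cat(sprintf("Sintering sequence analysis: %d frames (%d fitted)\n",
              x$n_frames, sum(x$trajectory$status == "ok")))
  if (!is.null(x$kinetics)) print(x$kinetics)
  else cat("  kinetics not computable:", x$kinetics_error, "\n")
  invisible(x)
}

#' @export
summary.sinter_analysis <- function(object, ...) {
  s <- analysis_summary(object)
  tr <- object$trajectory[object$trajectory$status == "ok", ]
  s$B_range <- range(tr$B)
  s$L_max_ratio_final <- tr$L_max_ratio[nrow(tr)]
  class(s) <- "summary.sinter_analysis"
  s
}

#' @export
print.summary.sinter_analysis <- function(x, ...) {
  cat(sprintf("Frames fitted: %d/%d\n", x$n_fitted, x$n_frames))
  cat(sprintf("B range: %.3f .. %.3f; final L_max ratio: %.3f\n",
              x$B_range[1], x$B_range[2], x$L_max_ratio_final))
  if (!is.null(x$t_vs))
    cat(sprintf("t_vs = %.1f +/- %.1f s (window [%g, %g] s)\n",
                x$t_vs, x$t_vs_uncertainty, x$window[1], x$window[2]))
  else cat("kinetics not computable:", x$kinetics_error, "\n")
  invisible(x)
}

#' @export
coef.sinter_analysis <- function(object, ...) {
  k <- object$kinetics
  if (is.null(k)) return(c(t_vs = NA_real_, slope = NA_real_))
  c(t_vs = k$t_vs, t_vs_se = k$t_vs_se, slope = k$slope,
    slope_se = k$slope_se, theoretical_coefficient = k$theoretical_coefficient,
    m2_ref = k$m2_ref)
}

#' Plot the fitted sintering trajectory
#'
#' Two panels: the shape parameter B and the normalized size
#' L_max/L_max_initial against time, with the analysis window shaded.
#'
#' @param x A `"sinter_analysis"`.
#' @param ... Unused.
#' @export
plot.sinter_analysis <- function(x, ...) {
  tr <- x$trajectory[x$trajectory$status == "ok", ]
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(tr$time_s, tr$B, xlab = "time (s)", ylab = "B", pch = 16, cex = 0.6)
  graphics::abline(v = x$config$window, lty = 3)
  plot(tr$time_s, tr$L_max_ratio, xlab = "time (s)",
       ylab = "L_max / L_max_initial", pch = 16, cex = 0.6)
  invisible(x)
}
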