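# Forward simulator: ground-truthed backlit sintering sequences.
#
# The generator emulates the acquisition geometry of an instrumented
# sintering oven: a dark filament-pair silhouette (a Booth-lemniscate
# region) backlit on a bright background, 8-bit grey levels, 1 frame/s,
# ~200 px/mm. The shape trajectory m(t) follows the master-curve kinetics
# at a prescribed true t_vs after a static thermal warm-up; late-stage
# viscoelastic swelling/spreading is emulated as isotropic scaling of the
# size coefficient at fixed B, ramping the observed L_max ratio to a
# plateau (the real phenomenology: size ratio stable at ~112% after about
# 90 s).

#' Simulation configuration
#'
#' Collects every knob of the synthetic-sequence generator with defaults
#' mirroring the real acquisition: 1 frame/s, ~200 px/mm, filament radius
#' about 1 mm so \eqn{R_0 = \sqrt{2} R_i \approx 283} px, 8-bit grey levels,
#' initial Hopper parameter 0.68 (a measured starting shape of B = 0.19),
#' a 20 s warm-up during which the shape is static, and a swell ramp that
#' takes the observed size ratio to 1.12 between 60 s and 90 s.
#'
#' @param t_vs_true True characteristic viscous sintering time (s).
#' @param m_initial Initial Hopper parameter in (0, 1).
#' @param warmup_s Static warm-up duration (s).
#' @param frame_interval_s Seconds between frames.
#' @param n_frames Number of frames.
#' @param R0_px Equivalent final radius in pixels.
#' @param image_size Integer `c(rows, cols)` of each frame.
#' @param object_grey,background_grey Grey levels of silhouette and
#'   backlight, separated by at least 50.
#' @param blur_sigma_px Gaussian blur of the optics (px, 0 disables).
#' @param noise_sigma_grey Additive Gaussian grey noise (sd, 0 disables).
#' @param swell_ratio_final Late-stage plateau of L_max / L_max_initial
#'   (`NA` disables swelling; default 1.12).
#' @param swell_start_s,swell_end_s Swell ramp timing (s): the observed size
#'   ratio rises linearly from its area-conserving value at `swell_start_s`
#'   to `swell_ratio_final` at `swell_end_s`, then holds.
#' @param base_strip_rows Rows of a solid dark "oven base" strip at the
#'   image bottom (0 disables).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(t_vs_true = 80, m_initial = 0.68,
                              warmup_s = 20, frame_interval_s = 1,
                              n_frames = 120L, R0_px = 283,
                              image_size = c(780L, 960L),
                              object_grey = 30, background_grey = 220,
                              blur_sigma_px = 1, noise_sigma_grey = 3,
                              swell_ratio_final = 1.12, swell_start_s = 60,
                              swell_end_s = 90, base_strip_rows = 0L,
                              seed = 1L) {
  stopifnot(t_vs_true > 0, m_initial > 0, m_initial < 1, warmup_s >= 0,
            frame_interval_s > 0, n_frames >= 1L, R0_px > 0,
            length(image_size) == 2L, all(image_size >= 16L),
            object_grey >= 0, object_grey <= 255,
            background_grey >= 0, background_grey <= 255,
            blur_sigma_px >= 0, noise_sigma_grey >= 0,
            base_strip_rows >= 0L)
  if (abs(object_grey - background_grey) < 50)
    stop("object and background grey levels must differ by at least 50",
         call. = FALSE)
  if (is.finite(swell_ratio_final))
    stopifnot(swell_ratio_final > 0, swell_start_s < swell_end_s)
  structure(list(t_vs_true = t_vs_true, m_initial = m_initial,
                 warmup_s = warmup_s, frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames), R0_px = R0_px,
                 image_size = as.integer(image_size),
                 object_grey = object_grey,
                 background_grey = background_grey,
                 blur_sigma_px = blur_sigma_px,
                 noise_sigma_grey = noise_sigma_grey,
                 swell_ratio_final = swell_ratio_final,
                 swell_start_s = swell_start_s, swell_end_s = swell_end_s,
                 base_strip_rows = as.integer(base_strip_rows),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Ground-truth shape trajectory
#'
#' Integrates the master-curve kinetics
#' \eqn{dm^2/dt = f(m^2)/t_{vs}} by fixed-step classical 4th-order
#' Runge-Kutta (4 substeps per frame interval), holding the shape static
#' during the warm-up and flooring \eqn{m^2} at 0. The size coefficient
#' follows the constant-area closed form, then the swell ramp described in
#' [simulation_config()].
#'
#' @param cfg A [simulation_config()].
#' @param curve A [master_curve()]; default the packaged Hopper curve. Its
#'   span must reach `m_initial^2`.
#' @return Data frame with columns `time_s`, `m_true`, `B_true`,
#'   `a_true_px`, `L_max_true_px`.
#' @export
simulate_trajectory <- function(cfg, curve = default_master_curve()) {
  stopifnot(inherits(cfg, "sim_config"))
  u0 <- cfg$m_initial^2
  if (u0 > curve$span[2])
    stop(sprintf("master curve span [%.3g, %.3g] does not reach m_initial^2 = %.3g",
                 curve$span[1], curve$span[2], u0), call. = FALSE)
  f <- curve_rate_fun(curve)
  times <- (seq_len(cfg$n_frames) - 1) * cfg$frame_interval_s
  u <- numeric(cfg$n_frames)
  u[1] <- u0
  nsub <- 4L
  h <- cfg$frame_interval_s / nsub
  cur <- u0
  for (i in seq_len(cfg$n_frames - 1L)) {
    t0 <- times[i]
    for (s in seq_len(nsub)) {
      ts <- t0 + (s - 1L) * h
      if (ts + h <= cfg$warmup_s) next          # static during warm-up
      hh <- if (ts < cfg$warmup_s) ts + h - cfg$warmup_s else h
      k1 <- f(cur) / cfg$t_vs_true
      k2 <- f(max(cur + hh / 2 * k1, 0)) / cfg$t_vs_true
      k3 <- f(max(cur + hh / 2 * k2, 0)) / cfg$t_vs_true
      k4 <- f(max(cur + hh * k3, 0)) / cfg$t_vs_true
      cur <- max(cur + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    }
    u[i + 1L] <- cur
  }
  m <- sqrt(u)
  B <- (1 - m) / (1 + m)
  a_area <- a_constant_area(B, cfg$R0_px)
  a_true <- a_area
  if (is.finite(cfg$swell_ratio_final)) {
    ratio_area <- a_area / a_area[1]
    r_start <- stats::approx(times, ratio_area, xout = cfg$swell_start_s,
                             rule = 2)$y
    ramp <- times > cfg$swell_start_s
    frac <- pmin((times - cfg$swell_start_s) /
                   (cfg$swell_end_s - cfg$swell_start_s), 1)
    target <- r_start + frac * (cfg$swell_ratio_final - r_start)
    a_true[ramp] <- target[ramp] * a_area[1]
  }
  data.frame(time_s = times, m_true = m, B_true = B, a_true_px = a_true,
             L_max_true_px = 2 * a_true)
}

# vertical half-extent of the Booth region (the lobe tops sit above the
# waist when B^2 < 1/2)
booth_half_height <- function(a, B) {
  ifelse(B^2 >= 0.5, a * B, a / (2 * sqrt(1 - B^2)))
}

#' Render one synthetic backlit frame
#'
#' Rasterizes the Booth-lemniscate region (the region is star-shaped about
#' its centre, so the inside test `r <= r_booth(phi)` is well defined) at
#' the image centre: silhouette pixels get `object_grey`, the rest
#' `background_grey`. Then, in order: Gaussian blur, additive Gaussian grey
#' noise, clipping to [0, 255], 8-bit quantization, and an optional solid
#' base strip over the bottom rows.
#'
#' @param truth A one-row slice of [simulate_trajectory()] output (or any
#'   list with `a_true_px`, `B_true`, and optionally `time_s`).
#' @param cfg A [simulation_config()].
#' @param seed Optional seed for the noise; default `NULL` draws from the
#'   current RNG state.
#' @return A [sinter_frame()].
#' @export
render_frame <- function(truth, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  a <- truth$a_true_px
  B <- truth$B_true
  nr <- cfg$image_size[1]
  nc <- cfg$image_size[2]
  # the object's symmetry axes are aligned with a pixel centre so that the
  # ground truth is not confounded by an arbitrary rasterization phase
  c_row <- ceiling((nr + 1) / 2)
  c_col <- ceiling((nc + 1) / 2)
  half_h <- booth_half_height(a, B)
  if (a + 5 > min(c_col - 1, nc - c_col) ||
      half_h + 5 > min(c_row - 1, nr - c_row))
    stop("shape does not fit in the frame with a 5 px margin", call. = FALSE)
  x <- matrix(rep(seq_len(nc) - c_col, each = nr), nr, nc)
  y <- matrix(rep(c_row - seq_len(nr), times = nc), nr, nc)
  r2 <- x^2 + y^2
  rb <- booth_radius(a, atan2(y, x), B = B)
  img <- matrix(cfg$background_grey, nr, nc)
  img[r2 <= rb^2] <- cfg$object_grey
  if (cfg$base_strip_rows > 0L)
    img[(nr - cfg$base_strip_rows + 1L):nr, ] <- cfg$object_grey
  if (cfg$blur_sigma_px > 0)
    img <- EBImage::gblur(img, sigma = cfg$blur_sigma_px)
  if (cfg$noise_sigma_grey > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + stats::rnorm(length(img), sd = cfg$noise_sigma_grey)
  }
  img <- round(pmin(pmax(img, 0), 255))
  sinter_frame(img, time_s = if (!is.null(truth$time_s)) truth$time_s
                             else NA_real_,
               pixel_scale = NA_real_)
}

#' Generate a ground-truthed synthetic dataset on disk
#'
#' Writes `n_frames` 8-bit grayscale PNG files (`frame_0001.png`, ...), a
#' manifest CSV (`filename`, `time_s`) and a ground-truth CSV matching
#' [simulate_trajectory()]. Re-running with the same configuration (and
#' seed) reproduces identical bytes.
#'
#' @param cfg A [simulation_config()].
#' @param curve A [master_curve()]; default the packaged Hopper curve.
#' @param out_dir Output directory (created if missing; parent must exist).
#' @return Invisibly, a list with `frames` (paths), `manifest`,
#'   `ground_truth` (paths) and the truth table.
#' @export
generate_dataset <- function(cfg, curve = default_master_curve(), out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(dirname(out_dir)))
    stop("parent directory does not exist: ", dirname(out_dir),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE)
  truth <- simulate_trajectory(cfg, curve)
  set.seed(cfg$seed)
  files <- sprintf("frame_%04d.png", seq_len(cfg$n_frames))
  for (i in seq_len(cfg$n_frames)) {
    fr <- render_frame(truth[i, ], cfg)
    ok <- tryCatch(png::writePNG(fr$pixels / 255,
                                 target = file.path(out_dir, files[i])),
                   error = function(e)
                     stop("failed to write ", file.path(out_dir, files[i]),
                          ": ", conditionMessage(e), call. = FALSE))
  }
  man_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(data.frame(filename = files, time_s = truth$time_s),
                   man_path, row.names = FALSE, quote = FALSE)
  gt_path <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(truth, gt_path, row.names = FALSE, quote = FALSE)
  invisible(list(frames = file.path(out_dir, files), manifest = man_path,
                 ground_truth = gt_path, truth = truth))
}
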