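# Shared fixtures: all synthetic, built in code at test time.

# brute-force 3x3 binary erosion (border treated as background): the oracle
# for the morphological contour definition
brute_erode3 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] != 1) next
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || mask[ii, jj] != 1)
        ok <- FALSE
    }
    if (ok) out[i, j] <- 1
  }
  out
}

# numeric quadrature of the enclosed area of r(phi), oracle for booth_area
quad_area <- function(a, B, n = 20000L) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- booth_radius(a, phi, B = B)
  0.5 * sum(r^2) * (2 * pi / n)
}

# render a single noise-controlled frame of a constant-area Booth shape
render_shape <- function(B, R0 = 90, noise = 0, blur = 0,
                         image_size = c(301L, 401L), seed = NULL) {
  cfg <- simulation_config(R0_px = R0, image_size = image_size,
                           n_frames = 2L, noise_sigma_grey = noise,
                           blur_sigma_px = blur, swell_ratio_final = NA)
  a <- a_constant_area(B, R0)
  render_frame(list(a_true_px = a, B_true = B, time_s = 0), cfg, seed = seed)
}

# small scaled-down simulated sequence rendered in memory
simulate_frames <- function(cfg, curve = default_master_curve()) {
  truth <- simulate_trajectory(cfg, curve)
  set.seed(cfg$seed)
  frames <- lapply(seq_len(cfg$n_frames),
                   function(i) render_frame(truth[i, ], cfg))
  list(truth = truth, frames = frames)
}

# master curve built from an arbitrary rate function (for surrogate-rate
# tests, e.g. a constant or linear law)
table_curve <- function(f, span = c(0.02, 0.9), n = 30L, degree = 3L) {
  u <- seq(span[1], span[2], length.out = n)
  master_curve(data.frame(m_squared = u, dm2_dtau = f(u)), degree = degree)
}
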