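# End-to-end sequence analysis, outputs, and the command-line interface.

small_cfg <- function(seed = 9, n_frames = 70L, t_vs = 40) {
  simulation_config(t_vs_true = t_vs, n_frames = n_frames, R0_px = 80,
                    image_size = c(281L, 341L), swell_ratio_final = NA,
                    seed = seed)
}

test_that("analyze_sequence recovers t_vs on a simulated sequence", {
  sim <- simulate_frames(small_cfg())
  out <- withr::local_tempdir()
  res <- analyze_sequence(sim$frames,
                          analysis_config(threshold = 128,
                                          output_dir = out))
  expect_s3_class(res, "sinter_analysis")
  expect_equal(nrow(res$trajectory), 70L)
  expect_true(all(res$trajectory$status == "ok"))
  expect_lt(abs(res$kinetics$t_vs / 40 - 1), 0.10)
  # written outputs
  expect_true(file.exists(file.path(out, "trajectory.csv")))
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(summ$t_vs, res$kinetics$t_vs, tolerance = 1e-12)
  # summary JSON round-trip: the identity t_vs = coeff / slope holds exactly
  csv <- read.csv(file.path(out, "trajectory.csv"))
  sl <- experimental_slope(build_trajectory(
    Map(function(a, B) structure(list(a = a, B = B, residual_rms = 0),
                                 class = "booth_fit"),
        csv$a_px, csv$B), csv$time_s), c(20, 60))
  redo <- characteristic_time(sl$slope, summ$theoretical_coefficient)
  expect_equal(redo$t_vs, summ$t_vs, tolerance = 1e-9)
})

test_that("failed frames are flagged without derailing the run", {
  sim <- simulate_frames(small_cfg(n_frames = 40L, t_vs = 20))
  frames <- sim$frames
  frames[[10]] <- sinter_frame(matrix(220, 281, 341))   # pure background
  res <- analyze_sequence(frames, analysis_config(threshold = 128))
  expect_equal(nrow(res$trajectory), 40L)
  expect_equal(res$trajectory$status[10], "failed")
  expect_equal(sum(res$trajectory$status == "failed"), 1L)
  expect_true(all(is.finite(res$trajectory$B[-10])))
})

test_that("kinetics degrade gracefully with too few frames in the window", {
  sim <- simulate_frames(small_cfg(n_frames = 10L, t_vs = 20))
  res <- analyze_sequence(sim$frames, analysis_config(threshold = 128))
  expect_null(res$kinetics)
  expect_match(res$kinetics_error, "window")
  expect_equal(nrow(res$trajectory), 10L)     # per-frame table still there
  # single frame
  res1 <- analyze_sequence(sim$frames[1], analysis_config(threshold = 128))
  expect_equal(nrow(res1$trajectory), 1L)
  expect_null(res1$kinetics)
})

test_that("overlay images are written with contour and curve colours", {
  sim <- simulate_frames(small_cfg(n_frames = 2L))
  out <- withr::local_tempdir()
  analyze_sequence(sim$frames,
                   analysis_config(threshold = 128, output_dir = out,
                                   overlays = TRUE, window = c(0, 1)))
  ov_path <- file.path(out, "overlay_0001.png")
  expect_true(file.exists(ov_path))
  ov <- png::readPNG(ov_path)
  expect_equal(dim(ov)[3], 3L)
  is_green <- ov[, , 2] == 1 & ov[, , 1] == 0
  is_red <- ov[, , 1] == 1 & ov[, , 2] == 0
  expect_gt(sum(is_green), 100)     # contour pixels
  expect_gt(sum(is_red), 100)       # fitted lemniscate
})

test_that("config files seed the analysis configuration and flags win", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("threshold: 77", "polarity: bright_object",
               "window: [10, 50]", "base_rows_excluded: 3"), f)
  cfg <- analysis_config(file = f)
  expect_equal(cfg$threshold, 77)
  expect_equal(cfg$polarity, "bright_object")
  expect_equal(cfg$window, c(10, 50))
  expect_equal(cfg$base_rows_excluded, 3L)
  # explicit arguments beat the file
  cfg2 <- analysis_config(threshold = 128, file = f)
  expect_equal(cfg2$threshold, 128)
  expect_equal(cfg2$window, c(10, 50))
  expect_error(analysis_config(threshold = 300), "threshold")
  expect_error(analysis_config(window = c(5, 2)), "window")
})

test_that("the CLI simulates reproducibly and analyzes its own output", {
  base <- withr::local_tempdir()
  d1 <- file.path(base, "sim1"); d2 <- file.path(base, "sim2")
  args <- c("simulate", "--t-vs", "40", "--frames", "30", "--seed", "7",
            "--r0-px", "60", "--out")
  expect_equal(sinterfit_cli(c(args, d1)), 0L)
  expect_equal(sinterfit_cli(c(args, d2)), 0L)
  expect_length(list.files(d1, pattern = "frame_.*png"), 30L)
  expect_identical(readLines(file.path(d1, "ground_truth.csv")),
                   readLines(file.path(d2, "ground_truth.csv")))
  # analyze the simulated directory through the CLI
  out <- file.path(base, "ana")
  st <- sinterfit_cli(c("analyze", d1, "--threshold", "128", "--out", out))
  expect_equal(st, 0L)
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_lt(abs(summ$t_vs / 40 - 1), 0.15)
  # single-frame diagnostic prints the fitted parameters
  msg <- capture.output(
    st2 <- sinterfit_cli(c("fit-frame", file.path(d1, "frame_0001.png"),
                           "--threshold", "128")))
  expect_equal(st2, 0L)
  expect_match(msg, "B = 0\\.1[5-9]", all = FALSE)
})

test_that("the CLI reports failures with a nonzero status", {
  base <- withr::local_tempdir()
  expect_equal(suppressMessages(
    sinterfit_cli(c("simulate", "--out", file.path(base, "no", "deep")))),
    1L)
  expect_equal(suppressMessages(sinterfit_cli("frobnicate")), 1L)
  expect_equal(suppressMessages(sinterfit_cli(character())), 1L)
  bad <- file.path(base, "corrupt.png")
  writeLines("not a png", bad)
  expect_equal(suppressMessages(sinterfit_cli(c("fit-frame", bad))), 1L)
})
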