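# From a raw backlit 8-bit frame to a centered, polar-converted contour
# point set.
#
# Coordinate conventions (used consistently across the package):
#   * pixel grids are integer matrices, rows x cols, 0-based indexing is NOT
#     used: (row, col) are 1-based with row 1 at the top, as R matrices;
#   * grey levels are integers in [0, 255];
#   * centered coordinates: x = col - centroid_col (rightward),
#     y = row_of_L_max - row (upward), so phi = atan2(y, x) follows the usual
#     mathematical orientation.

#' A single acquisition frame
#'
#' Wraps one 8-bit grayscale image with its acquisition time and spatial
#' scale.
#'
#' @param pixels Numeric/integer matrix of grey levels in [0, 255]
#'   (rows x cols).
#' @param time_s Acquisition time in seconds.
#' @param pixel_scale Pixels per millimetre (default `NA`).
#' @return An object of class `"sinter_frame"`.
#' @export
sinter_frame <- function(pixels, time_s = NA_real_, pixel_scale = NA_real_) {
  stopifnot(is.matrix(pixels))
  if (any(pixels < 0 | pixels > 255))
    stop("grey levels must lie in [0, 255] (8-bit)", call. = FALSE)
  structure(list(pixels = pixels, time_s = time_s, pixel_scale = pixel_scale),
            class = "sinter_frame")
}

#' @export
print.sinter_frame <- function(x, ...) {
  cat(sprintf("8-bit frame %d x %d px, t = %s s\n",
              nrow(x$pixels), ncol(x$pixels),
              format(x$time_s)))
  invisible(x)
}

#' Read one 8-bit grayscale frame from disk
#'
#' Supports PNG and TIFF. Multi-channel images are reduced to grayscale by
#' averaging the colour channels.
#'
#' @param path Image file path (`.png`, `.tif`, `.tiff`).
#' @param time_s Acquisition time attached to the frame.
#' @param pixel_scale Pixels per millimetre.
#' @return A [sinter_frame()].
#' @export
read_frame <- function(path, time_s = NA_real_, pixel_scale = NA_real_) {
  if (!file.exists(path)) stop("cannot read frame: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3L, dim(img)[3]),
                                               drop = FALSE], c(1, 2), mean)
  sinter_frame(round(img * 255), time_s = time_s, pixel_scale = pixel_scale)
}

#' Read an image sequence
#'
#' Frames are either listed in a manifest CSV (columns `filename`, `time_s`;
#' paths relative to the manifest location) or taken as all PNG/TIFF files in
#' a directory in lexicographic order, with times `(index - 1) *
#' frame_interval_s`.
#'
#' @param path Directory of frames, or path of a manifest CSV.
#' @param frame_interval_s Seconds between frames when no manifest gives
#'   explicit times (default 1, the usual 1 frame/s acquisition).
#' @param pixel_scale Pixels per millimetre, attached to every frame.
#' @return List of [sinter_frame()] objects in time order.
#' @export
read_sequence <- function(path, frame_interval_s = 1, pixel_scale = NA_real_) {
  if (dir.exists(path)) {
    manifest <- file.path(path, "manifest.csv")
    if (file.exists(manifest)) return(read_sequence(manifest,
                                                    frame_interval_s,
                                                    pixel_scale))
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames in ", path, call. = FALSE)
    times <- (seq_along(files) - 1) * frame_interval_s
  } else if (file.exists(path)) {
    man <- utils::read.csv(path)
    if (!all(c("filename", "time_s") %in% names(man)))
      stop("manifest needs columns 'filename' and 'time_s'", call. = FALSE)
    files <- file.path(dirname(path), man$filename)
    times <- man$time_s
    o <- order(times)
    files <- files[o]
    times <- times[o]
  } else stop("no such file or directory: ", path, call. = FALSE)
  unname(Map(read_frame, files, times,
             MoreArgs = list(pixel_scale = pixel_scale)))
}

#' Crop a region of interest
#'
#' Extracts a rectangular sub-image, leaving grey levels untouched.
#'
#' @param frame A [sinter_frame()].
#' @param roi Integer vector `c(row_min, row_max, col_min, col_max)`
#'   (1-based, inclusive), or `NULL` for no cropping.
#' @return A [sinter_frame()] of the cropped region.
#' @export
crop_roi <- function(frame, roi) {
  stopifnot(inherits(frame, "sinter_frame"))
  if (is.null(roi)) return(frame)
  roi <- as.integer(roi)
  if (length(roi) != 4L || roi[1] > roi[2] || roi[3] > roi[4])
    stop("roi must be c(row_min, row_max, col_min, col_max)", call. = FALSE)
  if (roi[1] < 1L || roi[3] < 1L || roi[2] > nrow(frame$pixels) ||
      roi[4] > ncol(frame$pixels))
    stop("roi extends outside the frame", call. = FALSE)
  sinter_frame(frame$pixels[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE],
               time_s = frame$time_s, pixel_scale = frame$pixel_scale)
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so labels
# touching only diagonally are merged afterwards with a small union-find.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))
  pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                        pairs[, 1] != pairs[, 2], , drop = FALSE])
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- lab
  out[lab > 0] <- root[lab[lab > 0]]
  out
}

#' Segment the filament silhouette
#'
#' Thresholds the frame into a binary mask with the filament pair as the
#' single foreground object (value 1) on background 0, regardless of the
#' imaging polarity: backlit frames show a dark object on a bright background
#' (`polarity = "dark_object"`, the default). After thresholding, only the
#' largest 8-connected component is kept and its enclosed holes are filled.
#'
#' @param frame A [sinter_frame()].
#' @param threshold Grey-level threshold in [0, 255]; a single value is used
#'   for a whole sequence under constant lighting. The default `NULL` invokes
#'   an automatic midpoint-between-modes fallback (see Details).
#' @param polarity `"dark_object"` (foreground where grey <= threshold) or
#'   `"bright_object"` (grey >= threshold).
#' @details The automatic fallback sets the threshold halfway between the
#'   means of the pixels below and above the image's global mean, iterated to
#'   convergence (isodata rule). A fixed, visually chosen threshold remains
#'   the recommended workflow for real sequences.
#' @return An integer 0/1 matrix of class `"sinter_mask"`, with the applied
#'   threshold in attribute `"threshold"`.
#' @export
segment <- function(frame, threshold = NULL,
                    polarity = c("dark_object", "bright_object")) {
  stopifnot(inherits(frame, "sinter_frame"))
  polarity <- match.arg(polarity)
  px <- frame$pixels
  if (is.null(threshold)) threshold <- isodata_threshold(px)
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]", call. = FALSE)
  fg <- if (polarity == "dark_object") px <= threshold else px >= threshold
  if (!any(fg)) stop("empty foreground: no object at this threshold",
                     call. = FALSE)
  lab <- label_components8(fg * 1)
  counts <- tabulate(lab[lab > 0])
  mask <- (lab == which.max(counts)) * 1
  mask <- EBImage::fillHull(mask)
  structure(mask, class = c("sinter_mask", class(mask)),
            threshold = threshold, polarity = polarity)
}

isodata_threshold <- function(px) {
  t_old <- -Inf
  t_new <- mean(px)
  while (abs(t_new - t_old) > 0.5) {
    t_old <- t_new
    lo <- px[px <= t_old]
    hi <- px[px > t_old]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
  }
  t_new
}

# binary erosion by the 3x3 box with the image border treated as background
# (EBImage pads with foreground, so the mask is zero-padded first)
erode3 <- function(mask) {
  pad <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  er <- EBImage::erode(pad, EBImage::makeBrush(3L, "box"))
  er[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L), drop = FALSE]
}

#' Contour pixels of the silhouette by morphological erosion
#'
#' The contour is the set of foreground pixels removed by one binary erosion
#' with a 3 x 3 structuring element; pixels in the bottom
#' `base_rows_excluded` rows (the oven base in real acquisitions) are dropped
#' from the contour.
#'
#' @param mask A `"sinter_mask"` (or plain 0/1 matrix) with one object.
#' @param base_rows_excluded Number of bottom image rows excluded from the
#'   contour (default 0).
#' @return List of class `"sinter_contour_raw"` with elements `rows`, `cols`
#'   (contour pixel coordinates), `interior` (eroded mask) and `mask`.
#' @export
contour_pixels <- function(mask, base_rows_excluded = 0L) {
  m <- unclass(mask) * 1
  if (!any(m == 1)) stop("empty mask", call. = FALSE)
  interior <- erode3(m)
  if (!any(interior == 1))
    stop("object vanishes under 3x3 erosion (thinner than 3 px)",
         call. = FALSE)
  edge <- m - interior
  if (base_rows_excluded > 0L) {
    keep_max_row <- nrow(m) - as.integer(base_rows_excluded)
    if (keep_max_row < 1L) stop("base_rows_excluded covers the whole image",
                                call. = FALSE)
    edge[(keep_max_row + 1L):nrow(m), ] <- 0
  }
  idx <- which(edge == 1, arr.ind = TRUE)
  structure(list(rows = idx[, 1], cols = idx[, 2],
                 interior = interior, mask = m,
                 base_rows_excluded = as.integer(base_rows_excluded)),
            class = "sinter_contour_raw")
}

#' Centroid of a binary mask
#'
#' Mean (row, col) position of the foreground pixels, i.e. the centre of
#' gravity of the white object; may be fractional.
#'
#' @param mask A 0/1 matrix.
#' @return Numeric `c(row, col)`.
#' @export
mask_centroid <- function(mask) {
  m <- unclass(mask)
  idx <- which(m == 1, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask", call. = FALSE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

#' Maximum horizontal length of the silhouette
#'
#' For each image row, the horizontal extent of the object is measured from
#' its leftmost to its rightmost foreground pixel (gaps included). The
#' maximum over rows is `L_max`; ties are broken toward the row nearest the
#' centroid row, then toward the smaller row index.
#'
#' @param mask A 0/1 matrix.
#' @return List with `L_max` (pixels) and `row` (the row achieving it).
#' @export
max_horizontal_length <- function(mask) {
  m <- unclass(mask)
  rows_any <- which(rowSums(m == 1) > 0)
  if (!length(rows_any)) stop("empty mask", call. = FALSE)
  lens <- vapply(rows_any, function(r) {
    cc <- which(m[r, ] == 1)
    max(cc) - min(cc) + 1L
  }, integer(1))
  lmax <- max(lens)
  cand <- rows_any[lens == lmax]
  c_row <- mask_centroid(m)["row"]
  cand <- cand[order(abs(cand - c_row), cand)]
  list(L_max = as.integer(lmax), row = as.integer(cand[1]))
}

#' Center the contour and convert it to polar coordinates
#'
#' Places the origin at the abscissa of the mask centroid and the ordinate of
#' the row where the horizontal extent is maximal, flips y to point upward,
#' and attaches polar coordinates \eqn{r = \sqrt{x^2+y^2}},
#' \eqn{\varphi = \mathrm{atan2}(y, x) \in (-\pi, \pi]}.
#'
#' @param contour A [contour_pixels()] result (or a list with `rows`,
#'   `cols`).
#' @param centroid_col Column of the horizontal centre (fractional allowed).
#' @param row_of_L_max Row of the vertical centre.
#' @return A data frame of class `"sinter_contour"` with columns `x`, `y`,
#'   `r`, `phi`, and attributes `center` (image-coordinate origin) and
#'   `L_max` when available.
#' @export
center_polarize <- function(contour, centroid_col, row_of_L_max) {
  if (!length(contour$rows)) stop("empty contour", call. = FALSE)
  x <- contour$cols - centroid_col
  y <- row_of_L_max - contour$rows
  r <- sqrt(x^2 + y^2)
  phi <- atan2(y, x)
  structure(data.frame(x = x, y = y, r = r, phi = phi),
            class = c("sinter_contour", "data.frame"),
            center = c(row = unname(row_of_L_max), col = unname(centroid_col)))
}

#' Extract the centered polar contour of one frame
#'
#' Convenience wrapper running segmentation, erosion-based contour
#' extraction, centroid and maximum-length measurement, and polar conversion
#' on a single frame.
#'
#' @inheritParams segment
#' @inheritParams contour_pixels
#' @param roi Optional crop rectangle, see [crop_roi()].
#' @return A `"sinter_contour"` data frame with attributes `L_max`,
#'   `center`, `threshold`, and `time_s`.
#' @export
frame_contour <- function(frame, threshold = NULL,
                          polarity = c("dark_object", "bright_object"),
                          roi = NULL, base_rows_excluded = 0L) {
  frame <- crop_roi(frame, roi)
  mask <- segment(frame, threshold, polarity)
  ctr <- contour_pixels(mask, base_rows_excluded)
  cen <- mask_centroid(mask)
  lm <- max_horizontal_length(mask)
  out <- center_polarize(ctr, cen["col"], lm$row)
  attr(out, "L_max") <- lm$L_max
  attr(out, "threshold") <- attr(mask, "threshold")
  attr(out, "time_s") <- frame$time_s
  out
}
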