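#' Convert calibrated pixel intensity to population size
#'
#' The scanner platform's conversion from background-subtracted, calibrated
#' colony intensity `x` to population cell count:
#' `y = 2.128e-2 x^5 + 1.023 x^4 + 11.47 x^3 + 25.62 x^2`.
#' All coefficients are positive and the lowest power is 2, so the curve is
#' strictly increasing and convex on `x > 0` with `calibrate_counts(0) = 0`.
#' Both scales are treated as opaque but internally consistent units: the
#' intensity scale is whatever the acquisition calibration produced, and
#' the count scale is cells per colony as anchored by optical-density
#' reference measurements.
#'
#' @param x Background-subtracted intensity, `>= 0` (callers floor negative
#'   measurements at zero first).
#' @return Population size `y`, same length as `x`.
#' @examples
#' calibrate_counts(1)  # sum of the four coefficients
#' @export
calibrate_counts <- function(x) {
  if (any(is.na(x)) || any(x < 0))
    stop("intensity must be non-negative (floor measurements at 0 first)")
  2.128e-2 * x^5 + 1.023 * x^4 + 11.47 * x^3 + 25.62 * x^2
}

#' Numerically invert the intensity calibration
#'
#' Finds the intensity `x >= 0` with `calibrate_counts(x) = y`, by
#' monotone root bracketing. Used by the synthetic renderer to decide what
#' integrated intensity a colony of a given population must show.
#'
#' @param y Population size, `>= 0`.
#' @param tol Relative tolerance of the root.
#' @param x_max Upper end of the invertible intensity range the
#'   calibration was established on; populations above
#'   `calibrate_counts(x_max)` are outside it and raise an error.
#' @return Intensity `x`, same length as `y`.
#' @export
invert_calibration <- function(y, tol = 1e-12, x_max = 1e3) {
  if (any(is.na(y)) || any(y < 0)) stop("population must be non-negative")
  y_max <- calibrate_counts(x_max)
  if (any(y > y_max))
    stop(sprintf("population %.3g outside the invertible calibration range (max %.3g)",
                 max(y), y_max))
  vapply(y, function(yi) {
    if (yi == 0) return(0)
    upper <- max(1, (yi / 2.128e-2)^(1 / 5), yi^(1 / 2) / 5)
    stats::uniroot(function(x) calibrate_counts(x) - yi,
                   lower = 0, upper = upper * 2,
                   tol = tol * max(1, upper))$root
  }, numeric(1))
}

#' Grid geometry of a plate image
#'
#' @param row_centers,col_centers Pixel coordinates (1-based, row/column
#'   index) of colony centers along each axis.
#' @param pitch_row,pitch_col Center-to-center spacing in pixels.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(row_centers, col_centers, pitch_row, pitch_col) {
  structure(list(row_centers = row_centers, col_centers = col_centers,
                 pitch_row = pitch_row, pitch_col = pitch_col),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry %d x %d, pitch %.2f x %.2f px>\n",
              length(x$row_centers), length(x$col_centers),
              x$pitch_row, x$pitch_col))
  invisible(x)
}

#' Render a plate dataset as a synthetic image stack
#'
#' The inverse of the quantification pipeline: for each time point, every
#' colony is drawn as a radially symmetric (Gaussian) footprint whose
#' integrated background-subtracted intensity equals the numerically
#' inverted calibration of its population, on a uniform background.
#'
#' @param populations Matrix (positions x time points) of population
#'   counts, positions in row-major layout order, or the `$data` long
#'   data.frame of [simulate_plate()].
#' @param format Plate format of the array.
#' @param times Acquisition times (hours), one per frame.
#' @param pitch_px Grid pitch in pixels.
#' @param footprint_sigma_px Gaussian footprint scale.
#' @param footprint_radius_px Footprint truncation radius; the footprint is
#'   renormalized to integrate to exactly the target intensity.
#' @param background Uniform background level added to every pixel.
#' @param photon_sd Additive Gaussian pixel noise sd.
#' @param seed Integer seed for the noise.
#' @return A list of class `image_stack`: `frames` (list of numeric
#'   matrices), `times`, and the geometry actually rendered (`geometry`).
#' @export
render_image_stack <- function(populations, format, times,
                               pitch_px = 12, footprint_sigma_px = 1.3,
                               footprint_radius_px = 4,
                               background = 0.5, photon_sd = 0, seed = 1) {
  if (is.data.frame(populations)) {
    stopifnot(all(c("row", "col", "time_h", "count") %in% names(populations)))
    times <- sort(unique(populations$time_h))
    idx <- populations$row * format$cols + populations$col + 1L
    tix <- match(populations$time_h, times)
    populations <- {
      m <- matrix(0, format$rows * format$cols, length(times))
      m[cbind(idx, tix)] <- populations$count
      m
    }
  }
  n_pos <- format$rows * format$cols
  stopifnot(nrow(populations) == n_pos, ncol(populations) == length(times))
  if (footprint_radius_px > pitch_px / 2 - 1)
    stop("footprint radius must fit inside one grid cell (radius <= pitch/2 - 1)")
  H <- format$rows * pitch_px; W <- format$cols * pitch_px
  off <- seq(-footprint_radius_px, footprint_radius_px)
  stamp <- exp(-(outer(off^2, off^2, `+`)) / (2 * footprint_sigma_px^2))
  stamp <- stamp / sum(stamp)
  cr <- round((seq_len(format$rows) - 0.5) * pitch_px + 0.5)
  cc <- round((seq_len(format$cols) - 0.5) * pitch_px + 0.5)
  x <- matrix(invert_calibration(as.vector(populations)),
              n_pos, length(times))
  set.seed(seed)
  frames <- vector("list", length(times))
  for (f in seq_along(times)) {
    img <- matrix(background, H, W)
    xf <- x[, f]
    for (r in seq_len(format$rows)) for (c in seq_len(format$cols)) {
      i <- (r - 1L) * format$cols + c
      if (xf[i] <= 0) next
      rr <- cr[r] + off; cols_ <- cc[c] + off
      img[rr, cols_] <- img[rr, cols_] + xf[i] * stamp
    }
    if (photon_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, photon_sd), H, W)
    frames[[f]] <- img
  }
  structure(list(frames = frames, times = times,
                 geometry = grid_geometry(cr, cc, pitch_px, pitch_px)),
            class = "image_stack")
}

# 1-D profile peak positions: integer-phase comb matching followed by
# local centroid refinement and a linear (regular-grid) fit
profile_centers <- function(profile, n_cells, axis_name) {
  n_px <- length(profile)
  pitch <- n_px / n_cells
  p0 <- profile - min(profile)
  if (max(p0) <= 0 || stats::sd(profile) < 1e-12 * (mean(abs(profile)) + 1))
    stop("grid-detection failure: no intensity contrast along ", axis_name)
  # count peaks: local maxima of a lightly smoothed profile above 10% of
  # the contrast range (colony rows differ in brightness, so no fixed
  # half-max threshold works)
  kw <- max(3L, 2L * floor(pitch / 6) + 1L)
  ps <- stats::filter(p0, rep(1 / kw, kw), sides = 2)
  ps[is.na(ps)] <- 0
  is_peak <- c(FALSE, diff(sign(diff(ps))) < 0, FALSE) & ps > 0.1 * max(ps)
  n_peaks <- sum(is_peak)
  if (n_peaks < n_cells)
    stop(sprintf("grid-detection failure: %d peaks found along %s, %d cells expected",
                 n_peaks, axis_name, n_cells))
  phases <- seq(-pitch / 2, pitch / 2 - 0.25, by = 0.25)
  score <- vapply(phases, function(ph) {
    centers <- ph + (seq_len(n_cells) - 0.5) * pitch + 0.5
    y <- stats::approx(seq_len(n_px), p0, xout = centers, rule = 1)$y
    sum(y, na.rm = TRUE)
  }, numeric(1))
  ph <- phases[which.max(score)]
  centers <- ph + (seq_len(n_cells) - 0.5) * pitch + 0.5
  half <- max(2L, floor(pitch / 4))
  refined <- vapply(centers, function(ctr) {
    lo <- max(1L, min(n_px, floor(ctr - half)))
    hi <- max(1L, min(n_px, ceiling(ctr + half)))
    if (hi < lo) return(ctr)
    w <- p0[lo:hi]
    if (sum(w) <= 0) return(ctr)
    sum((lo:hi) * w) / sum(w)
  }, numeric(1))
  k <- seq_len(n_cells)
  fit <- stats::lm.fit(cbind(1, k), refined)
  list(centers = fit$coefficients[1] + fit$coefficients[2] * k,
       pitch = unname(fit$coefficients[2]))
}

#' Detect the colony grid on a plate image
#'
#' Row- and column-projection profiles of the frame are matched against a
#' regular comb with the format's pitch (the plate is rigidly held, so the
#' grid is regular up to translation), then each center is refined by a
#' local intensity centroid and a linear fit across the array. Detection is
#' deterministic; by convention it is run once on the final
#' (highest-contrast) frame and reused for the whole stack.
#'
#' @param frame Numeric matrix (one grayscale image).
#' @param format Plate format of the array in the image.
#' @return A [grid_geometry()].
#' @export
detect_grid <- function(frame, format) {
  rowp <- rowMeans(frame)
  colp <- colMeans(frame)
  r <- profile_centers(rowp, format$rows, "rows")
  c_ <- profile_centers(colp, format$cols, "cols")
  grid_geometry(r$centers, c_$centers, r$pitch, c_$pitch)
}

#' Measure background-subtracted colony intensities
#'
#' For every frame and grid cell, sums the pixel intensities inside the
#' cell's bounding box and subtracts a local background estimated as the
#' median pixel value of the box's border margin (width = pitch / 8,
#' minimum 1 px), floored at zero. Because the background is taken per box
#' from its own border, adding a constant to every pixel leaves all
#' measurements unchanged.
#'
#' @param stack An `image_stack` (list with `frames` and `times`).
#' @param grid A [grid_geometry()], e.g. from [detect_grid()] on the final
#'   frame.
#' @return Long data.frame: `row`, `col` (0-based), `time_h`, `raw`,
#'   `background`, `value` (background-subtracted summed intensity).
#' @export
measure_intensities <- function(stack, grid) {
  nr <- length(grid$row_centers); nc <- length(grid$col_centers)
  H <- nrow(stack$frames[[1]]); W <- ncol(stack$frames[[1]])
  half_r <- grid$pitch_row / 2; half_c <- grid$pitch_col / 2
  m_r <- max(1L, round(grid$pitch_row / 8))
  m_c <- max(1L, round(grid$pitch_col / 8))
  boxes <- vector("list", nr * nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r0 <- max(1L, ceiling(grid$row_centers[r] - half_r))
    r1 <- min(H, floor(grid$row_centers[r] + half_r - 1e-9))
    c0 <- max(1L, ceiling(grid$col_centers[c] - half_c))
    c1 <- min(W, floor(grid$col_centers[c] + half_c - 1e-9))
    boxes[[(r - 1L) * nc + c]] <- c(r0, r1, c0, c1)
  }
  out <- vector("list", length(stack$frames))
  for (f in seq_along(stack$frames)) {
    img <- stack$frames[[f]]
    raw <- numeric(nr * nc); bg <- numeric(nr * nc); val <- numeric(nr * nc)
    for (i in seq_along(boxes)) {
      b <- boxes[[i]]
      box <- img[b[1]:b[2], b[3]:b[4], drop = FALSE]
      nrb <- nrow(box); ncb <- ncol(box)
      inner_r <- (m_r + 1):(nrb - m_r); inner_c <- (m_c + 1):(ncb - m_c)
      border <- box
      border[inner_r, inner_c] <- NA
      bgi <- stats::median(border, na.rm = TRUE)
      raw[i] <- sum(box)
      bg[i] <- bgi
      val[i] <- max(0, raw[i] - bgi * nrb * ncb)
    }
    out[[f]] <- data.frame(
      row = rep(seq_len(nr) - 1L, each = nc),
      col = rep(seq_len(nc) - 1L, nr),
      time_h = stack$times[f], raw = raw, background = bg, value = val)
  }
  do.call(rbind, out)
}

#' Quantify an image stack into a population time-series table
#'
#' Convenience wrapper: grid detection on the final frame, intensity
#' measurement on every frame, calibration to cell counts.
#'
#' @param stack An `image_stack`.
#' @param format Plate format.
#' @return Long data.frame `row`, `col`, `time_h`, `count`.
#' @export
quantify_stack <- function(stack, format) {
  grid <- detect_grid(stack$frames[[length(stack$frames)]], format)
  meas <- measure_intensities(stack, grid)
  data.frame(row = meas$row, col = meas$col, time_h = meas$time_h,
             count = calibrate_counts(meas$value))
}

#' Write / read an image stack as multi-frame 16-bit grayscale TIFF
#'
#' Pixel values are stored normalized by `max_value` (default: the stack
#' maximum, written to a `<path>.scale` sidecar so reading restores the
#' original scale). Quantization to 16 bits limits file round-trip
#' fidelity to ~1.5e-5 of full scale.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @param max_value Normalization constant (pixel value mapped to 1.0).
#' @return `write_image_stack` returns `path` invisibly;
#'   `read_image_stack` returns an `image_stack`.
#' @export
write_image_stack <- function(stack, path, max_value = NULL) {
  if (is.null(max_value))
    max_value <- max(vapply(stack$frames, max, numeric(1)))
  frames <- lapply(stack$frames,
                   function(f) pmin(pmax(f / max_value, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  utils::write.table(
    data.frame(max_value = max_value, times = paste(stack$times, collapse = ",")),
    paste0(path, ".scale"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".scale")
  max_value <- 1; times <- seq_along(frames)
  if (file.exists(sidecar)) {
    sc <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    max_value <- sc$max_value[1]
    times <- as.numeric(strsplit(sc$times[1], ",")[[1]])
  }
  structure(list(frames = lapply(frames, function(f) f * max_value),
                 times = times, geometry = NULL),
            class = "image_stack")
}
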