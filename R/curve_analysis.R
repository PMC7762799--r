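#' Configuration of the curve-analysis pipeline
#'
#' All thresholds of smoothing, segmentation and QC in one place, echoed
#' into output tables so analyses are self-describing.
#'
#' @param window Smoothing window (odd point count).
#' @param degree Local polynomial degree.
#' @param floor_count Counts below this are floored before log2 (avoids
#'   `-Inf` while preserving a non-growing shape).
#' @param d_lo,d_hi Flat-phase bounds on the per-sampling-interval first
#'   derivative of the smoothed log2 curve (the classic `-0.02 < d < 0.02`
#'   rule; with 10-min sampling this is about 0.12 log2 units/h).
#' @param flat_min_len Minimum run length (points) of a flat phase.
#' @param flat_max_start_frac A flat phase must start within this leading
#'   fraction of the series to count as "initial".
#' @param flat_max_level_frac An initial flat phase must also sit near the
#'   curve's starting level: its level may exceed the first smoothed
#'   values by at most this fraction of the curve's total rise (plus a
#'   small absolute slack for non-growing curves). This keeps an early
#'   saturation plateau of a no-lag colony from posing as the lag phase.
#' @param linear_window Sliding-window length (points) of the linear-phase
#'   search.
#' @param merge_tol Windows whose slope is within this relative tolerance
#'   of the best window are merged into the linear segment.
#' @param min_slope Minimum slope (log2 units/h) for a linear phase to be
#'   reported; below it the curve is called non-growing.
#' @param deposition_floor_log2 Initial smoothed log2 level below which a
#'   position is flagged as mispinned (failed deposition).
#' @param max_drop_log2 Maximum tolerated single-step drop in the smoothed
#'   log2 curve; larger artifacts reject the curve.
#' @param wide_window Escalation window for noisy curves: after smoothing
#'   at `window`, if the residual noise sd exceeds `noise_sd_threshold`
#'   the curve is re-smoothed at this window so the derivative stays
#'   quiet relative to the flat-phase band. Set equal to `window` to
#'   disable the escalation.
#' @param noise_sd_threshold Residual log2 sd above which the wide window
#'   is used.
#' @return A named list of class `curve_config`.
#' @export
curve_config <- function(window = 9, degree = 2, floor_count = 1,
                         d_lo = -0.02, d_hi = 0.02, flat_min_len = 3,
                         flat_max_start_frac = 0.25,
                         flat_max_level_frac = 0.25,
                         linear_window = 5, merge_tol = 0.2,
                         min_slope = 0.05,
                         deposition_floor_log2 = 9, max_drop_log2 = 1,
                         wide_window = 21, noise_sd_threshold = 0.05) {
  stopifnot(window %% 2 == 1, window >= degree + 2, d_lo < d_hi,
            flat_min_len >= 1, linear_window >= 2, min_slope >= 0,
            wide_window %% 2 == 1, wide_window >= window)
  structure(list(window = window, degree = degree, floor_count = floor_count,
                 d_lo = d_lo, d_hi = d_hi, flat_min_len = flat_min_len,
                 flat_max_start_frac = flat_max_start_frac,
                 flat_max_level_frac = flat_max_level_frac,
                 linear_window = linear_window, merge_tol = merge_tol,
                 min_slope = min_slope,
                 deposition_floor_log2 = deposition_floor_log2,
                 max_drop_log2 = max_drop_log2,
                 wide_window = wide_window,
                 noise_sd_threshold = noise_sd_threshold),
            class = "curve_config")
}

#' Write / read a curve-analysis config as YAML
#'
#' @param config A [curve_config()].
#' @param path File path.
#' @export
write_curve_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_curve_config
#' @export
read_curve_config <- function(path) {
  do.call(curve_config, yaml::read_yaml(path))
}

tricube <- function(u) ifelse(abs(u) < 1, (1 - abs(u)^3)^3, 0)

check_timeseries <- function(times, values) {
  if (length(times) < 10) stop("time series too short (need >= 10 points)")
  dt <- diff(times)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9)
    stop("times must be strictly increasing and uniform")
  if (any(values < 0)) stop("counts must be non-negative")
  dt[1]
}

#' Smooth a growth curve on the log2 scale
#'
#' Locally weighted polynomial smoothing: at each point, a polynomial of
#' the given degree is fit to the log2-transformed counts over a window
#' centered there, with tricube distance weights; the fitted value at the
#' center is the smoothed value. Endpoints use truncated (asymmetric)
#' windows. The per-interval first derivative `d[i] = s[i+1] - s[i]` is
#' recomputed from the smoothed values only; it is what the flat-phase
#' thresholds apply to.
#'
#' Noisy curves (residual log2 sd above `noise_sd_threshold` after the
#' first pass) are re-smoothed at `wide_window`, so that the derivative
#' noise stays small relative to the fixed flat-phase band; clean curves
#' keep the short window, which resolves short lags better.
#'
#' @param ts Data.frame with `time_h` and `count` columns (uniform grid).
#' @param config A [curve_config()].
#' @return A list of class `smoothed_curve`: `times`, `s` (smoothed log2
#'   values), `d` (forward differences of `s`, one fewer point), `dt_h`,
#'   `window` (the window actually used).
#' @export
smooth_curve <- function(ts, config = curve_config()) {
  times <- ts$time_h; values <- ts$count
  dt <- check_timeseries(times, values)
  y <- log2(pmax(values, config$floor_count))
  s1 <- smooth_log2(y, config$window, config$degree)
  used <- config$window
  if (config$wide_window > config$window &&
      stats::sd(y - s1) > config$noise_sd_threshold) {
    s1 <- smooth_log2(y, min(config$wide_window, 2 * (length(y) %/% 2) - 1),
                      config$degree)
    used <- config$wide_window
  }
  structure(list(times = times, s = s1, d = diff(s1), dt_h = dt,
                 window = used),
            class = "smoothed_curve")
}

# one pass of tricube-weighted local polynomial smoothing on log2 values
smooth_log2 <- function(y, w, deg) {
  n <- length(y)
  h <- (w - 1L) %/% 2L
  off <- -h:h
  wt <- tricube(off / (h + 1))
  X <- outer(off, 0:deg, `^`)
  # interior points: one shared convolution kernel (weighted LSQ at center)
  A <- t(X * wt) %*% X
  kern <- as.numeric(solve(A, t(X * wt))[1, ])
  s <- numeric(n)
  if (n >= w) {
    interior <- (h + 1):(n - h)
    sf <- stats::filter(y, rev(kern), sides = 2)
    s[interior] <- sf[interior]
  } else {
    interior <- integer(0)
  }
  edge <- setdiff(seq_len(n), interior)
  for (i in edge) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    oi <- (lo:hi) - i
    wi <- tricube(oi / (h + 1))
    Xi <- outer(oi, 0:min(deg, hi - lo), `^`)
    fit <- stats::lm.wfit(Xi, y[lo:hi], wi)
    s[i] <- fit$coefficients[1]
  }
  s
}

# maximal runs of TRUE in a logical vector: data.frame(start, end) inclusive
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Find the initial flat phase of a smoothed curve
#'
#' The flat phase is the earliest maximal run of at least `flat_min_len`
#' consecutive points whose per-interval derivative lies strictly inside
#' `(d_lo, d_hi)`, starting within the first quarter of the series (it must
#' be the *initial* phase, not a later plateau).
#'
#' @param curve A [smooth_curve()] result.
#' @param config A [curve_config()].
#' @return `NULL` if no qualifying run exists, else a list with `start`,
#'   `end` (half-open point indices, 1-based), and `level` (mean smoothed
#'   log2 value over the segment).
#' @export
find_flat_phase <- function(curve, config = curve_config()) {
  d <- curve$d
  n <- length(curve$s)
  ok <- d > config$d_lo & d < config$d_hi
  if (!any(ok)) return(NULL)
  rr <- runs_of(ok)
  max_start <- max(1L, floor(n * config$flat_max_start_frac))
  rr <- rr[rr$end - rr$start + 1L >= config$flat_min_len &
           rr$start <= max_start, , drop = FALSE]
  if (nrow(rr) == 0) return(NULL)
  s1 <- mean(curve$s[seq_len(min(config$flat_min_len, n))])
  level_cap <- s1 + max(config$flat_max_level_frac * (max(curve$s) - s1),
                        0.2)
  for (j in seq_len(nrow(rr))) {  # earliest run at the starting level
    seg <- rr[j, ]
    start <- seg$start; end <- seg$end + 2L  # d-run i..j covers pts i..j+1
    level <- mean(curve$s[start:(end - 1L)])
    if (level <= level_cap)
      return(list(start = start, end = end, level = level))
  }
  NULL
}

#' Find the linear (exponential) phase
#'
#' Searches the region after the flat phase (or the whole curve when no
#' flat phase exists) with fixed-length sliding windows, fitting a least-
#' squares line on (time, smoothed log2) in each. The window with the
#' largest total increase (slope x span; with equal spans, the largest
#' slope, earliest on ties) seeds the segment; adjacent windows whose
#' slopes are within `merge_tol` of the best are merged, and the line is
#' refit over the merged segment.
#'
#' @param curve A [smooth_curve()] result.
#' @param after Flat-phase segment (from [find_flat_phase()]) or `NULL`.
#' @param config A [curve_config()].
#' @return `NULL` when the best slope does not exceed `min_slope`, else a
#'   list with `start`, `end` (half-open point indices), `slope` (log2
#'   units/h) and `intercept` (log2 units at t = 0) of the refit line.
#' @export
find_linear_phase <- function(curve, after = NULL,
                              config = curve_config()) {
  n <- length(curve$s)
  a0 <- if (is.null(after)) 1L else after$end
  w <- config$linear_window
  if (n - a0 + 1L < w) return(NULL)
  s <- curve$s[a0:n]; t <- curve$times[a0:n]
  m <- length(s) - w + 1L
  # slope of the LSQ line in each window (uniform grid: closed form)
  off <- 0:(w - 1L)
  cw <- (off - mean(off))
  denom <- sum(cw^2) * curve$dt_h
  M <- stats::embed(s, w)[, w:1, drop = FALSE]  # row i = s[i..i+w-1]
  slopes <- as.numeric(M %*% cw) / denom
  best <- which.max(slopes)  # earliest on ties
  if (slopes[best] <= config$min_slope) return(NULL)
  thr <- (1 - config$merge_tol) * slopes[best]
  lo <- best; while (lo > 1L && slopes[lo - 1L] >= thr) lo <- lo - 1L
  hi <- best; while (hi < m && slopes[hi + 1L] >= thr) hi <- hi + 1L
  i0 <- lo; i1 <- hi + w - 1L
  fit <- stats::lm.fit(cbind(1, t[i0:i1]), s[i0:i1])
  list(start = a0 + i0 - 1L, end = a0 + i1, # half-open in curve indices
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]))
}

#' Quality-control a growth curve
#'
#' @param ts Data.frame with `time_h` and `count`.
#' @param config A [curve_config()].
#' @param curve Optionally the precomputed [smooth_curve()] of `ts`.
#' @return `"pass"`, `"mispinned"` (initial smoothed population below the
#'   deposition floor: failed pinning) or `"rejected"` (non-monotone
#'   artifact: the smoothed log2 curve falls more than `max_drop_log2`
#'   below its running maximum; smoothing spreads a sharp raw drop over
#'   the window, so the drawdown, not a single step, is bounded).
#' @export
qc_curve <- function(ts, config = curve_config(), curve = NULL) {
  if (is.null(curve)) curve <- smooth_curve(ts, config)
  if (mean(curve$s[1:3]) < config$deposition_floor_log2) return("mispinned")
  if (max(cummax(curve$s) - curve$s) > config$max_drop_log2)
    return("rejected")
  "pass"
}

#' Extract lag time and growth rate from one growth curve
#'
#' The lag is the time where the linear-phase regression line crosses the
#' flat-phase level: `lag = (flat_level - intercept) / slope`, defined when
#' the linear phase starts after the initial flat phase ends and the
#' crossing falls between the flat-phase start and the linear-phase end.
#' A curve with a linear phase but no initial flat phase grows from the
#' first observation ("no detectable lag"): `lag_flag = "no_lag"`,
#' `lag_h = 0`. A curve with no linear phase is non-growing:
#' `lag_flag = "no_growth"`, `lag_h = NA` (downstream censoring applies).
#'
#' @param ts Data.frame with `time_h` and `count`.
#' @param config A [curve_config()].
#' @return One-row data.frame: `lag_h`, `lag_flag`
#'   (`measured`/`no_lag`/`no_growth`), `rate`, `qc`.
#' @export
extract_features <- function(ts, config = curve_config()) {
  curve <- smooth_curve(ts, config)
  qc <- qc_curve(ts, config, curve)
  out <- data.frame(lag_h = NA_real_, lag_flag = NA_character_,
                    rate = NA_real_, qc = qc, stringsAsFactors = FALSE)
  if (qc != "pass") return(out)
  flat <- find_flat_phase(curve, config)
  lin <- find_linear_phase(curve, flat, config)
  if (is.null(lin)) {
    out$lag_flag <- "no_growth"
    return(out)
  }
  out$rate <- lin$slope
  if (is.null(flat)) {
    out$lag_flag <- "no_lag"; out$lag_h <- 0
    return(out)
  }
  t_star <- (flat$level - lin$intercept) / lin$slope
  t_lo <- curve$times[flat$start]
  t_hi <- curve$times[lin$end - 1L]
  if (t_star < t_lo) {
    # crossing before the observed flat phase: indistinguishable from
    # growth from the first observation
    out$lag_flag <- "no_lag"; out$lag_h <- 0
  } else if (t_star > t_hi) {
    out$lag_flag <- "no_growth"; out$lag_h <- NA_real_; out$rate <- NA_real_
  } else {
    out$lag_flag <- "measured"; out$lag_h <- t_star
  }
  out
}

#' Extract features for every position of a long time-series table
#'
#' @param data Long data.frame with `row`, `col`, `time_h`, `count` and
#'   optionally `plate`.
#' @param config A [curve_config()].
#' @return Features table: one row per (plate, row, col) with `lag_h`,
#'   `lag_flag`, `rate`, `qc`.
#' @export
extract_features_table <- function(data, config = curve_config()) {
  if (!"plate" %in% names(data)) data$plate <- "plate1"
  key <- interaction(data$plate, data$row, data$col, drop = TRUE)
  parts <- lapply(split(data, key), function(d) {
    d <- d[order(d$time_h), ]
    cbind(plate = d$plate[1], row = d$row[1], col = d$col[1],
          extract_features(d[, c("time_h", "count")], config))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$plate, out$row, out$col), ]
}

#' Write a features table with its configuration header
#'
#' The config is echoed as `# key: value` comment lines above the header,
#' so downstream files are self-describing.
#'
#' @param features Features table from [extract_features_table()].
#' @param path Output path.
#' @param config The [curve_config()] used.
#' @export
write_features <- function(features, path, config = curve_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(config))
    writeLines(sprintf("# %s: %s", k, format(config[[k]])), con)
  utils::write.table(features, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
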