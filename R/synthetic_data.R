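#' Growth-curve model parameters
#'
#' The canonical colony growth model on a doubly selective mating plate is
#' piecewise linear on the log2 population scale: flat at `log2(n0)` during
#' the lag (conjugation + resistance expression time), then linear with
#' slope `rate` (doublings per hour), then flat at `log2(capacity)` once the
#' colony saturates.
#'
#' @param n0 Initial deposited population (cells), > 0.
#' @param lag_h Lag duration in hours, >= 0.
#' @param rate Exponential-phase slope in log2 units (doublings) per hour,
#'   > 0.
#' @param capacity Saturation population (cells), >= `n0`.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(n0 = 2e4, lag_h = 5.46, rate = 1.5,
                          capacity = 2e6) {
  stopifnot(n0 > 0, capacity >= n0, lag_h >= 0, rate > 0)
  structure(list(n0 = n0, lag_h = lag_h, rate = rate, capacity = capacity),
            class = "growth_params")
}

#' Measurement noise model
#'
#' @param sd_log2 Standard deviation of additive noise on the log2
#'   population scale, per time point.
#' @param baseline_sd Additive measurement noise on the raw count scale
#'   (scanner background fluctuation).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd_log2 = 0, baseline_sd = 0) {
  stopifnot(sd_log2 >= 0, baseline_sd >= 0)
  structure(list(sd_log2 = sd_log2, baseline_sd = baseline_sd),
            class = "noise_model")
}

#' Default acquisition time grid
#'
#' Scans every 10 minutes for 24 hours: 145 time points.
#'
#' @param total_h Total duration (hours).
#' @param dt_h Sampling interval (hours).
#' @return Numeric vector of times in hours.
#' @export
default_times <- function(total_h = 24, dt_h = 1 / 6) {
  seq(0, total_h, by = dt_h)
}

# log2 population at times t for one parameter set; optional C1 corner
# rounding replaces each slope break by a quadratic blend over `span_h`.
# ramp(t; t0) is max(0, t - t0) with the kink smoothed over t0 +/- span/2,
# so the trajectory is l0 + rate * (ramp at lag) - rate * (ramp at
# saturation), which rounds both corners at once.
log2_trajectory <- function(params, t, span_h = 0) {
  l0 <- log2(params$n0); lc <- log2(params$capacity)
  if (span_h <= 0 || lc <= l0)
    return(pmin(lc, l0 + params$rate * pmax(0, t - params$lag_h)))
  ramp <- function(t, t0, h) {
    y <- pmax(0, t - t0)
    inside <- abs(t - t0) < h / 2
    y[inside] <- (t[inside] - t0 + h / 2)^2 / (2 * h)
    y
  }
  t_sat <- params$lag_h + (lc - l0) / params$rate
  l0 + params$rate * (ramp(t, params$lag_h, span_h) - ramp(t, t_sat, span_h))
}

#' Simulate one colony growth curve
#'
#' Generates a population time series from the piecewise-linear log2 growth
#' model plus measurement noise. With `smooth_span_h > 0` the two slope
#' breaks (lag end, saturation) are rounded into C1 quadratic blends over
#' that span, to probe segmentation robustness against less idealized
#' curves.
#'
#' @param params A [growth_params()] object.
#' @param times Uniform time grid in hours.
#' @param noise A [noise_model()].
#' @param seed Integer seed; identical seeds give identical curves.
#' @param smooth_span_h Corner-rounding span (hours); 0 keeps sharp breaks.
#' @return A data.frame with columns `time_h` and `count`.
#' @examples
#' ts <- simulate_curve(growth_params(lag_h = 5), seed = 1)
#' head(ts)
#' @export
simulate_curve <- function(params, times = default_times(),
                           noise = noise_model(), seed = NULL,
                           smooth_span_h = 0) {
  stopifnot(inherits(params, "growth_params"))
  dt <- diff(times)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9)
    stop("`times` must be strictly increasing and uniform")
  if (!is.null(seed)) set.seed(seed)
  l <- log2_trajectory(params, times, smooth_span_h)
  if (noise$sd_log2 > 0)
    l <- l + stats::rnorm(length(l), 0, noise$sd_log2)
  count <- 2^l
  if (noise$baseline_sd > 0)
    count <- count + stats::rnorm(length(l), 0, noise$baseline_sd)
  data.frame(time_h = times, count = pmax(0, count))
}

#' Smooth multiplicative spatial field over a plate
#'
#' Emulates the small, smooth position effects (illumination, temperature,
#' agar thickness) seen across a plate: a random low-order polynomial
#' surface over `(row, col)`, rescaled to mean 1 and the requested
#' coefficient of variation. The same field applies to controls and
#' experimental matings at the same position, which is what the
#' interleaved-control normalization exploits.
#'
#' @param format A [plate_format()].
#' @param cv_lag,cv_rate Coefficients of variation of the multiplicative
#'   factor on lag and on growth rate (0 disables that field).
#' @param degree Polynomial surface order.
#' @param seed Integer seed.
#' @return A list of class `spatial_field` with matrices `lag_factor` and
#'   `rate_factor` (rows x cols, all factors > 0).
#' @export
spatial_field <- function(format, cv_lag = 0.09, cv_rate = 0,
                          degree = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  surface <- function(cv) {
    if (cv <= 0)
      return(matrix(1, format$rows, format$cols))
    u <- if (format$rows > 1)
      seq(-1, 1, length.out = format$rows) else 0
    v <- if (format$cols > 1)
      seq(-1, 1, length.out = format$cols) else 0
    f <- matrix(0, format$rows, format$cols)
    for (i in 0:degree) for (j in 0:degree) {
      if (i + j == 0 || i + j > degree) next
      f <- f + stats::rnorm(1) * outer(u^i, v^j)
    }
    if (stats::sd(f) == 0) f[] <- stats::rnorm(length(f)) # degenerate draw
    f <- (f - mean(f)) / stats::sd(f)
    fac <- 1 + cv * f
    # a smooth field with small cv stays positive; guard pathological draws
    pmax(fac, 0.05)
  }
  structure(list(lag_factor = surface(cv_lag), rate_factor = surface(cv_rate)),
            class = "spatial_field")
}

flat_field <- function(format) {
  structure(list(lag_factor = matrix(1, format$rows, format$cols),
                 rate_factor = matrix(1, format$rows, format$cols)),
            class = "spatial_field")
}

#' Screen ground truth
#'
#' @param strain Character vector of strain identifiers.
#' @param effect True log2 lag effect of each strain relative to the
#'   control (a strain with effect +1 lags twice as long as the local
#'   control).
#' @param non_grower Logical; strains whose matings never grow (no finite
#'   lag; censored downstream).
#' @return A data.frame of class `screen_truth`.
#' @export
screen_truth <- function(strain, effect = 0, non_grower = FALSE) {
  df <- data.frame(strain = as.character(strain),
                   effect = rep_len(effect, length(strain)),
                   non_grower = rep_len(non_grower, length(strain)),
                   stringsAsFactors = FALSE)
  class(df) <- c("screen_truth", "data.frame")
  df
}

# per-position growth parameters implied by layout + truth + field
position_params <- function(layout, truth, base, field,
                            mispin_n0 = 10, dt_h = 1 / 6) {
  p <- layout$positions
  m <- match(p$strain, truth$strain)
  eff <- truth$effect[m]
  nong <- truth$non_grower[m]
  fidx <- cbind(p$row + 1L, p$col + 1L)
  lagf <- field$lag_factor[fidx]
  ratef <- field$rate_factor[fidx]

  lag <- rep(NA_real_, nrow(p))
  grows <- rep(FALSE, nrow(p))
  n0 <- rep(base$n0, nrow(p))
  is_exp <- p$role == "experimental_mating"
  is_ctl <- p$role == "control_mating"
  is_pos <- p$role == "positive_control"
  if (any(is_exp & is.na(m)))
    stop("strain missing from truth table: ",
         paste(unique(p$strain[is_exp & is.na(m)])[1:3], collapse = ", "))
  lag[is_exp] <- base$lag_h * 2^eff[is_exp] * lagf[is_exp]
  grows[is_exp] <- !nong[is_exp]
  lag[is_ctl] <- base$lag_h * lagf[is_ctl]
  grows[is_ctl] <- TRUE
  lag[is_pos] <- 0
  grows[is_pos] <- TRUE
  n0[p$role == "empty"] <- 0
  data.frame(row = p$row, col = p$col, role = p$role, strain = p$strain,
             replicate = p$replicate, true_lag_h = lag, grows = grows,
             n0 = n0, rate = base$rate * ratef, stringsAsFactors = FALSE)
}

#' Simulate a whole plate of growth curves
#'
#' Composes [simulate_curve()] over a layout: experimental lag is
#' `base$lag_h * 2^effect * field`, control lag is `base$lag_h * field`,
#' donor-only / recipient-only positions and non-grower strains give
#' constant (non-growing) curves, and mispinned positions carry an initial
#' population below the deposition-detectability floor.
#'
#' @param layout A `plate_layout`.
#' @param truth A [screen_truth()] covering every experimental strain.
#' @param base Baseline [growth_params()] of the control mating.
#' @param field A [spatial_field()] or `NULL` for a flat plate.
#' @param noise A [noise_model()].
#' @param fraction_mispinned Fraction of non-empty positions whose
#'   deposition failed (near-zero signal).
#' @param times Acquisition grid (hours).
#' @param seed Integer seed; fully determines the dataset.
#' @param mispin_n0 Residual cell count at a mispinned position.
#' @param smooth_span_h Corner rounding passed to the growth model.
#' @return A list with `data` (long data.frame: `row`, `col`, `time_h`,
#'   `count`), `positions` (per-position truth: role, strain, replicate,
#'   `true_lag_h`, `grows`, `mispinned`) and `truth` (the strain-level
#'   table, echoed).
#' @export
simulate_plate <- function(layout, truth, base = growth_params(),
                           field = NULL, noise = noise_model(),
                           fraction_mispinned = 0,
                           times = default_times(), seed = 1,
                           mispin_n0 = 10, smooth_span_h = 0) {
  if (is.null(field)) field <- flat_field(layout$format)
  set.seed(seed)
  pp <- position_params(layout, truth, base, field, mispin_n0)
  n <- nrow(pp); nt <- length(times)
  mis <- rep(FALSE, n)
  eligible <- pp$role != "empty"
  if (fraction_mispinned > 0)
    mis[eligible] <- stats::runif(sum(eligible)) < fraction_mispinned
  pp$mispinned <- mis
  n0 <- ifelse(mis, mispin_n0, pp$n0)

  l0 <- log2(pmax(n0, .Machine$double.xmin))
  lcap <- log2(base$capacity)
  tm <- matrix(times, n, nt, byrow = TRUE)
  lagm <- matrix(ifelse(pp$grows & !mis, pp$true_lag_h, Inf), n, nt)
  ratem <- matrix(pp$rate, n, nt)
  growth <- ratem * pmax(tm - lagm, 0)
  growth[!is.finite(growth)] <- 0
  l <- pmin(l0 + growth, lcap)  # matrix first: pmin keeps its dimensions
  if (smooth_span_h > 0) {
    for (i in which(pp$grows & !mis)) {
      par_i <- growth_params(n0 = n0[i], lag_h = pp$true_lag_h[i],
                             rate = pp$rate[i], capacity = base$capacity)
      l[i, ] <- log2_trajectory(par_i, times, smooth_span_h)
    }
  }
  if (noise$sd_log2 > 0)
    l <- l + matrix(stats::rnorm(n * nt, 0, noise$sd_log2), n, nt)
  counts <- 2^l
  counts[n0 == 0, ] <- 0
  if (noise$baseline_sd > 0)
    counts <- counts + matrix(stats::rnorm(n * nt, 0, noise$baseline_sd),
                              n, nt)
  counts <- pmax(counts, 0)  # matrix first: pmax keeps its dimensions
  data <- data.frame(
    row = rep(pp$row, each = nt), col = rep(pp$col, each = nt),
    time_h = rep(times, n), count = as.vector(t(counts)))
  list(data = data, positions = pp, truth = truth)
}

# choose the per-plate replicate count of a screen design: the largest
# divisor of n_replicates not exceeding 6 (n = 8 -> 4 reps x 2 plates,
# n = 18 -> 6 reps x 3 plates)
replicates_per_plate <- function(n_replicates) {
  divs <- which(n_replicates %% seq_len(min(6, n_replicates)) == 0)
  max(divs)
}

#' Simulate a full multi-plate screen
#'
#' Builds the interleaved-control layouts for a deletion-library screen
#' (strains grouped into 96-well source plates, two source plates per
#' target plate at `reps_per_plate` replicates, target plates copied until
#' `n_replicates` is reached), then simulates every plate. With
#' `level = "lag"` the per-replicate lag times are generated directly on
#' the log2 scale (lag = base lag x 2^effect x field x 2^noise), skipping
#' curve synthesis; with `level = "curve"` full growth curves are produced
#' for the image/curve pipeline.
#'
#' @param n_strains Number of library strains.
#' @param n_replicates Total replicates per strain (8 in the primary
#'   design: 4 per plate on two plates; 18 in the secondary: 6 on each of
#'   three plates).
#' @param effect Strain effects: a numeric vector of length `n_strains`, a
#'   single sd for a centred normal effect distribution, or a function
#'   `function(n)` drawing `n` effects.
#' @param fraction_non_growers Fraction of strains with no measurable
#'   growth in any replicate.
#' @param fraction_mispinned Fraction of positions with failed deposition.
#' @param base Baseline control [growth_params()].
#' @param field_cv_lag Spatial-field CV on lag, per plate (0 = flat).
#' @param noise_sd_log2 For `level = "lag"`, the sd of replicate lag noise
#'   on the log2 scale; for `level = "curve"`, the per-point curve noise sd.
#' @param level `"lag"` (fast, statistics-level) or `"curve"`.
#' @param reps_per_plate Replicates of a strain on one plate; default
#'   derived from `n_replicates` (largest divisor <= 6).
#' @param times Acquisition grid for `level = "curve"`.
#' @param seed Integer seed; fully determines layouts, truth and data.
#' @return A list with `plates` (per plate: `layout`, `field`, and `lags`
#'   data.frame or `curves` simulation), `truth` (strain-level
#'   [screen_truth()]) and `design` metadata.
#' @export
simulate_screen <- function(n_strains, n_replicates = 8, effect = 0.23,
                            fraction_non_growers = 0,
                            fraction_mispinned = 0,
                            base = growth_params(),
                            field_cv_lag = 0.09,
                            noise_sd_log2 = 0.05,
                            level = c("lag", "curve"),
                            reps_per_plate = NULL,
                            times = default_times(), seed = 1) {
  level <- match.arg(level)
  stopifnot(n_strains >= 1, n_replicates >= 1)
  set.seed(seed)
  strains <- sprintf("strain%04d", seq_len(n_strains))
  eff <- if (is.function(effect)) effect(n_strains)
         else if (length(effect) == n_strains) effect
         else if (length(effect) == 1) stats::rnorm(n_strains, 0, effect)
         else stop("`effect` must be length 1, length n_strains, or a function")
  nong <- stats::runif(n_strains) < fraction_non_growers
  truth <- screen_truth(strains, eff, nong)

  if (is.null(reps_per_plate)) reps_per_plate <- replicates_per_plate(n_replicates)
  if (n_replicates %% reps_per_plate != 0)
    stop("n_replicates must be a multiple of reps_per_plate")
  n_copies <- n_replicates %/% reps_per_plate
  plates_per_target <- max(1, 8 %/% reps_per_plate)
  src <- split(strains, (seq_len(n_strains) - 1) %/% 96)
  names(src) <- sprintf("K%d", seq_along(src))
  groups <- split(seq_along(src),
                  (seq_along(src) - 1) %/% plates_per_target)

  plates <- list(); plate_id <- 0L
  for (g in groups) for (copy in seq_len(n_copies)) {
    plate_id <- plate_id + 1L
    lay <- build_screen_layout(src[g], n_replicates_per_plate = reps_per_plate)
    lay$positions$replicate <- lay$positions$replicate +
      ifelse(is.na(lay$positions$replicate), 0L,
             (copy - 1L) * reps_per_plate)
    fld <- if (field_cv_lag > 0)
      spatial_field(lay$format, cv_lag = field_cv_lag,
                    seed = seed + 1000L + plate_id)
    else flat_field(lay$format)
    if (level == "lag") {
      lags <- simulate_plate_lags(lay, truth, base, fld,
                                  sd_log2 = noise_sd_log2,
                                  fraction_mispinned = fraction_mispinned,
                                  seed = seed + 2000L + plate_id)
      plates[[plate_id]] <- list(layout = lay, field = fld, lags = lags)
    } else {
      sim <- simulate_plate(lay, truth, base, fld,
                            noise = noise_model(sd_log2 = noise_sd_log2),
                            fraction_mispinned = fraction_mispinned,
                            times = times, seed = seed + 2000L + plate_id)
      plates[[plate_id]] <- list(layout = lay, field = fld, curves = sim)
    }
  }
  list(plates = plates, truth = truth,
       design = list(n_strains = n_strains, n_replicates = n_replicates,
                     reps_per_plate = reps_per_plate, n_plates = plate_id,
                     level = level, seed = seed))
}

#' Simulate per-position lag times directly
#'
#' The statistics-level fast path: generates each position's extracted lag
#' as `true lag x 2^noise` without synthesizing curves. Non-growing
#' positions get status `"no_growth"`, mispinned ones `"mispinned"`.
#'
#' @inheritParams simulate_plate
#' @param sd_log2 Replicate lag noise sd on the log2 scale.
#' @return A data.frame: `row`, `col`, `role`, `strain`, `replicate`,
#'   `lag_h`, `rate`, `status` (`ok`/`no_growth`/`mispinned`),
#'   `true_lag_h`.
#' @export
simulate_plate_lags <- function(layout, truth, base = growth_params(),
                                field = NULL, sd_log2 = 0.05,
                                fraction_mispinned = 0, seed = 1) {
  if (is.null(field)) field <- flat_field(layout$format)
  set.seed(seed)
  pp <- position_params(layout, truth, base, field)
  keep <- pp$role %in% c("experimental_mating", "control_mating",
                         "positive_control", "donor_only", "recipient_only")
  pp <- pp[keep, , drop = FALSE]
  n <- nrow(pp)
  mis <- if (fraction_mispinned > 0) stats::runif(n) < fraction_mispinned
         else rep(FALSE, n)
  lag <- pp$true_lag_h * 2^stats::rnorm(n, 0, sd_log2)
  status <- ifelse(mis, "mispinned", ifelse(pp$grows, "ok", "no_growth"))
  lag[status != "ok"] <- NA_real_
  data.frame(row = pp$row, col = pp$col, role = pp$role, strain = pp$strain,
             replicate = pp$replicate, lag_h = lag, rate = pp$rate,
             status = status, true_lag_h = pp$true_lag_h,
             stringsAsFactors = FALSE)
}

#' Write the long-format time-series table
#'
#' @param data Long data.frame (`row`, `col`, `time_h`, `count`), e.g. from
#'   [simulate_plate()].
#' @param path Output path; tab-separated with header.
#' @param plate Plate identifier recorded in the `plate` column.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(data, path, plate = "plate1") {
  out <- cbind(plate = plate, data)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("plate", "row", "col", "time_h")
  if (!all(need %in% names(df)))
    stop("time-series table must have columns: plate, row, col, time_h, ",
         "and a count (or value) column")
  if (!"count" %in% names(df)) {
    if ("value" %in% names(df)) df$count <- df$value
    else stop("no count/value column")
  }
  df
}
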