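#' Local control reference for one position
#'
#' The normalization reference of a position is the median lag of its `k`
#' nearest interleaved control matings (Euclidean grid distance, ties by
#' `(row, col)`), leaving the position itself out when it is a control.
#' With controls in every fourth position, the k = 4 default guarantees the
#' neighbourhood lies within the surrounding few rows and columns, so a
#' smooth spatial field is absorbed by the reference.
#'
#' @param layout A `plate_layout`.
#' @param control_lags Data.frame with `row`, `col`, `lag_h` for the
#'   plate's valid (QC-passing, finite-lag) control matings.
#' @param pos Length-2 `c(row, col)`, 0-based.
#' @param k Controls per neighbourhood.
#' @param stat Averaging statistic over the k neighbours.
#' @return Reference lag in hours.
#' @export
local_reference <- function(layout, control_lags, pos, k = 4,
                            stat = stats::median) {
  ok <- is.finite(control_lags$lag_h)
  control_lags <- control_lags[ok, , drop = FALSE]
  self <- control_lags$row == pos[1] & control_lags$col == pos[2]
  cand <- control_lags[!self, , drop = FALSE]
  if (nrow(cand) < k)
    stop(sprintf("only %d valid controls available; %d needed", nrow(cand), k))
  d <- sqrt((cand$row - pos[1])^2 + (cand$col - pos[2])^2)
  ord <- order(d, cand$row, cand$col)[seq_len(k)]
  stat(cand$lag_h[ord])
}

#' Normalized lag effect
#'
#' The per-replicate effect is the log2 ratio of the position's lag to its
#' local control reference. Positive effects mean a longer lag, i.e.
#' delayed conjugation.
#'
#' @param lag_h Lag time (hours), finite and positive.
#' @param reference Local reference lag (hours), positive.
#' @return `log2(lag_h / reference)`.
#' @export
normalize_effect <- function(lag_h, reference) {
  if (any(!is.finite(lag_h)) || any(lag_h <= 0) ||
      any(!is.finite(reference)) || any(reference <= 0))
    stop("lag and reference must be finite and positive")
  log2(lag_h / reference)
}

#' Censoring value for non-growing replicates
#'
#' Replicates with no measurable growth are assigned a normalized effect of
#' exactly 2, i.e. a lag at least four times the local control's. Measured
#' finite effects are never altered by this rule (effects above 2 from an
#' actual lag are reported as computed).
#'
#' @param effects Data.frame with at least `e` and `status` columns
#'   (`status == "no_growth"` marks the replicates to censor).
#' @return The data.frame with `e = 2` and `censored = TRUE` on censored
#'   rows.
#' @export
apply_censoring <- function(effects) {
  cens <- !is.na(effects$status) & effects$status == "no_growth"
  effects$e[cens] <- 2
  effects$censored <- cens
  effects
}

# fast row medians for small fixed k
row_median_k <- function(M) {
  k <- ncol(M)
  if (k == 1) return(M[, 1])
  if (k == 2) return((M[, 1] + M[, 2]) / 2)
  if (k == 4) {
    lo <- pmin(pmin(M[, 1], M[, 2]), pmin(M[, 3], M[, 4]))
    hi <- pmax(pmax(M[, 1], M[, 2]), pmax(M[, 3], M[, 4]))
    return((rowSums(M) - lo - hi) / 2)
  }
  apply(M, 1, stats::median)
}

#' Normalize a plate of replicate lags against interleaved controls
#'
#' For every mating position with a usable lag, computes the local
#' reference (median of the k nearest QC-passing controls, leave-self-out
#' for controls) and the log2 lag ratio; applies the censoring rule to
#' non-growing replicates; treats zero-lag (`no_lag`) matings as one
#' sampling interval (the minimum measurable lag) to keep the ratio
#' finite.
#'
#' @param lags Data.frame with `row`, `col`, `role`, `strain`, `replicate`,
#'   `lag_h` and `status` (`ok`/`no_growth`/`no_lag`/`mispinned`/
#'   `rejected`); [features_to_lags()] converts a curve-pipeline features
#'   table into this form.
#' @param layout The plate's `plate_layout`.
#' @param k Neighbourhood size.
#' @param min_lag_h Minimum measurable lag substituted for zero-lag
#'   replicates (default one 10-min sampling interval).
#' @return The input restricted to experimental and control matings, with
#'   `reference`, `e` (normalized log2 effect; `NA` when QC failed or no
#'   reference exists) and `censored` columns added.
#' @export
normalize_plate <- function(lags, layout, k = 4, min_lag_h = 1 / 6) {
  p <- layout$positions
  ctl_pos <- p[p$role == "control_mating", c("row", "col")]
  df <- lags[lags$role %in% c("experimental_mating", "control_mating"), ,
             drop = FALSE]
  # valid controls: QC pass and finite lag, in layout (row, col) order
  ctl_key <- paste(ctl_pos$row, ctl_pos$col)
  df_key <- paste(df$row, df$col)
  ctl_rows <- df[df$role == "control_mating", , drop = FALSE]
  m <- match(ctl_key, paste(ctl_rows$row, ctl_rows$col))
  ctl_lag <- ctl_rows$lag_h[m]
  ctl_ok <- !is.na(m) & ctl_rows$status[m] == "ok" & is.finite(ctl_lag) &
    ctl_lag > 0
  map <- control_neighbour_map(layout, k = k, valid = ctl_ok)
  pos_index <- match(df_key, paste(p$row, p$col))
  nb <- map$neighbour_index[pos_index, , drop = FALSE]
  lag_mat <- matrix(ctl_lag[nb], nrow = nrow(nb))
  reference <- row_median_k(lag_mat)
  df$reference <- reference
  lag_use <- df$lag_h
  no_lag <- !is.na(df$status) & df$status == "no_lag"
  lag_use[no_lag] <- min_lag_h
  usable <- df$status %in% c("ok", "no_lag") & is.finite(lag_use) &
    lag_use > 0 & is.finite(reference) & reference > 0
  df$e <- NA_real_
  df$e[usable] <- log2(lag_use[usable] / reference[usable])
  df <- apply_censoring(df)
  df$e[!(usable | df$censored)] <- NA_real_
  df
}

#' Convert a curve-pipeline features table to replicate lags
#'
#' Joins extracted features to the plate layout and recodes the
#' `lag_flag`/`qc` pair into the single `status` column that
#' [normalize_plate()] consumes.
#'
#' @param features Features table (`plate`, `row`, `col`, `lag_h`,
#'   `lag_flag`, `rate`, `qc`).
#' @param layout The `plate_layout` of those positions.
#' @return Replicate-lag data.frame.
#' @export
features_to_lags <- function(features, layout) {
  p <- layout$positions
  m <- match(paste(features$row, features$col), paste(p$row, p$col))
  if (any(is.na(m))) stop("features contain positions missing from layout")
  status <- ifelse(features$qc != "pass", features$qc,
            ifelse(features$lag_flag == "no_growth", "no_growth",
            ifelse(features$lag_flag == "no_lag", "no_lag", "ok")))
  data.frame(plate = if ("plate" %in% names(features)) features$plate else "plate1",
             row = features$row, col = features$col,
             role = p$role[m], strain = p$strain[m],
             replicate = p$replicate[m],
             lag_h = features$lag_h, rate = features$rate,
             status = status, stringsAsFactors = FALSE)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether paired effects are symmetrically distributed about `mu`.
#' Zeros are handled by Pratt's method (ranked with the rest, then dropped
#' from the statistic). The null distribution is exact (signed-rank
#' distribution) when there are no zeros or ties and n <= 25, exact by
#' sign-flip enumeration when zeros are present but the non-zero values
#' are untied and few, and a normal approximation with continuity, tie and
#' zero corrections otherwise.
#'
#' @param x Numeric vector.
#' @param mu Null center.
#' @param alternative `"two.sided"`, `"greater"` (shifted above `mu`) or
#'   `"less"`.
#' @param exact_max Largest n for the exact signed-rank path.
#' @return List with `statistic` (V, the positive-rank sum), `p.value`,
#'   `n` (non-missing values used) and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @export
wilcoxon_signed_rank <- function(x, mu = 0,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_max = 25) {
  alternative <- match.arg(alternative)
  d <- x[!is.na(x)] - mu
  n <- length(d)
  if (n == 0) return(list(statistic = NA_real_, p.value = NA_real_,
                          n = 0L, method = "none"))
  r <- rank(abs(d))           # Pratt: zeros ranked with the rest
  nz <- d != 0
  V <- sum(r[d > 0])
  if (!any(nz))               # all values at the null center
    return(list(statistic = V, p.value = 1, n = n, method = "degenerate"))
  has_ties <- anyDuplicated(abs(d[nz])) > 0
  n_zero <- sum(!nz)

  if (!has_ties && n_zero == 0 && n <= exact_max) {
    p <- switch(alternative,
      two.sided = min(1, 2 * min(stats::psignrank(V, n),
                                 stats::psignrank(V - 1, n, lower.tail = FALSE))),
      greater   = stats::psignrank(V - 1, n, lower.tail = FALSE),
      less      = stats::psignrank(V, n))
    return(list(statistic = V, p.value = p, n = n, method = "exact"))
  }
  if (!has_ties && n_zero > 0 && sum(nz) <= 16) {
    # exact by enumeration over sign assignments of the non-zero values,
    # with Pratt ranks (computed against the full sample including zeros)
    rz <- r[nz]
    m <- length(rz)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    Vs <- as.numeric(signs %*% rz)
    p_ge <- mean(Vs >= V); p_le <- mean(Vs <= V)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_ge, p_le)),
      greater = p_ge, less = p_le)
    return(list(statistic = V, p.value = p, n = n, method = "exact"))
  }
  # normal approximation with Pratt zero correction, tie correction and
  # continuity correction
  mu_V <- (n * (n + 1) / 4) - n_zero * (n_zero + 1) / 4
  ties <- table(r[nz])
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    n_zero * (n_zero + 1) * (2 * n_zero + 1) / 24 -
    sum(ties^3 - ties) / 48
  z_num <- V - mu_V
  cc <- 0.5
  p <- switch(alternative,
    two.sided = min(1, 2 * stats::pnorm((abs(z_num) - cc) / sqrt(sigma2),
                                        lower.tail = FALSE)),
    greater = stats::pnorm((z_num - cc) / sqrt(sigma2), lower.tail = FALSE),
    less = stats::pnorm((z_num + cc) / sqrt(sigma2)))
  list(statistic = V, p.value = p, n = n, method = "normal_approx")
}

#' Aggregate replicate effects per strain and test against zero
#'
#' For every strain: replicate count, median and SEM of the normalized
#' effects (censored replicates enter at their censored value 2), a
#' one-sample Wilcoxon signed-rank p-value against zero, Benjamini-
#' Hochberg FDR across strains, and the rank by decreasing median effect
#' (rank 1 = most delayed conjugation).
#'
#' @param effects Data.frame of normalized replicate effects with `strain`
#'   and `e` columns (e.g. [normalize_plate()] output over all plates),
#'   restricted to experimental matings by default.
#' @param min_n Minimum replicates for a p-value; strains under it are
#'   flagged (`p = NA`).
#' @param alternative Sidedness of the Wilcoxon test.
#' @param experimental_only Keep only `role == "experimental_mating"` rows
#'   when a `role` column is present.
#' @return Data.frame: `strain`, `n`, `median_e`, `sem_e`, `p`, `q`,
#'   `rank`, ordered by rank.
#' @export
aggregate_and_test <- function(effects, min_n = 3,
                               alternative = "two.sided",
                               experimental_only = TRUE) {
  if (experimental_only && "role" %in% names(effects))
    effects <- effects[effects$role == "experimental_mating", , drop = FALSE]
  effects <- effects[!is.na(effects$e) & !is.na(effects$strain), , drop = FALSE]
  groups <- split(effects$e, effects$strain)
  res <- data.frame(
    strain = names(groups),
    n = vapply(groups, length, integer(1)),
    median_e = vapply(groups, stats::median, numeric(1)),
    sem_e = vapply(groups, function(e)
      stats::sd(e) / sqrt(length(e)), numeric(1)),
    stringsAsFactors = FALSE)
  res$p <- vapply(groups, function(e) {
    if (length(e) < min_n) return(NA_real_)
    wilcoxon_signed_rank(e, alternative = alternative)$p.value
  }, numeric(1))
  res$q <- fdr_adjust(res$p)
  res$rank <- rank(-res$median_e, ties.method = "first")
  res <- res[order(res$rank), ]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q(i) = min_{j >= i} m p(j) / j` (monotone cumulative
#' minimum from the largest p down), as in `stats::p.adjust`.
#'
#' @param p P-values in `[0, 1]` (`NA` allowed, passed through).
#' @return Adjusted q-values, `q >= p` elementwise.
#' @export
fdr_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Gene-set over-representation among screen hits
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) of the 2x2
#' table hits x set membership over a common strain universe.
#'
#' @param hits Character vector of hit strains (subset of `universe`).
#' @param gene_set Character vector of set members (subset of `universe`).
#' @param universe Character vector of all tested strains.
#' @return List with `overlap`, `expected`, and one-sided `p.value` of
#'   seeing at least the observed overlap.
#' @export
enrichment <- function(hits, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  hits <- unique(hits); gene_set <- unique(gene_set)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  if (!all(gene_set %in% universe))
    stop("gene set members must be a subset of the universe")
  k <- length(intersect(hits, gene_set))
  p <- stats::phyper(k - 1, length(gene_set),
                     length(universe) - length(gene_set),
                     length(hits), lower.tail = FALSE)
  list(overlap = k,
       expected = length(hits) * length(gene_set) / length(universe),
       p.value = p)
}

#' Concordance between two screens
#'
#' Squared Pearson correlation of matched strain-level median effects
#' (e.g. primary vs secondary screen).
#'
#' @param primary,secondary Data.frames with `strain` and `median_e` (or a
#'   column named by `value`).
#' @param value Effect column name.
#' @return List with `r_squared`, `slope` (secondary on primary), `n`
#'   matched strains, and `flag` (`"ok"` or `"zero_variance"`).
#' @export
concordance <- function(primary, secondary, value = "median_e") {
  m <- merge(primary[, c("strain", value)], secondary[, c("strain", value)],
             by = "strain", suffixes = c("_1", "_2"))
  if (nrow(m) < 3) stop("need >= 3 matched strains")
  x <- m[[paste0(value, "_1")]]; y <- m[[paste0(value, "_2")]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r_squared = NA_real_, slope = NA_real_, n = nrow(m),
                flag = "zero_variance"))
  list(r_squared = stats::cor(x, y)^2,
       slope = unname(stats::coef(stats::lm(y ~ x))[2]),
       n = nrow(m), flag = "ok")
}

#' Growth-rate vs lag-effect confound check
#'
#' Tests whether apparent conjugation delays are explained by slow donor
#' growth: squared Pearson correlation between strains' relative growth
#' rates and relative lag effects (both log2 vs control). Independence
#' (R^2 near 0) argues against the growth confound.
#'
#' @param rate_effects,lag_effects Data.frames with `strain` and a `value`
#'   column (log2 relative rate / lag).
#' @param value Column name.
#' @return List with `r_squared`, `n`, `flag`, and the matched scatter
#'   `table` (strain, rate, lag).
#' @export
rate_lag_check <- function(rate_effects, lag_effects, value = "median_e") {
  m <- merge(rate_effects[, c("strain", value)],
             lag_effects[, c("strain", value)],
             by = "strain", suffixes = c("_rate", "_lag"))
  x <- m[[paste0(value, "_rate")]]; y <- m[[paste0(value, "_lag")]]
  tab <- data.frame(strain = m$strain, rate = x, lag = y)
  if (nrow(m) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r_squared = NA_real_, n = nrow(m), flag = "zero_variance",
                table = tab))
  list(r_squared = stats::cor(x, y)^2, n = nrow(m), flag = "ok", table = tab)
}

#' Screen-level distribution summary
#'
#' Mean and sd of the strain effects, coefficient of variation of the
#' control lags, and a quantile-quantile table of the observed effects
#' against a normal distribution with the same mean and sd.
#'
#' @param strain_effects Numeric vector of strain-level median effects.
#' @param control_lags Numeric vector of control lag times (hours).
#' @return List with `mu`, `sigma`, `cv` (sd/mean of control lags) and
#'   `qq` (data.frame `expected`, `observed`, both sorted).
#' @export
screen_summary <- function(strain_effects, control_lags = numeric(0)) {
  strain_effects <- strain_effects[!is.na(strain_effects)]
  if (length(strain_effects) < 10) stop("need >= 10 strain effects")
  mu <- mean(strain_effects); sigma <- stats::sd(strain_effects)
  cv <- if (length(control_lags) > 1)
    stats::sd(control_lags) / mean(control_lags) else NA_real_
  obs <- sort(strain_effects)
  expd <- stats::qnorm(stats::ppoints(length(obs)), mean = mu, sd = sigma)
  list(mu = mu, sigma = sigma, cv = cv,
       qq = data.frame(expected = expd, observed = obs))
}

#' Analyze a simulated or measured screen end to end
#'
#' Normalizes every plate against its interleaved controls, pools
#' replicate effects, and aggregates per strain with Wilcoxon + FDR.
#'
#' @param plates List of plates; each element a list with `layout` and
#'   either `lags` (replicate-lag data.frame) or `curves` (a
#'   [simulate_plate()] result whose curves are first run through the
#'   feature extractor).
#' @param k Control neighbourhood size.
#' @param config [curve_config()] for curve-level plates.
#' @param alternative Wilcoxon sidedness.
#' @return List with `replicates` (pooled normalized effects), `strains`
#'   (per-strain results) and `summary` (distribution summary incl.
#'   control-lag CV).
#' @export
analyze_screen <- function(plates, k = 4, config = curve_config(),
                           alternative = "two.sided") {
  norm <- vector("list", length(plates))
  for (i in seq_along(plates)) {
    pl <- plates[[i]]
    lags <- if (!is.null(pl$lags)) pl$lags else {
      feats <- extract_features_table(pl$curves$data, config)
      features_to_lags(feats, pl$layout)
    }
    nm <- normalize_plate(lags, pl$layout, k = k)
    nm$plate <- sprintf("plate%d", i)
    norm[[i]] <- nm
  }
  norm <- do.call(rbind, norm)
  strains <- aggregate_and_test(norm, alternative = alternative)
  ctl <- norm$role == "control_mating" & norm$status == "ok" &
    is.finite(norm$lag_h)
  summary <- if (nrow(strains) >= 10)
    screen_summary(strains$median_e, norm$lag_h[ctl]) else NULL
  list(replicates = norm, strains = strains, summary = summary)
}

#' Write per-strain screen results
#'
#' @param strains Strain results from [aggregate_and_test()].
#' @param path Output path (tab-separated).
#' @export
write_strain_results <- function(strains, path) {
  utils::write.table(strains, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
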