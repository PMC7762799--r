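#' Titer from serial-dilution spot counts
#'
#' Colony counts from 10-fold serial dilutions spotted in small volumes
#' are converted to CFU/ml. Technical replicate spots of the same dilution
#' are averaged first; the titer is then read from the most dilute dilution
#' whose mean count falls in the countable band (default 3-30 colonies per
#' 10-ul spot). When no dilution is countable, the dilution whose mean
#' count is closest to the band (log-scale distance) is used and the
#' estimate is flagged; all-zero counts give a zero titer, flagged.
#'
#' @param spots Data.frame with columns `dilution_exponent` (integer <= 0;
#'   the spotted dilution is `10^dilution_exponent`), `volume_ml` (plated
#'   volume per spot, default 0.010 ml), `colonies` (count), and
#'   optionally `tech_rep`.
#' @param band Countable range of mean colonies per spot.
#' @return List of class `titer_estimate`: `cfu_per_ml`,
#'   `dilution_exponent` used, `mean_colonies`, `flag`
#'   (`"ok"`, `"out_of_band"` or `"no_growth"`).
#' @examples
#' titer_from_spots(data.frame(dilution_exponent = -5, volume_ml = 0.01,
#'                             colonies = c(6, 8)))
#' @export
titer_from_spots <- function(spots, band = c(3, 30)) {
  stopifnot(nrow(spots) >= 1, all(spots$colonies >= 0),
            all(spots$volume_ml > 0))
  agg <- stats::aggregate(
    cbind(colonies = spots$colonies, volume_ml = spots$volume_ml),
    by = list(dilution_exponent = spots$dilution_exponent), FUN = mean)
  if (all(agg$colonies == 0))
    return(structure(list(cfu_per_ml = 0, dilution_exponent = NA_integer_,
                          mean_colonies = 0, flag = "no_growth"),
                     class = "titer_estimate"))
  in_band <- agg$colonies >= band[1] & agg$colonies <= band[2]
  if (any(in_band)) {
    use <- agg[in_band, ]
    use <- use[which.min(use$dilution_exponent), ]  # most dilute countable
    flag <- "ok"
  } else {
    pos <- agg[agg$colonies > 0, ]
    dist <- pmax(0, log10(band[1] / pos$colonies),
                 log10(pos$colonies / band[2]))
    use <- pos[order(dist, pos$dilution_exponent), ][1, ]
    flag <- "out_of_band"
  }
  structure(list(
    cfu_per_ml = use$colonies / (use$volume_ml * 10^use$dilution_exponent),
    dilution_exponent = use$dilution_exponent,
    mean_colonies = use$colonies, flag = flag), class = "titer_estimate")
}

#' Conjugation frequency: transconjugants per donor
#'
#' @param transconjugant,donor [titer_from_spots()] estimates (or raw
#'   CFU/ml numbers) from the transconjugant-selective and donor-selective
#'   plates of the same mating mixture.
#' @return Frequency (transconjugant CFU / donor CFU).
#' @export
conjugation_frequency <- function(transconjugant, donor) {
  tt <- if (inherits(transconjugant, "titer_estimate"))
    transconjugant$cfu_per_ml else transconjugant
  dd <- if (inherits(donor, "titer_estimate")) donor$cfu_per_ml else donor
  if (is.na(dd) || dd <= 0) stop("donor titer must be positive")
  tt / dd
}

#' Normalize a conjugation frequency to the same-day control matings
#'
#' @param frequency Mating frequency of one replicate.
#' @param control_frequencies Control-mating frequencies measured the same
#'   day (>= 1 value).
#' @param day Optional day label, used in the error message.
#' @return `frequency / mean(control_frequencies)`.
#' @export
normalize_day_control <- function(frequency, control_frequencies, day = NULL) {
  control_frequencies <- control_frequencies[!is.na(control_frequencies)]
  if (length(control_frequencies) == 0)
    stop("no same-day control mating", if (!is.null(day))
      paste0(" for day '", day, "'") else "")
  frequency / mean(control_frequencies)
}

#' One-sided test of mutant vs control conjugation ratios
#'
#' Welch two-sample t-test with alternative "mutant conjugates less than
#' control" (the screen's direction of effect). A pooled-variance Student
#' test is available via `var_equal = TRUE`.
#'
#' @param mutant,control Numeric vectors of normalized conjugation ratios,
#'   >= 2 values each.
#' @param var_equal Use the pooled-variance test.
#' @return List with `p.value`, `estimate` (mean difference mutant -
#'   control) and `flag` (`"ok"` or `"degenerate_variance"` when both
#'   groups are constant).
#' @export
test_vs_control <- function(mutant, control, var_equal = FALSE) {
  stopifnot(length(mutant) >= 2, length(control) >= 2)
  est <- mean(mutant) - mean(control)
  if (stats::sd(mutant) == 0 && stats::sd(control) == 0)
    return(list(p.value = NA_real_, estimate = est,
                flag = "degenerate_variance"))
  tt <- stats::t.test(mutant, control, alternative = "less",
                      var.equal = var_equal)
  list(p.value = tt$p.value, estimate = est, flag = "ok")
}

#' Compute liquid-mating results from a spot-count table
#'
#' Full calculator: per (strain, day, biological replicate), titers for
#' both selections, the conjugation frequency (transconjugants per donor),
#' normalization to the mean same-day control frequency, and per strain a
#' one-sided test of the mutant's ratios against the control's.
#'
#' @param spots Data.frame with columns `strain`, `day`, `bio_rep`,
#'   `tech_rep`, `selection` (`"transconjugant"` or `"donor"`),
#'   `dilution_exponent`, `volume_ml`, `colonies`.
#' @param control_strain Identifier of the control mating.
#' @param band Countable band passed to [titer_from_spots()].
#' @return List with `replicates` (per biological replicate: frequency,
#'   ratio, flags) and `strains` (per strain: mean ratio, n, p one-sided
#'   vs control).
#' @export
mating_results <- function(spots, control_strain = "control",
                           band = c(3, 30)) {
  need <- c("strain", "day", "bio_rep", "selection", "dilution_exponent",
            "volume_ml", "colonies")
  if (!all(need %in% names(spots)))
    stop("spot table must have columns: ", paste(need, collapse = ", "))
  key <- interaction(spots$strain, spots$day, spots$bio_rep, drop = TRUE)
  reps <- lapply(split(spots, key), function(d) {
    tr <- d[d$selection == "transconjugant", , drop = FALSE]
    dn <- d[d$selection == "donor", , drop = FALSE]
    if (nrow(tr) == 0 || nrow(dn) == 0)
      stop("both selections required for ", d$strain[1], " day ",
           d$day[1], " rep ", d$bio_rep[1])
    t_tit <- titer_from_spots(tr, band)
    d_tit <- titer_from_spots(dn, band)
    data.frame(strain = d$strain[1], day = d$day[1], bio_rep = d$bio_rep[1],
               transconjugant_cfu = t_tit$cfu_per_ml,
               donor_cfu = d_tit$cfu_per_ml,
               frequency = conjugation_frequency(t_tit, d_tit),
               titer_flag = if (t_tit$flag == "ok" && d_tit$flag == "ok")
                 "ok" else "check_titer",
               stringsAsFactors = FALSE)
  })
  reps <- do.call(rbind, reps)
  rownames(reps) <- NULL
  reps$ratio <- NA_real_
  for (day in unique(reps$day)) {
    sel <- reps$day == day
    ctl <- reps$frequency[sel & reps$strain == control_strain]
    if (length(ctl) == 0)
      stop("no same-day control mating for day '", day, "'")
    reps$ratio[sel] <- reps$frequency[sel] / mean(ctl)
  }
  ctl_ratios <- reps$ratio[reps$strain == control_strain]
  strains <- lapply(split(reps, reps$strain), function(d) {
    s <- d$strain[1]
    p <- if (s == control_strain || length(d$ratio) < 2 ||
             length(ctl_ratios) < 2) NA_real_
    else test_vs_control(d$ratio, ctl_ratios)$p.value
    data.frame(strain = s, n = nrow(d), mean_frequency = mean(d$frequency),
               mean_ratio = mean(d$ratio),
               sem_ratio = stats::sd(d$ratio) / sqrt(nrow(d)),
               p = p, stringsAsFactors = FALSE)
  })
  strains <- do.call(rbind, strains)
  rownames(strains) <- NULL
  list(replicates = reps, strains = strains)
}

#' Efficiency of plating (EOP)
#'
#' Ratio of a phage's titer on a test strain to its titer on the reference
#' strain, with the qualitative bands used for spot assays: equivalent to
#' the reference vs below detection (no plaques at any dilution).
#'
#' @param test_titer,reference_titer PFU/ml (numbers or
#'   [titer_from_spots()] estimates).
#' @param detection_limit_pfu Smallest detectable titer given the spotted
#'   volumes and dilution series; a zero test titer reports
#'   `eop < detection_limit_pfu / reference`.
#' @return List with `eop`, `band` (`"equivalent"`, `"reduced"` or
#'   `"below_detection"`) and `detection_eop` (the detection bound as an
#'   EOP fraction).
#' @export
efficiency_of_plating <- function(test_titer, reference_titer,
                                  detection_limit_pfu = 100) {
  tt <- if (inherits(test_titer, "titer_estimate"))
    test_titer$cfu_per_ml else test_titer
  rr <- if (inherits(reference_titer, "titer_estimate"))
    reference_titer$cfu_per_ml else reference_titer
  if (is.na(rr) || rr <= 0) stop("reference titer must be positive")
  det <- detection_limit_pfu / rr
  if (tt <= 0)
    return(list(eop = 0, band = "below_detection", detection_eop = det))
  eop <- tt / rr
  band <- if (eop >= 0.5) "equivalent" else "reduced"
  list(eop = eop, band = band, detection_eop = det)
}
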