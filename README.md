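# conjscreen

Analysis of high-throughput solid-plate bacterial conjugation screens.

## The problem

Horizontal transfer of plasmid-borne antibiotic resistance is driven by
conjugation: a donor cell transfers a plasmid to a recipient through direct
contact. To find chromosomal genes the donor needs for efficient transfer,
genome-wide deletion libraries can be mated to a fixed recipient on plates
that are **doubly selective** — only transconjugants (recipients that
received the plasmid) can grow. The growth lag of each pinned mixed
population is then the time to conjugate plus a fixed
resistance-expression delay, so **lag time is a proxy for conjugation
time**. `conjscreen` is for researchers running such screens: it converts
time-lapse colony intensities (or raw plate image stacks) into calibrated
growth curves, extracts lag times, normalizes them against control matings
interleaved across the plate, and calls conjugation-deficient strains.

## The method

* **Layout** — on a 1536 plate (32 × 48), the reference control mating
  occupies every fourth position (one per 2 × 2 block; 384 controls,
  1,152 deposited test populations).
* **Quantification** — colonies are located by projection-profile grid
  detection, intensities are background-subtracted per cell box (border
  median) and converted to population counts with the calibration
  `y = 2.128e-2 x^5 + 1.023 x^4 + 11.47 x^3 + 25.62 x^2`.
* **Lag extraction** — curves are smoothed on the log2 scale by locally
  weighted polynomial regression; the initial **flat phase** is the
  earliest run of ≥ 3 points with derivative in (−0.02, 0.02) per 10-min
  interval, the **linear phase** is the steepest sustained sliding-window
  segment after it, and the lag is the crossing of the two:
  `lag = (flat_level − intercept) / slope`.
* **Hit calling** — each replicate's effect is
  `e = log2(lag / median lag of the 4 nearest controls)`; no-growth
  replicates are censored to `e = 2` (≥ 4× control). Strains are ranked
  by median effect and tested with a one-sample Wilcoxon signed-rank test
  vs 0 (exact null when feasible, Pratt zero handling) with
  Benjamini–Hochberg FDR across strains.
* **Validation calculators** — liquid-mating conjugation frequency
  (transconjugants per donor from serial-dilution spot counts, normalized
  to same-day controls, one-sided Welch test) and phage efficiency of
  plating.

A truth-tagged simulator generates synthetic screens (growth curves,
spatial fields, non-growers, mispinning, rendered image stacks) at the
same design points, so the full pipeline is testable end to end.

## Worked example

Simulate a 500-strain screen (n = 8: four replicates on each of two
plates) in which 50 strains truly double their lag, then analyze it:

```r
library(conjscreen)

scr <- simulate_screen(500, 8, effect = c(rep(0.8, 50), rep(0, 450)),
                       noise_sd_log2 = 0.1, seed = 1)
res <- analyze_screen(scr$plates, alternative = "greater")
head(res$strains, 6)
#>       strain n median_e  sem_e       p      q rank
#> 1 strain0027 8    0.950 0.0474 0.00391 0.0376    1
#> 2 strain0002 8    0.936 0.0624 0.00391 0.0376    2
#> 3 strain0001 8    0.916 0.0311 0.00391 0.0376    3
#> 4 strain0031 8    0.902 0.0324 0.00391 0.0376    4
#> 5 strain0009 8    0.889 0.0365 0.00391 0.0376    5
#> 6 strain0006 8    0.889 0.0491 0.00391 0.0376    6
sum(res$strains$q < 0.05)   # 52 called; all 50 true mutants among them
```

`median_e` is the strain's median log2 lag ratio to its local controls
(0.95 ≈ a 1.9× longer lag), `p` the exact one-sided Wilcoxon p-value
(with n = 8 all-delayed replicates give the floor 1/2^8 = 0.0039), and `q`
its BH-adjusted value. With n = 8 exact p-values are granular; strains
below ~16 replicates-worth of evidence cannot individually beat q < 0.05
unless enough other strains share the floor.

Single curves work the same way:

```r
ts <- simulate_curve(growth_params(lag_h = 5.46, rate = 1.5),
                     noise = noise_model(sd_log2 = 0.05), seed = 2)
extract_features(ts)
#>   lag_h lag_flag rate   qc
#> 1 5.481 measured 1.51 pass
```

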