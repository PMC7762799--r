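# Independent oracles used across tests: exhaustive enumerations and
# closed forms kept deliberately separate from the package's code paths.

# Wilcoxon signed-rank p by brute-force sign-flip enumeration (Pratt ranks:
# zeros ranked with the rest, excluded from the statistic; only non-zero
# signs flip)
enum_signrank_p <- function(x, alternative = "two.sided") {
  d <- x
  r <- rank(abs(d))
  nz <- d != 0
  V <- sum(r[d > 0])
  rz <- r[nz]
  if (length(rz) == 0) return(1)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(rz))))
  Vs <- as.numeric(signs %*% rz)
  p_ge <- mean(Vs >= V)
  p_le <- mean(Vs <= V)
  switch(alternative,
         two.sided = min(1, 2 * min(p_ge, p_le)),
         greater = p_ge,
         less = p_le)
}

# hypergeometric upper-tail by direct summation
brute_hyper_p <- function(overlap, n_hits, n_set, n_universe) {
  j <- overlap:min(n_set, n_hits)
  sum(choose(n_set, j) * choose(n_universe - n_set, n_hits - j)) /
    choose(n_universe, n_hits)
}

# brute-force nearest controls by scanning all positions
brute_nearest <- function(layout, pos, k) {
  ctl <- layout$positions[layout$positions$role == "control_mating", ]
  d <- sqrt((ctl$row - pos[1])^2 + (ctl$col - pos[2])^2)
  ord <- order(d, ctl$row, ctl$col)
  ctl[ord[seq_len(k)], c("row", "col")]
}

# miniature interleaved screen layout (8 x 12 grid, 2 x 3-well source
# plates) for fast curve-level end-to-end tests
mini_screen <- function(n_strains = 12, reps = 2) {
  fmt <- plate_format(c(8, 12))
  strains <- sprintf("m%02d", seq_len(n_strains))
  src <- split(strains, (seq_along(strains) - 1) %/% 6)
  names(src) <- sprintf("S%d", seq_along(src))
  list(format = fmt, strains = strains,
       layout = build_screen_layout(src, format = fmt,
                                    n_replicates_per_plate = reps))
}
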