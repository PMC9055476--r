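# Independent brute-force oracles. These deliberately re-derive each
# quantity by enumeration, never through the package's own algorithms.

# Trapezoidal area under an empirical ROC curve.
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) *
        (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

# Pair enumeration of P(case < control) + P(tie) / 2.
pair_auc <- function(cases, controls) {
  s <- 0
  for (a in cases) for (b in controls) s <- s + (a < b) + 0.5 * (a == b)
  s / (length(cases) * length(controls))
}

# Triple enumeration of the three-class ordering probability with the
# 1 / 1/2 / 1/6 tie-credit convention.
brute_vus <- function(dem, mci, nc) {
  s <- 0
  for (d in dem) for (m in mci) for (n in nc) {
    if (d == m && m == n) {
      s <- s + 1 / 6
    } else if (d < m && m < n) {
      s <- s + 1
    } else if ((d == m && m < n) || (d < m && m == n)) {
      s <- s + 1 / 2
    }
  }
  s / (length(dem) * length(mci) * length(nc))
}

# Full scan of the candidate cutoff grid for the best objective.
brute_best_objective <- function(g, weights = c(1, 1, 1)) {
  pooled <- sort(unique(c(g$dementia, g$MCI, g$NC)))
  cand <- c(-Inf, if (length(pooled) > 1)
    (pooled[-1] + pooled[-length(pooled)]) / 2, Inf)
  best <- -Inf
  for (c1 in cand) for (c2 in cand) {
    if (c1 > c2) next
    obj <- weights[1] * mean(g$dementia <= c1) +
      weights[2] * mean(g$MCI > c1 & g$MCI <= c2) +
      weights[3] * mean(g$NC > c2)
    best <- max(best, obj)
  }
  best
}
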