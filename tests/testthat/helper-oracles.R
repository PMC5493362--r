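# Independent oracles used to check the implementation by a different route.

# AUC by exhaustive concordant-pair counting (ties count 1/2).
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Centroid of a Mamdani aggregation evaluated by fine-grid quadrature:
# rules = list of list(strength = s, mf = fuzzy_mf), universe = c(lo, hi).
centroid_fine_grid <- function(rules, universe, n_points = 2e5) {
  grid <- seq(universe[1], universe[2], length.out = n_points)
  degrees <- rep(0, n_points)
  for (r in rules)
    degrees <- pmax(degrees, pmin(r$strength, membership(r$mf, grid)))
  sum(grid * degrees) / sum(degrees)
}

# Apparent temperature recomputed independently, spelled out step by step.
apparent_temperature_oracle <- function(ta, rh) {
  sat_vp <- function(t) exp(17.27 * t / (237.7 + t))  # Magnus, up to scale
  vp <- (rh / 100) * sat_vp(ta)
  td <- 237.7 * log(vp) / (17.27 - log(vp))
  -2.653 + 0.994 * ta + 0.0153 * td^2
}

# A random valid trapezoid over [lo, hi].
random_trapezoid <- function(lo, hi) {
  bp <- sort(stats::runif(4, lo, hi))
  mf_trapezoid("t", bp)
}
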