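# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementations they check.

# IVW via explicit summation of the closed form.
oracle_ivw <- function(E, D, D_se) {
  num <- 0
  den <- 0
  for (k in seq_along(E)) {
    w <- 1 / D_se[k]^2
    num <- num + E[k] * D[k] * w
    den <- den + E[k]^2 * w
  }
  c(beta = num / den, se = sqrt(1 / den))
}

# Weighted regression with intercept via brute-force normal equations,
# solving the 2x2 system by Cramer's rule. Orients exposure betas positive
# first, as MR-Egger requires.
oracle_egger <- function(E, D, D_se) {
  D <- ifelse(E < 0, -D, D)
  E <- abs(E)
  s0 <- s1 <- s2 <- t0 <- t1 <- 0
  for (k in seq_along(E)) {
    w <- 1 / D_se[k]^2
    s0 <- s0 + w
    s1 <- s1 + w * E[k]
    s2 <- s2 + w * E[k]^2
    t0 <- t0 + w * D[k]
    t1 <- t1 + w * E[k] * D[k]
  }
  det <- s0 * s2 - s1^2
  intercept <- (s2 * t0 - s1 * t1) / det
  slope <- (s0 * t1 - s1 * t0) / det
  rss <- 0
  for (k in seq_along(E)) {
    rss <- rss + (D[k] - intercept - slope * E[k])^2 / D_se[k]^2
  }
  scale2 <- max(1, rss / (length(E) - 2))
  # variance of (intercept, slope) from the inverse normal-equation matrix
  c(intercept = intercept, slope = slope,
    intercept_se = sqrt(scale2 * s2 / det),
    slope_se = sqrt(scale2 * s0 / det))
}

# Exhaustive weighted-percentile oracle: compute every ordered ratio's
# percentile directly from the definition and scan for the pair bracketing
# the 50th, interpolating linearly.
oracle_weighted_median <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord]
  w <- w / sum(w)
  p <- numeric(length(r))
  for (j in seq_along(r)) {
    s <- 0
    for (k in 1:j) s <- s + w[k]
    p[j] <- 100 * (s - w[j] / 2)
  }
  if (50 <= p[1]) return(r[1])
  if (50 >= p[length(r)]) return(r[length(r)])
  for (j in seq_len(length(r) - 1)) {
    if (p[j] <= 50 && 50 <= p[j + 1]) {
      return(r[j] + (50 - p[j]) * (r[j + 1] - r[j]) / (p[j + 1] - p[j]))
    }
  }
  stop("oracle failed to bracket the median")
}

# Small harmonised data frame for estimator tests.
toy_harmonised <- function(E, D, D_se, E_se = rep(0.01, length(E))) {
  data.frame(variant_id = sprintf("rs%d", seq_along(E)),
             E = E, E_se = E_se, D = D, D_se = D_se)
}

# Random estimator inputs with reproducible seeds.
random_instance <- function(k, seed) {
  set.seed(seed)
  toy_harmonised(E = rnorm(k, 0.1, 0.05), D = rnorm(k, 0.05, 0.05),
                 D_se = runif(k, 0.005, 0.05), E_se = runif(k, 0.001, 0.01))
}

# Build a tiny instrument set inline.
toy_set <- function(df, trait = "trait", type = "continuous", unit = "SD") {
  instrument_set(trait, type, unit, df)
}

toy_records <- function(ids, ea, oa, beta, se = 0.05, eaf = 0.3) {
  data.frame(variant_id = ids, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, stringsAsFactors = FALSE)
}
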