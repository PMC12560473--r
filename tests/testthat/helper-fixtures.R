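# Small in-code fixtures shared across test files.

# Mono-exponential (f = 0) noiseless series on a tiny grid: every voxel
# decays as S0 * exp(-b * D).
monoExpSeries <- function(S0 = 1000, D = 1e-3,
                          b = c(0, 10, 500, 750, 1000),
                          dim3 = c(4L, 4L, 2L)) {
  dwiSeries(b, lapply(b, function(bb) array(S0 * exp(-bb * D), dim3)))
}

# Brute-force pairwise AUC oracle: P(pos > neg) + 0.5 P(pos == neg),
# independent of the ROC-curve implementation.
pairwiseAUC <- function(values, labels) {
  u <- sort(unique(labels))
  pos <- values[labels == u[2]]
  neg <- values[labels == u[1]]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# A pair of vectors with an exact given sample Pearson correlation.
exactCorPair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  z <- stats::rnorm(n)
  z <- stats::residuals(stats::lm(z ~ x))
  xs <- as.numeric(scale(x)); zs <- as.numeric(scale(z))
  list(x = xs, y = r * xs + sqrt(1 - r^2) * zs)
}

# Counts behind a printed percentage at a known group size.
pctToCount <- function(pct, n) round(pct / 100 * n)
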