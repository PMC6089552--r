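# Independent oracles: deliberately naive implementations used to verify
# the package's statistics. These never call the code paths they check.

# One-sided (enrichment) Fisher p by explicit enumeration of the
# hypergeometric sample space with fixed margins.
oracle_fisher_greater <- function(a, b, c, d) {
  n <- a + b + c + d
  row1 <- a + b
  col1 <- a + c
  xs <- max(0, col1 - (c + d)):min(row1, col1)
  probs <- choose(row1, xs) * choose(n - row1, col1 - xs) / choose(n, col1)
  sum(probs[xs >= a])
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m * p_(j) / j,
# clipped to 1, original order restored.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Sort-based median (no stats::median).
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_mad <- function(x) oracle_median(abs(x - oracle_median(x)))
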