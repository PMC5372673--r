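# Independent oracles used to cross-check the package's own implementations.
# Each deliberately takes a different computational route from the code it
# verifies.

# Hardy-Weinberg exact test by direct closed-form enumeration: probability
# of each heterozygote count from the multinomial/hypergeometric formula
# via log-gamma, not the recurrence used by hweExactTest().
hweOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  rare <- 2 * min(nAA, naa) + nAa
  rare <- min(rare, 2 * n - rare)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    homR <- (rare - h) / 2
    homC <- n - h - homR
    lgamma(n + 1) - lgamma(homR + 1) - lgamma(h + 1) - lgamma(homC + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == nAa)
  min(1, sum(p[p <= p[obs] * (1 + 1e-7)]))
}

# OLS slope inference via explicit normal-equations linear algebra (QR-free,
# full-matrix route) -- independent of the streaming sums in regressTrait().
olsOracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  coefs <- solve(XtX, t(X) %*% y)
  res <- y - X %*% coefs
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 * solve(XtX)[2, 2])
  t <- coefs[2] / se
  list(n = n, beta = coefs[2], se = se, t = t,
       p = 2 * pt(-abs(t), n - 2))
}

# Benjamini-Hochberg by literal definition: scan all k for the largest with
# p_(k) <= k q / m and reject the k smallest p-values.
bhOracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kmax <- k
  if (kmax == 0) integer() else sort(o[seq_len(kmax)])
}

# small genotype panel with uncorrelated SNPs, fixed seed
makePanel <- function(nSamples = 30, nSnps = 10, maf = 0.3, seed = 42) {
  simulateGenotypes(SimulationConfig(nSamples = nSamples, nSnps = nSnps,
                                     mafSpec = maf, seed = seed))
}
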