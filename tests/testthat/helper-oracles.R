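# Independent oracles, coded step-by-step from first principles and kept
# separate from the package implementations they check.

# Trimmed-mean-of-M-values factors, following the published recipe directly:
# per-pair M and A values against a reference sample, double trim, weighted
# mean with inverse asymptotic variances, rescale to geometric mean 1.
oracle_tmm <- function(counts, logratioTrim = 0.30, sumTrim = 0.05,
                       ref = NULL) {
  lib <- colSums(counts)
  if (is.null(ref)) {
    f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
    ref <- which.min(abs(f75 - mean(f75)))
  }
  one <- function(obs, refc, nO, nR) {
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1;      hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
            rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), function(j)
    one(counts[, j], counts[, ref], lib[j], lib[ref]), 0)
  f / exp(mean(log(f)))
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws: fraction of draws containing >= k category members.
oracle_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- combn(N, n)
  # category members are items 1..K
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Benjamini-Hochberg step-up, written out explicitly.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Closed-form simple OLS.
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  list(slope = b, intercept = a,
       r2 = 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2))
}
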