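# Independent oracle implementations used to cross-check the package's
# estimators. These deliberately use different algorithmic routes (double
# loops, dist(), direct enumeration) from the compiled code paths.

# Fuzzy entropy by direct double loops over baselined templates.
fe_oracle <- function(x, m = 2, r_frac = 0.15) {
  r <- r_frac * sd(x)
  n <- length(x)
  phi <- function(k) {
    nt <- n - m # same template count for both dimensions
    tot <- 0
    for (i in 1:(nt - 1)) {
      xi <- x[i:(i + k - 1)]
      xi <- xi - mean(xi)
      for (j in (i + 1):nt) {
        xj <- x[j:(j + k - 1)]
        xj <- xj - mean(xj)
        d <- max(abs(xi - xj))
        tot <- tot + exp(-(d / r)^2)
      }
    }
    tot / (nt * (nt - 1) / 2)
  }
  -log(phi(m + 1) / phi(m))
}

# Correlation sum by dist() over an explicit delay embedding.
corr_sum_oracle <- function(x, m, tau, radius, theiler) {
  M <- length(x) - (m - 1) * tau
  emb <- sapply(0:(m - 1), function(k) x[(1:M) + k * tau])
  d <- as.matrix(dist(emb, method = "maximum"))
  keep <- abs(row(d) - col(d)) > theiler
  sum(d[keep] <= radius) / sum(keep)
}

# Segment count by explicit enumeration of admissible start offsets.
segment_count_oracle <- function(n, wn, tn) {
  starts <- seq(1, n, by = tn)
  sum(starts + wn - 1 <= n)
}

logistic_map <- function(n, x0 = 0.4) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}

# Mann-Whitney AUC by direct pair counting.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  100 * wins / (length(pos) * length(neg))
}
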