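# Independent numerical oracles, kept free of the code paths they check.

# Two-sided tail mass of the t distribution by numerical integration of
# the density (no stats::pt).
tCdfTailOracle <- function(t, df) {
  dens <- function(x)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  2 * stats::integrate(dens, abs(t), Inf, rel.tol = 1e-10)$value
}

# Equal-prior posteriors from the Gaussian density ratio with pooled
# (N - K) covariance, computed directly (no MASS).
gaussianPosteriorOracle <- function(train, labels, newdata) {
  y <- factor(labels)
  mu <- rowsum(train, y) / as.vector(table(y))
  S <- 0
  for (cl in levels(y)) {
    cen <- sweep(train[y == cl, , drop = FALSE], 2,
                 colMeans(train[y == cl, , drop = FALSE]))
    S <- S + crossprod(cen)
  }
  S <- S / (nrow(train) - nlevels(y))
  d2 <- sapply(levels(y), function(cl)
    stats::mahalanobis(newdata, mu[cl, ], S))
  d2 <- matrix(d2, nrow = nrow(newdata),
               dimnames = list(NULL, levels(y)))
  un <- exp(-0.5 * (d2 - apply(d2, 1, min)))
  un / rowSums(un)
}

# 12-sample, 2-variable, 3-class toy with fixed values.
toyLdaData <- function() {
  train <- rbind(c(1.0, 0.2), c(1.2, 0.1), c(0.9, 0.3), c(1.1, 0.4),
                 c(3.0, 1.0), c(3.2, 1.2), c(2.9, 0.8), c(3.1, 1.1),
                 c(1.5, 2.5), c(1.6, 2.8), c(1.4, 2.4), c(1.7, 2.6))
  colnames(train) <- c("v1", "v2")
  rownames(train) <- paste0("s", 1:12)
  list(x = train, y = rep(c("ortho", "meta", "para"), each = 4))
}
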