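# Independent oracles used to cross-check the package implementations.
# Each is deliberately written from the mathematical definition, not from
# the code path it checks.

# brute-force Benjamini-Hochberg step-up:
# q_i = min over j with p_(j) >= p_(i) of min(1, m * p_(j) / rank(j))
bhBruteForce <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) min(1, m * ranked[j] / j), numeric(1))
    q[o[i]] <- min(cand)
  }
  q
}

# exhaustive hypergeometric upper tail: enumerate every size-n subset of an
# N-element universe and count those overlapping the K reference genes in at
# least k elements
hyperEnumerate <- function(N, K, n, k) {
  if (k <= 0) return(1)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # reference = elements 1..K
  mean(hits >= k)
}

# independent coordinate-descent elastic net for the estimator glmnet
# actually solves with standardize = FALSE:
#   (1/2n)||y - b0 - Xb||^2 + lambda * (a|b|_1 + (1-a)/(2*sy) |b|_2^2),
# sy the population SD of the training response (glmnet rescales y, which
# leaves the L1 part equivariant but divides the quadratic penalty by sy)
cdElasticNet <- function(X, y, alpha, lambda, tol = 1e-11, maxit = 200000) {
  n <- nrow(X); p <- ncol(X)
  sy <- sd(y) * sqrt((n - 1) / n)
  b <- rep(0, p); b0 <- mean(y); r <- y - b0
  z <- colMeans(X^2)
  for (it in seq_len(maxit)) {
    dmax <- 0
    nb0 <- b0 + mean(r)
    if (nb0 != b0) {
      r <- r - (nb0 - b0); dmax <- max(dmax, abs(nb0 - b0)); b0 <- nb0
    }
    for (j in seq_len(p)) {
      rho <- mean(X[, j] * r) + z[j] * b[j]
      bj <- sign(rho) * max(0, abs(rho) - lambda * alpha) /
        (z[j] + lambda * (1 - alpha) / sy)
      if (bj != b[j]) {
        r <- r - X[, j] * (bj - b[j]); dmax <- max(dmax, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    if (dmax < tol) break
  }
  list(b0 = b0, b = b)
}

# exhaustive CV grid: mean held-out squared error over all observations for
# every (alpha, lambda) pair, using cdElasticNet fold fits
cvGridOracle <- function(X, y, grid, foldid) {
  out <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    errs <- numeric(length(y))
    for (k in sort(unique(foldid))) {
      tr <- foldid != k
      f <- cdElasticNet(X[tr, , drop = FALSE], y[tr],
                        grid$alpha[i], grid$lambda[i])
      errs[!tr] <- (y[!tr] - (f$b0 + X[!tr, , drop = FALSE] %*% f$b))^2
    }
    out[i] <- mean(errs)
  }
  out
}

# binomial 95% CI for a rejection rate at nominal level `a` over `m` tests
binomCI95 <- function(a, m) a + c(-1, 1) * 1.959964 * sqrt(a * (1 - a) / m)
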