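# Shared fixtures and independent oracles, built in code at test time.

# small deterministic genotype container
toy_genotypes <- function(values, status) {
  poda_genotypes(values, status)
}

# scalar, loop-based reimplementation of the leave-one-out standardised-mean
# statistic: per sample, per locus, with physical removal of the sample from
# its own class pool. Kept deliberately naive and independent of the
# package's vectorised path.
oracle_D <- function(values, case) {
  n <- nrow(values)
  D <- numeric(n)
  for (i in seq_len(n)) {
    d <- c()
    for (j in seq_len(ncol(values))) {
      y <- values[i, j]
      if (is.na(y)) next
      ctrl_pool <- which(!case & seq_len(n) != i)
      case_pool <- which(case & seq_len(n) != i)
      f <- mean(values[ctrl_pool, j], na.rm = TRUE)
      g <- mean(values[case_pool, j], na.rm = TRUE)
      if (is.nan(f) || is.nan(g)) next
      d <- c(d, abs(y - f) - abs(y - g))
    }
    s <- length(d)
    m <- mean(d)
    sdd <- stats::sd(d)
    if (s == 1L || sdd < 1e-12) {
      D[i] <- if (abs(m) < 1e-12) 0 else sign(m) * 1e6
    } else {
      D[i] <- m / (sdd / sqrt(s))
    }
  }
  D
}

# independent midrank rank-sum oracle: rank by counting, never via rank()
oracle_ranksum <- function(D, case) {
  r <- vapply(seq_along(D), function(i) {
    1 + sum(D < D[i]) + (sum(D == D[i]) - 1) / 2
  }, numeric(1))
  sum(r[case])
}

# brute-force two-sided Fisher p by hypergeometric enumeration over all
# tables with the observed margins
oracle_fisher2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand-rolled IRLS for logistic regression (intercept + one covariate)
oracle_irls_logistic <- function(x, y, tol = 1e-12, max_iter = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (it in seq_len(max_iter)) {
    eta <- X %*% beta
    mu <- 1 / (1 + exp(-eta))
    w <- as.vector(mu * (1 - mu))
    z <- eta + (y - mu) / w
    beta_new <- solve(t(X) %*% (w * X), t(X) %*% (w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.vector(beta)
}

# brute-force BH step-up, literal definition: q_(i) = min_{j >= i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(m * p[o][i:m] / seq(i, m))
  }, numeric(1))
  pmin(1, q_sorted)[order(o)]
}
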