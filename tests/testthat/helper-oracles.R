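# Independent oracles, kept deliberately naive: each reimplements the
# quantity it checks from first principles, on a different code path from
# the package.

# Two-sided Fisher p by full hypergeometric enumeration in log space:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's (within relative 1e-7).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n2 <- c_ + d; k <- a + c_
  xs <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n2, k - xs) - lchoose(m + n2, k)
  obs <- logp[xs == a]
  min(1, sum(exp(logp[logp <= obs + log(1 + 1e-7)])))
}

# Log-likelihood of a univariate Gaussian mixture (direct formula).
oracle_gmm_loglik <- function(x, pi_k, mu, sg) {
  dens <- rowSums(vapply(seq_along(mu), function(k) {
    pi_k[k] * dnorm(x, mu[k], sg[k])
  }, numeric(length(x))))
  sum(log(dens))
}

# Brute-force grid fitter for a two-component equal-variance mixture:
# exhaustive search over (mu1, mu2, sigma, pi). Coarse but completely
# independent of EM.
oracle_gmm_grid2 <- function(x, mu1_grid, mu2_grid, sigma_grid, pi_grid) {
  best <- list(loglik = -Inf)
  for (s in sigma_grid) for (p in pi_grid) {
    for (m1 in mu1_grid) for (m2 in mu2_grid) {
      ll <- oracle_gmm_loglik(x, c(p, 1 - p), c(m1, m2), c(s, s))
      if (ll > best$loglik) {
        best <- list(loglik = ll, mu = c(m1, m2), sigma = s, pi = p)
      }
    }
  }
  best
}

# Equal-posterior gray value of a 2-component mixture: root of the
# quadratic obtained by equating the weighted component log-densities.
oracle_equal_posterior_root <- function(pi_k, mu, sg, lower, upper) {
  aa <- 1 / sg[2]^2 - 1 / sg[1]^2
  bb <- 2 * (mu[1] / sg[1]^2 - mu[2] / sg[2]^2)
  cc <- mu[2]^2 / sg[2]^2 - mu[1]^2 / sg[1]^2 +
    2 * log(pi_k[1] / pi_k[2]) + 2 * log(sg[2] / sg[1])
  if (abs(aa) < 1e-12) {
    roots <- -cc / bb
  } else {
    disc <- bb^2 - 4 * aa * cc
    roots <- (-bb + c(-1, 1) * sqrt(disc)) / (2 * aa)
  }
  roots <- roots[roots > lower & roots < upper]
  stopifnot(length(roots) == 1)
  roots
}

# Dense-grid one-phase fit: profile the rate over a fine k grid with the
# intercept/amplitude solved by textbook normal equations.
oracle_one_phase_ss <- function(x, y, k_max = 1, n_grid = 2000) {
  ss_at <- function(k) {
    z <- exp(-k * x)
    if (max(z) - min(z) < 1e-12) return(sum((y - mean(y))^2))
    sum(lm.fit(cbind(1, z), y)$residuals^2)
  }
  # coarse log grid, then repeated grid zooming around the best k
  ks <- c(0, 10^seq(-6, log10(k_max), length.out = n_grid))
  ss <- vapply(ks, ss_at, numeric(1))
  for (zoom in 1:6) {
    i <- which.min(ss)
    lo <- ks[max(1, i - 1)]
    hi <- ks[min(length(ks), i + 1)]
    if (hi <= lo) hi <- lo + 1e-8
    ks <- seq(lo, hi, length.out = 200)
    ss <- vapply(ks, ss_at, numeric(1))
  }
  min(ss)
}

# Bayes-optimal labels under the true generator parameters.
oracle_bayes_labels <- function(x, pi_k, mu, sg) {
  post_intense <- pi_k[1] * dnorm(x, mu[1], sg[1])
  post_weak <- pi_k[2] * dnorm(x, mu[2], sg[2])
  ifelse(post_intense > post_weak, "intense", "weak")
}
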