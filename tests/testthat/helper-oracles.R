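# Independent oracles, written against the definitions rather than the
# package implementation.

# Efron partial log-likelihood, plain double loop over unique event times.
oracle_efron_loglik <- function(beta, time, event, X) {
  eta <- as.vector(X %*% beta)
  r <- exp(eta)
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sum_r_R <- sum(r[R])
    sum_r_D <- sum(r[D])
    ll <- ll + sum(eta[D])
    for (j in seq_len(d) - 1L)
      ll <- ll - log(sum_r_R - (j / d) * sum_r_D)
  }
  ll
}

# Brute-force maximization of the Efron partial likelihood.
oracle_cox_fit <- function(time, event, X) {
  X <- as.matrix(X)
  opt <- stats::optim(rep(0, ncol(X)),
                      function(b) -oracle_efron_loglik(b, time, event, X),
                      method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  list(coef = opt$par, loglik = -opt$value)
}

# Double-loop Gaussian kernel density estimates.
oracle_kde <- function(sample, h, query) {
  out <- numeric(length(query))
  for (i in seq_along(query)) {
    s <- 0
    for (x in sample) s <- s + exp(-0.5 * ((query[i] - x) / h)^2) / sqrt(2 * pi)
    out[i] <- s / (length(sample) * h)
  }
  out
}

oracle_bkde <- function(sample, H, query) {
  Hinv <- solve(H)
  detH <- det(H)
  out <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    s <- 0
    for (j in seq_len(nrow(sample))) {
      z <- as.numeric(query[i, ] - sample[j, ])
      s <- s + exp(-0.5 * drop(t(z) %*% Hinv %*% z))
    }
    out[i] <- s / (nrow(sample) * 2 * pi * sqrt(detH))
  }
  out
}

# Benjamini-Hochberg step-up, straight from the formula
# min_{j >= i} p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  cummin_rev <- rev(cummin(rev(p[o] * m / seq_len(m))))
  adj[o] <- pmin(cummin_rev, 1)
  adj
}
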