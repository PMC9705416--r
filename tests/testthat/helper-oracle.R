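# Independent Newton-Raphson logistic ML oracle, written directly against
# the Bernoulli log-likelihood (no glm machinery). Used to cross-check
# fit_logistic.
nr_logistic <- function(y, X, tol = 1e-12, maxit = 60) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(t(X) %*% (y - p))
    H <- t(X) %*% (X * (p * (1 - p)))
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(grad)) < tol) break
  }
  eta <- drop(X %*% beta)
  list(coef = beta,
       ll = sum(y * eta - log(1 + exp(eta))))
}

# random small dataset on which logistic ML is well behaved
random_logit_data <- function(n, k, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k)
  beta <- runif(k + 1, -0.8, 0.8)
  eta <- beta[1] + drop(X %*% beta[-1])
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  list(y = y, X = X)
}
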