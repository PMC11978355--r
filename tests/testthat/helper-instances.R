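# Shared fixtures and numeric-differentiation oracles.

# small random Poisson regression instance with log-linear truth
rand_instance <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(runif(n * p, 0, 2), n, p)
  beta <- c(runif(1, 0.5, 1.5), runif(p, -0.5, 0.5))
  y <- rpois(n, exp(drop(cbind(1, X) %*% beta)))
  list(data = count_dataset(y, X), beta_true = beta, X = X, y = y)
}

# central finite-difference gradient of a scalar function
num_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

# central finite-difference Jacobian of a vector function
num_jac <- function(f, x, eps = 1e-5) {
  cols <- lapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  })
  do.call(cbind, cols)
}
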