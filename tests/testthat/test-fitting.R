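test_that("OLS initialization recentres the raw least-squares fit at x0", {
  # constant response: intercept c, zero slopes
  d <- count_dataset(rep(4L, 6), matrix(rnorm(6), 6, 1))
  expect_equal(ols_init(d, 0.5), c(4, 0), ignore_attr = TRUE)
  # exact line y = 2x, x0 = 3: raw fit (0, 2) -> centered (6, 2)
  d2 <- count_dataset(c(2, 4, 6, 8), matrix(1:4))
  expect_equal(ols_init(d2, 3), c(6, 2), ignore_attr = TRUE)
  # random instance vs explicit normal equations
  inst <- rand_instance(20, 2, seed = 41)
  Xs <- cbind(1, inst$X)
  b_raw <- solve(t(Xs) %*% Xs, t(Xs) %*% inst$y)
  x0 <- c(0.7, 1.2)
  expect_equal(ols_init(inst$data, x0),
               c(b_raw[1] + sum(b_raw[-1] * x0), b_raw[-1]),
               ignore_attr = TRUE)
  # rank-deficient raw design
  ddup <- count_dataset(c(1, 2, 3, 4, 2), cbind(1:5, 2 * (1:5)))
  expect_error(ols_init(ddup, c(1, 2)), "rank deficient")
})

test_that("Newton-Raphson solves the unit-weight Poisson MLE", {
  # intercept-only: closed form log(mean(y))
  y <- c(3L, 7L, 2L, 8L, 5L)
  des <- structure(list(Xc = matrix(1, 5), w = rep(1, 5), y = y,
                        x0 = numeric(0)), class = "local_design")
  fit <- newton_raphson(des, 0, fit_options())
  expect_true(fit$converged)
  expect_equal(fit$beta, log(mean(y)), tolerance = 1e-8)
  # unit weights, uncentered design: matches glm on seeded instances
  opts <- fit_options(epsilon = 1e-12)
  for (seed in 42:44) {
    inst <- rand_instance(100, 2, seed = seed)
    g <- fit_global(inst$data, opts)
    oracle <- glm(inst$y ~ inst$X, family = poisson,
                  control = glm.control(epsilon = 1e-12))
    expect_lt(max(abs(g$beta - coef(oracle))), 1e-8)
    expect_equal(g$loglik, as.numeric(logLik(oracle)), tolerance = 1e-10)
  }
  # starting at the optimum converges immediately
  inst <- rand_instance(50, 2, seed = 45)
  desu <- structure(list(Xc = cbind(1, inst$X), w = rep(1, 50), y = inst$y,
                         x0 = c(0, 0)), class = "local_design")
  mle <- newton_raphson(desu, ols_init(inst$data, c(0, 0)), fit_options())$beta
  refit <- newton_raphson(desu, mle, fit_options())
  expect_true(refit$converged)
  expect_lte(refit$n_iter, 2L)
})

test_that("safeguarded fitting never decreases the likelihood from its start", {
  inst <- rand_instance(40, 2, seed = 46)
  spec <- kernel_spec("gaussian", c(0.5, 0.5))
  x0 <- inst$X[7, ]
  des <- build_local_design(inst$data, x0, spec)
  init <- ols_init(inst$data, x0)
  if (!all(is.finite(exp(linear_predictor(des, init))))) init <- c(log(mean(inst$y)), 0, 0)
  fit <- newton_raphson(des, init, fit_options())
  expect_gte(fit$loglik, local_loglik(des, init))
  expect_lt(fit$score_max, 1e-4)
})

test_that("fit_local records windows and handles degenerate neighbourhoods", {
  inst <- rand_instance(30, 2, seed = 47)
  spec <- kernel_spec("gaussian", c(0.6, 0.9))
  fit <- fit_local(inst$data, c(1, 1), spec)
  expect_true(fit$converged)
  expect_equal(unname(fit$window[, "upper"] - fit$window[, "lower"]),
               2 * spec$bandwidths)
  expect_equal(fit$effective_weight,
               sum(product_kernel_weights(inst$X, c(1, 1), spec)))
  expect_error(
    fit_local(inst$data, c(50, 50), kernel_spec("epanechnikov", c(0.1, 0.1))),
    "degenerate")
})

test_that("local fits are equivariant under predictor shifts", {
  inst <- rand_instance(35, 2, seed = 48)
  spec <- kernel_spec("gaussian", c(0.7, 0.7))
  x0 <- c(0.8, 1.1)
  f1 <- fit_local(inst$data, x0, spec, fit_options(epsilon = 1e-10))
  shift <- c(3.5, -1.25)
  dshift <- count_dataset(inst$y, sweep(inst$X, 2, -shift))
  f2 <- fit_local(dshift, x0 + shift, spec, fit_options(epsilon = 1e-10))
  expect_equal(f2$beta, f1$beta, tolerance = 1e-8)
})

test_that("per-observation fitting is row-wise independent", {
  inst <- rand_instance(8, 2, seed = 49)
  spec <- kernel_spec("gaussian", c(0.8, 0.8))
  fits <- fit_at_observations(inst$data, spec)
  expect_length(fits, 8)
  expect_true(all(vapply(fits, function(f) length(f$beta) == 3, logical(1))))
  ct <- coef_table(fits)
  expect_equal(dim(ct), c(8, 9))
  # permuting rows permutes the fitted coefficients identically
  perm <- c(3, 1, 2, 8, 7, 4, 5, 6)
  dperm <- count_dataset(inst$y[perm], inst$X[perm, ])
  fits_p <- fit_at_observations(dperm, spec)
  for (i in seq_along(perm)) {
    expect_equal(fits_p[[i]]$beta, fits[[perm[i]]]$beta, tolerance = 1e-8)
  }
})

test_that("pointwise estimates of a smooth log-mean improve with sample size", {
  rmse_at <- function(n) {
    sc <- simulation_scenario(n = n, p = 1, mean_function = "quadratic",
                              coefficients = c(2, 0.8), quad = -0.4,
                              ranges = matrix(c(0, 2), 1), seed = 50)
    d <- simulate_counts(sc)
    truth <- attr(d, "true_log_mean")
    x0s <- c(0.5, 1, 1.5)
    est <- vapply(x0s, function(x0) {
      fit_local(d, x0, kernel_spec("gaussian", 0.25))$beta[1]
    }, numeric(1))
    sqrt(mean((est - truth(matrix(x0s)))^2))
  }
  errs <- vapply(c(100, 400, 1600), rmse_at, numeric(1))
  expect_lt(errs[3], errs[1])
})

test_that("dispersion diagnostic returns variance-to-mean ratio with summaries", {
  d <- count_dataset(c(3L, 3L, 3L), matrix(c(1, 2, 3)))
  res <- dispersion_check(d)
  expect_equal(res$ratio, 0)
  expect_named(res$table, c("variable", "mean", "min", "max", "sd"))
  d2 <- count_dataset(rep(c(0L, 2L), 4), matrix(rnorm(8)))
  expect_gt(dispersion_check(d2)$ratio, 1)
  # law of large numbers under a constant-mean Poisson law
  set.seed(51)
  big <- count_dataset(rpois(1e5, 110), matrix(runif(1e5)))
  expect_gt(dispersion_check(big)$ratio, 0.97)
  expect_lt(dispersion_check(big)$ratio, 1.03)
})
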