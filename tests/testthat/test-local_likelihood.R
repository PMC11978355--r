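test_that("local design centers predictors and carries product-kernel weights", {
  inst <- rand_instance(12, 2, seed = 21)
  spec <- kernel_spec("gaussian", c(0.8, 0.8))
  x0 <- inst$X[3, ]
  des <- build_local_design(inst$data, x0, spec)
  expect_equal(unname(des$Xc[3, ]), c(1, 0, 0))
  expect_equal(des$w, product_kernel_weights(inst$X, x0, spec))
  # arithmetic of one centered row
  d2 <- count_dataset(c(1, 2, 3, 4), cbind(c(5, 1, 2, 3), c(7, 8, 9, 10)))
  des2 <- build_local_design(d2, c(4, 10), kernel_spec("gaussian", c(1, 1)))
  expect_equal(unname(des2$Xc[1, ]), c(1, 1, -3))
  # compact kernel with isolated evaluation point: empty neighbourhood
  expect_error(
    build_local_design(inst$data, c(100, 100),
                       kernel_spec("epanechnikov", c(0.01, 0.01))),
    "degenerate neighbourhood")
})

test_that("linear predictor is the centered dot product", {
  inst <- rand_instance(8, 2, seed = 22)
  des <- build_local_design(inst$data, inst$X[1, ],
                            kernel_spec("gaussian", c(1, 1)))
  expect_equal(linear_predictor(des, c(0, 0, 0)), rep(0, 8))
  des1 <- structure(list(Xc = matrix(c(1, 2, -1), 1), w = 1, y = 2,
                         x0 = c(2, -1)), class = "local_design")
  expect_equal(linear_predictor(des1, c(1, 0.5, 0.5)), 1.5)
  expect_error(linear_predictor(des, c(1, 2)), "length")
})

test_that("weighted log-likelihood matches closed forms and is linear in weights", {
  # one active row with w = 1, y = 0, eta = 0: 0*0 - e^0 - ln(0!) = -1
  des <- structure(list(Xc = matrix(c(1, 1), 2), w = c(0, 1), y = c(5, 0),
                        x0 = numeric(0)), class = "local_design")
  expect_equal(local_loglik(des, 0), -1)
  # unit weights reduce to the standard Poisson log-likelihood
  inst <- rand_instance(15, 2, seed = 23)
  desu <- structure(list(Xc = cbind(1, inst$X), w = rep(1, 15), y = inst$y,
                         x0 = c(0, 0)), class = "local_design")
  beta <- c(0.8, 0.2, -0.1)
  mu <- exp(drop(cbind(1, inst$X) %*% beta))
  expect_equal(local_loglik(desu, beta), sum(dpois(inst$y, mu, log = TRUE)))
  # linearity in the weights
  desw <- build_local_design(inst$data, inst$X[2, ],
                             kernel_spec("gaussian", c(0.6, 0.6)))
  des2w <- desw; des2w$w <- 2 * desw$w
  expect_equal(local_loglik(des2w, beta), 2 * local_loglik(desw, beta))
})

test_that("score and Hessian agree with numeric differentiation and closed forms", {
  for (seed in 31:34) {
    p <- sample(1:3, 1)
    inst <- rand_instance(15, p, seed = seed)
    des <- build_local_design(inst$data, inst$X[1, ],
                              kernel_spec("gaussian", rep(0.9, p)))
    beta <- c(log(mean(inst$y) + 1), runif(p, -0.2, 0.2))
    g <- local_score(des, beta)
    expect_equal(g, num_grad(function(b) local_loglik(des, b), beta),
                 tolerance = 1e-6, ignore_attr = TRUE)
    H <- local_hessian(des, beta)
    expect_equal(H, num_jac(function(b) local_score(des, b), beta),
                 tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(H, t(H))
    # score vanishes when the residuals vanish
    yfit <- exp(linear_predictor(des, beta))
    des_exact <- des; des_exact$y <- yfit
    expect_equal(max(abs(local_score(des_exact, beta))), 0, tolerance = 1e-12)
  }
})

test_that("Hessian closed form at beta = 0 and Fisher information identities hold", {
  inst <- rand_instance(10, 2, seed = 35)
  des <- build_local_design(inst$data, inst$X[4, ],
                            kernel_spec("gaussian", c(0.7, 0.7)))
  desu <- des; desu$w <- rep(1, 10)
  expect_equal(local_hessian(desu, c(0, 0, 0)),
               -crossprod(des$Xc), ignore_attr = TRUE)
  beta <- c(1, 0.1, -0.2)
  expect_equal(fisher_information(des, beta) + local_hessian(des, beta),
               matrix(0, 3, 3), ignore_attr = TRUE)
  expect_true(all(eigen(fisher_information(des, beta))$values >= -1e-10))
})

test_that("likelihood pieces are invariant to permuting observations", {
  inst <- rand_instance(12, 2, seed = 36)
  spec <- kernel_spec("gaussian", c(0.8, 0.8))
  x0 <- c(1, 1)
  beta <- c(1, 0.2, -0.2)
  des <- build_local_design(inst$data, x0, spec)
  perm <- sample(12)
  dperm <- count_dataset(inst$y[perm], inst$X[perm, ])
  desp <- build_local_design(dperm, x0, spec)
  expect_equal(local_loglik(desp, beta), local_loglik(des, beta))
  expect_equal(local_score(desp, beta), local_score(des, beta))
  expect_equal(local_hessian(desp, beta), local_hessian(des, beta))
})

test_that("count dataset validation rejects bad responses and tiny samples", {
  expect_error(count_dataset(c(1, -2, 3, 1), matrix(1:4)), "non-negative")
  expect_error(count_dataset(c(1, 2.5, 3, 1), matrix(1:4)), "offending row 2")
  expect_error(count_dataset(c(1, NA, 3, 1), matrix(1:4)), "missing")
  expect_error(count_dataset(c(1, 2), matrix(1:2)), "n > p \\+ 1")
})
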