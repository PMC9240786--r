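# simulate a training set with known signal
sim_training <- function(n, p, n_qtl, h2, seed) {
  set.seed(seed)
  Z <- matrix(rbinom(n * p, 2, 0.4), n, p)
  b <- rep(0, p)
  b[sample.int(p, n_qtl)] <- rnorm(n_qtl)
  g <- drop(Z %*% b)
  e <- rnorm(n, sd = sqrt(var(g) * (1 - h2) / h2))
  list(Z = Z, y = g + e, g = g, b = b)
}

test_that("fast mode equals the closed-form ridge solution", {
  d <- sim_training(50, 100, 20, 0.5, 101)
  m <- fit_marker_effects(d$y, d$Z, method = "fast", h2 = 0.5)
  # independent closed-form computation
  Zc <- scale(d$Z, center = TRUE, scale = FALSE)
  beta_ref <- solve(crossprod(Zc) + diag(m$lambda, 100),
                    crossprod(Zc, d$y - mean(d$y)))
  expect_lt(max(abs(m$beta - drop(beta_ref))), 1e-8)
})

test_that("a single informative marker recovers sign and magnitude", {
  set.seed(5)
  Z <- matrix(rbinom(200, 2, 0.5), 200, 1)
  y <- 0.8 * Z[, 1]
  m <- fit_marker_effects(y, Z, method = "fast", h2 = 0.99)
  expect_gt(m$beta[1], 0.7)
  expect_lt(m$beta[1], 0.81)
})

test_that("Gibbs sampler agrees with the closed-form ridge", {
  d <- sim_training(50, 100, 20, 0.5, 202)
  fast <- fit_marker_effects(d$y, d$Z, method = "fast", h2 = 0.5)
  set.seed(1)
  fixed <- fit_marker_effects(d$y, d$Z, method = "gibbs", h2 = 0.5,
                              iter = 1500, burnin = 300,
                              fixed_variances = TRUE)
  # matched variance components: posterior mean is the ridge solution
  expect_lt(max(abs(fixed$beta - fast$beta)), 0.05 * sd(fast$beta) +
              max(abs(fast$beta)) * 0.05)
  expect_gt(cor(fixed$beta, fast$beta), 0.98)
  set.seed(2)
  full <- fit_marker_effects(d$y, d$Z, method = "gibbs", h2 = 0.5,
                             iter = 1500, burnin = 300)
  # with sampled variances the estimates stay close to the ridge solution
  expect_gt(cor(full$beta, fast$beta), 0.9)
})

test_that("GEBVs are the linear combination of marker effects", {
  d <- sim_training(30, 20, 5, 0.5, 303)
  m <- fit_marker_effects(d$y, d$Z, method = "fast", h2 = 0.5)
  u <- gebv(d$Z, m)
  # hand-computed dot products
  for (i in 1:3) {
    expect_equal(u[i], m$intercept +
                   sum((d$Z[i, ] - m$centers) * m$beta))
  }
  # zero effects predict the intercept everywhere
  m0 <- m
  m0$beta <- rep(0, 20)
  expect_true(all(gebv(d$Z, m0) == m$intercept))
  # identical genotypes get identical GEBVs
  Z2 <- d$Z[c(1, 1, 2), ]
  expect_equal(gebv(Z2, m)[1], gebv(Z2, m)[2])
  expect_error(gebv(d$Z[, 1:5], m), "mismatch")
})

test_that("prediction accuracy is the Pearson correlation with guards", {
  g <- rnorm(50)
  expect_equal(prediction_accuracy(g, g), 1)
  expect_equal(prediction_accuracy(-g, g), -1)
  expect_error(prediction_accuracy(g[1:2], g[1:2]), "at least 3")
  expect_error(prediction_accuracy(rep(1, 10), rnorm(10)), "variance")
  # affine invariance
  u <- rnorm(50)
  expect_equal(prediction_accuracy(2 * u + 3, g),
               prediction_accuracy(u, g))
})

test_that("shrinkage is monotone: larger lambda, smaller effect norm", {
  d <- sim_training(60, 80, 20, 0.5, 404)
  norms <- vapply(c(0.1, 1, 10, 100, 1000), function(l) {
    m <- fit_marker_effects(d$y, d$Z, method = "fast", lambda = l)
    sum(m$beta^2)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("out-of-sample accuracy matches an independent ridge oracle", {
  d <- sim_training(800, 2000, 100, 0.5, 505)
  train <- 1:400
  valid <- 401:800
  m <- fit_marker_effects(d$y[train], d$Z[train, ], method = "fast",
                          h2 = 0.5)
  acc <- prediction_accuracy(gebv(d$Z[valid, ], m), d$g[valid])
  # independent closed-form ridge on the same data
  Zc <- scale(d$Z[train, ], center = TRUE, scale = FALSE)
  beta_ref <- solve(crossprod(Zc) + diag(m$lambda, 2000),
                    crossprod(Zc, d$y[train] - mean(d$y[train])))
  u_ref <- drop(scale(d$Z[valid, ], center = m$centers,
                      scale = FALSE) %*% beta_ref)
  acc_ref <- cor(u_ref, d$g[valid])
  expect_lt(abs(acc - acc_ref), 0.1)
  expect_gt(acc, 0.3)  # a real signal is picked up
})

test_that("degenerate training inputs are rejected", {
  expect_error(fit_marker_effects(rep(1, 10),
                                  matrix(rbinom(100, 2, 0.5), 10, 10)),
               "zero variance")
  expect_error(fit_marker_effects(rnorm(10), matrix(0L, 10, 5)),
               "monomorphic")
})
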