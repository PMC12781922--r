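test_that("the weighted estimating equation reduces to known closed forms", {
  # intercept-only weighted mean: (1 + 2 + 2*3) / 4 = 2.25
  f <- solve_iiw_gee(c(1, 2, 3), cbind(rep(1, 3)), id = 1:3,
                     weights = c(1, 1, 2))
  expect_equal(unname(f$beta), 2.25, tolerance = 1e-12)

  # constant weights cancel: identical to OLS
  set.seed(4)
  t <- runif(40, 0, 2)
  X <- traj_basis(t)
  y <- mean_trajectory(t, c(3.3, 4, 10.5)) + rnorm(40)
  w <- rep(0.37, 40)
  b_w <- solve_iiw_gee(y, X, id = rep(1:10, 4), weights = w)$beta
  b_ols <- coef(lm(y ~ 0 + X))
  expect_equal(unname(b_w), unname(b_ols), tolerance = 1e-10)

  # exact-fit invariance: noiseless outcomes recover beta for any weights
  y0 <- mean_trajectory(t, c(1, -2, 5))
  set.seed(5)
  b_exact <- suppressWarnings(  # a perfect fit trips summary.lm's warning
    solve_iiw_gee(y0, X, id = rep(1:10, 4),
                  weights = runif(40, 0.2, 3)))$beta
  expect_equal(unname(b_exact), c(1, -2, 5), tolerance = 1e-10)
})

test_that("invalid GEE inputs error", {
  expect_error(solve_iiw_gee(numeric(), matrix(nrow = 0, ncol = 1),
                             integer(), numeric()), "zero assessments")
  expect_error(solve_iiw_gee(1:3, cbind(rep(1, 3)), 1:3,
                             weights = c(1, -1, 1)), "positive")
  X_def <- cbind(1, c(1, 1, 1))
  expect_error(solve_iiw_gee(1:3, X_def, 1:3, rep(1, 3)), "rank-deficient")
})

test_that("the sandwich covariance is symmetric PSD and halves when every
          cluster is duplicated", {
  set.seed(11)
  t <- runif(60, 0, 2)
  X <- traj_basis(t)
  id <- rep(1:20, 3)
  y <- mean_trajectory(t, c(3.3, 4, 10.5)) + rnorm(60)
  f1 <- solve_iiw_gee(y, X, id, rep(1, 60))
  expect_equal(f1$vcov, t(f1$vcov))
  expect_true(all(eigen(f1$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  f2 <- solve_iiw_gee(c(y, y), rbind(X, X), c(id, id + 100), rep(1, 120))
  expect_equal(unname(f2$beta), unname(f1$beta), tolerance = 1e-12)
  # 1/n scaling of the cluster-robust variance, up to small-sample factors
  expect_equal(unname(diag(f2$vcov) / diag(f1$vcov)), rep(0.5, 3),
               tolerance = 0.05)
})

test_that("the AUC antiderivative matches quadrature and the constant-mean
          identity", {
  expect_equal(auc_from_beta(c(3.3, 0, 0), tau = 1)$value, 3.3,
               tolerance = 1e-10)
  expect_equal(auc_from_beta(c(3.3, 0, 0), tau = 2)$value, 6.6,
               tolerance = 1e-10)

  set.seed(2)
  for (i in 1:8) {
    beta <- rnorm(3, sd = 5)
    tau <- runif(1, 0.5, 4)
    quad <- integrate(function(t) mean_trajectory(t, beta), 0, tau,
                      rel.tol = 1e-12, abs.tol = 1e-12)$value
    expect_equal(auc_from_beta(beta, tau)$value, quad, tolerance = 1e-8)
  }
  # mechanism-1 closed form against the quadrature oracle
  expect_equal(auc_from_beta(c(3.3, 4, 10.5), tau = 2)$value,
               true_auc(2, mechanism = 1), tolerance = 1e-8)
  # vanishing interval
  expect_lt(auc_from_beta(c(3.3, 4, 10.5), tau = 1e-9)$value, 1e-7)
  expect_error(auc_from_beta(c(1, 1, 1), tau = 0))

  # delta-method SE agrees with the explicit gradient form
  V <- crossprod(matrix(rnorm(9), 3))
  tau <- 2
  g <- c(tau, tau / (1 + tau), 1 - (log(1 + tau) + 1) / (1 + tau))
  expect_equal(auc_from_beta(c(1, 2, 3), tau, V)$se,
               sqrt(drop(t(g) %*% V %*% g)), tolerance = 1e-12)
})

test_that("for fixed weights, removing zero-assessment subjects leaves the
          solution bit-identical", {
  long <- fixture_long_visits()           # subject 3 has no follow-up
  fu <- long[long$time > 0, ]
  X <- traj_basis(fu$time)
  w <- c(0.8, 1.1, 0.6)
  b_all <- solve_iiw_gee(fu$outcome, X, fu$subject_id, w)$beta
  # "dropping" subject 3 changes nothing upstream: it has no assessment rows
  keep <- fu$subject_id %in% c(1, 2)
  b_fu <- solve_iiw_gee(fu$outcome[keep], X[keep, ], fu$subject_id[keep],
                        w[keep])$beta
  expect_identical(b_all, b_fu)
})
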