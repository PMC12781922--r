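test_that("weighted moments match their closed forms", {
  sm <- s_moments("bernoulli", gamma = 0, Lambda0 = 1)
  expect_equal(sm$s0, 1, tolerance = 1e-12)
  expect_equal(sm$s1, 0.5, tolerance = 1e-12)
  expect_equal(sm$s2, 0.5, tolerance = 1e-12)

  # Normal MGF: E(e^{gZ}) = e^{g^2/2}; derivatives give s1, s2
  sn <- s_moments("normal01", gamma = 1, Lambda0 = 1)
  expect_equal(sn$s0, exp(0.5), tolerance = 1e-9)
  expect_equal(sn$s1, exp(0.5), tolerance = 1e-9)
  expect_equal(sn$s2, 2 * exp(0.5), tolerance = 1e-9)

  # Gamma(1,1) MGF: 1/(1-g); s1 = 1/(1-g)^2, s2 = 2/(1-g)^3
  sg <- s_moments("gamma11", gamma = 0.5, Lambda0 = 1)
  expect_equal(sg$s0, 2, tolerance = 1e-9)
  expect_equal(sg$s1, 4, tolerance = 1e-9)
  expect_equal(sg$s2, 16, tolerance = 1e-9)

  expect_error(s_moments("gamma11", gamma = 1.2, Lambda0 = 1), "divergent")
})

test_that("conditioning on follow-up is inert when the weight ignores Z, and
          Jensen's inequality holds throughout", {
  for (d in list(z_dist("bernoulli", 0.3), z_dist("normal01"),
                 z_dist("gamma11"))) {
    sm0 <- s_moments(d, gamma = 0, Lambda0 = 2)
    expect_lt(abs(sm0$s1_star / sm0$s0_star - sm0$s1 / sm0$s0), 1e-10)
    for (g in c(-0.5, 0.2, 0.8)) {
      if (d$name == "gamma11" && g >= 1) next
      sm <- s_moments(d, gamma = g, Lambda0 = 0.7)
      expect_gte(sm$s2 * sm$s0 - sm$s1^2, -1e-12)
      expect_gte(sm$s2_star * sm$s0_star - sm$s1_star^2, -1e-12)
      expect_gt(sm$s0, 0); expect_gt(sm$s0_star, 0)
    }
  }
})

test_that("starred moments agree with plain Monte-Carlo integration", {
  Lambda0 <- 1
  set.seed(99)
  for (dn in c("normal01", "gamma11")) {
    # the Gamma tilt must stay small enough that z^2 e^{gz} has finite
    # Monte-Carlo variance under the Gamma(1,1) tail
    g <- if (dn == "normal01") 0.5 else 0.2
    z <- if (dn == "normal01") rnorm(1e7) else rgamma(1e7, 1, 1)
    w <- 1 - exp(-Lambda0 * exp(g * z))
    pf <- mean(w)
    sm <- s_moments(dn, gamma = g, Lambda0 = Lambda0)
    for (k in 0:2) {
      num <- z^k * exp(g * z) * w
      mc <- mean(num) / pf
      se_mc <- sd(num) / sqrt(length(num)) / pf
      analytic <- switch(k + 1L, sm$s0_star, sm$s1_star, sm$s2_star)
      expect_lt(abs(analytic - mc), 4 * se_mc)
    }
    rm(z, w)
  }
})

test_that("the no-follow-up probability is the Poisson zero mass", {
  expect_equal(no_followup_prob(0, gamma = 0, lambda0 = 0.5, tau = 2),
               exp(-1), tolerance = 1e-12)
  expect_identical(no_followup_prob(c(-2, 0, 3), gamma = 1, lambda0 = 0,
                                    tau = 2), rep(1, 3))
  expect_equal(no_followup_prob(1, gamma = log(2), lambda0 = 0.5, tau = 2),
               exp(-2), tolerance = 1e-12)
})

test_that("the analytic FU bias vanishes at gamma0 = 0, depends on the
          design only through Lambda0, and dies off as Lambda0 grows", {
  for (d in c("bernoulli", "normal01", "gamma11")) {
    for (ord in c("asymptotic", "first")) {
      expect_lt(abs(gamma_bias_closed_form(d, 0, 0.5, 2, order = ord)),
                1e-10)
      b1 <- gamma_bias_closed_form(d, 0.5, lambda0 = 0.5, tau = 2,
                                   order = ord)
      b2 <- gamma_bias_closed_form(d, 0.5, lambda0 = 1, tau = 1,
                                   order = ord)
      expect_lt(abs(b1 - b2), 1e-10)
      expect_lt(b1, 0)  # attenuation for gamma0 > 0
    }
    expect_lt(abs(gamma_bias_closed_form(d, 0.5, lambda0 = 25, tau = 2)),
              1e-6)
  }
})

test_that("the Taylor form approximates the exact asymptotic bias when the
          bias is small", {
  for (d in c("bernoulli", "normal01", "gamma11")) {
    a <- gamma_bias_closed_form(d, 0.05, 0.5, 2, order = "asymptotic")
    f <- gamma_bias_closed_form(d, 0.05, 0.5, 2, order = "first")
    expect_equal(a, f, tolerance = 0.05)
  }
  # at a sizeable bias the two differ visibly but share sign and magnitude
  a <- gamma_bias_closed_form("bernoulli", 0.5, 0.5, 2)
  f <- gamma_bias_closed_form("bernoulli", 0.5, 0.5, 2, order = "first")
  expect_equal(f, -0.2549723, tolerance = 1e-6)
  expect_equal(a, f, tolerance = 0.05)
})

test_that("analytic bias tracks the simulate-and-refit oracle over a
          (gamma0, Lambda0) grid", {
  seed <- 400
  for (g0 in c(0.2, 0.5, 0.8)) {
    for (L0 in c(0.5, 1, 2)) {
      seed <- seed + 1
      mc <- mc_gamma_bias("bernoulli", g0, lambda0 = L0 / 2, tau = 2,
                          n = 2000, n_reps = 50, seed = seed)
      cf <- gamma_bias_closed_form("bernoulli", g0, lambda0 = L0 / 2,
                                   tau = 2)
      expect_lt(abs(cf - mc$bias), 3 * mc$mcse)
    }
  }
})

test_that("first-order outcome-coefficient bias matches hand-derived and
          brute-force oracles on scalar toys", {
  tau <- 2
  # unbiased weights propagate nothing
  expect_identical(
    beta_bias_first_order(tau, function(z) tau * 1.5 * (z - 0.5),
                          function(z) 0, "bernoulli"), 0)
  # outcome mean-independent of Z propagates nothing
  expect_identical(
    beta_bias_first_order(tau, function(z) 0, function(z) -0.2,
                          "bernoulli"), 0)
  # intercept-only, E(Y|Z) = a + bZ, constant gamma-bias g0:
  # bias = -b g0 Var(Z) (hand derivation) for Bernoulli(p)
  b <- 1.5; g0 <- -0.2; p <- 0.5
  got <- beta_bias_first_order(tau, function(z) tau * b * (z - p),
                               function(z) g0, z_dist("bernoulli", p))
  expect_equal(got, -b * g0 * p * (1 - p), tolerance = 1e-10)
  # same toy under a standard Normal covariate: Var(Z) = 1
  got_n <- beta_bias_first_order(tau, function(z) tau * b * z,
                                 function(z) g0, "normal01")
  expect_equal(got_n, -b * g0, tolerance = 1e-8)
  # brute-force expectation oracle (dense numeric sum)
  zs <- seq(-8, 8, by = 1e-3)
  brute <- -sum(tau * b * zs * zs * g0 * dnorm(zs)) * 1e-3 / tau
  expect_equal(got_n, brute, tolerance = 1e-4)
})

test_that("bias curves reproduce the qualitative design story", {
  lam_grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  bc_l <- bias_curve("lambda0", "bernoulli", grid = lam_grid)
  expect_true(all(diff(abs(bc_l$bias)) < 0))

  bc_t <- bias_curve("tau", "bernoulli", grid = c(1, 1.5, 2, 2.5, 3))
  expect_true(all(diff(abs(bc_t$bias)) < 0))

  bc_p <- bias_curve("lambda0_tau_fixed_product", "bernoulli",
                     grid = lam_grid)
  expect_lt(max(bc_p$bias) - min(bc_p$bias), 1e-10)
  expect_equal(bc_p$lambda0 * bc_p$tau, rep(1, 5), tolerance = 1e-12)

  bc_g <- bias_curve("gamma_fixed_visits", "bernoulli",
                     grid = c(0, 0.2, 0.4, 0.6, 0.8))
  expect_identical(bc_g$bias[1], 0)
  # expected assessments held at the base value along the whole curve
  ev <- vapply(seq_len(nrow(bc_g)), function(i) {
    sm <- s_moments("bernoulli", bc_g$gamma0[i], Lambda0 = 1)
    bc_g$lambda0[i] * sm$s0
  }, 0)
  expect_equal(ev, rep(ev[1], 5), tolerance = 1e-10)
  # bias grows in magnitude as the dependence strengthens
  expect_true(all(diff(abs(bc_g$bias)) > 0))
})
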