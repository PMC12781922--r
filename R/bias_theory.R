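#' Covariate distribution for the time-invariant bias theory
#'
#' @param name `"bernoulli"`, `"normal01"` (standard Normal) or `"gamma11"`
#'   (Gamma with shape 1, rate 1).
#' @param p success probability for the Bernoulli case.
#' @return An object of class `"z_dist"`.
#' @export
z_dist <- function(name = c("bernoulli", "normal01", "gamma11"), p = 0.5) {
  name <- match.arg(name)
  if (name == "bernoulli") stopifnot(p > 0, p < 1)
  structure(list(name = name, p = p), class = "z_dist")
}

as_z_dist <- function(dist, p = 0.5) {
  if (inherits(dist, "z_dist")) dist else z_dist(dist, p = p)
}

# E( Z^k exp(tilt * Z) * w(Z) ), with w(z) = 1 unconditionally or
# w(z) = 1 - exp(-Lambda0 * exp(gamma0 * z)) for the "has follow-up" weight.
# Bernoulli: exact sum.  Normal / Gamma: adaptive quadrature on the full
# (transformed-infinite) domain, absolute tolerance 1e-10.
zmom <- function(dist, k, tilt, gamma0 = NULL, Lambda0 = NULL,
                 conditional = FALSE) {
  dist <- as_z_dist(dist)
  w <- if (conditional) {
    stopifnot(Lambda0 > 0)
    function(z) 1 - exp(-Lambda0 * exp(gamma0 * z))
  } else {
    function(z) rep(1, length(z))
  }
  switch(dist$name,
    bernoulli = {
      p <- dist$p
      (1 - p) * (0^k) * w(0) + p * exp(tilt) * w(1)
    },
    normal01 = {
      # single exp() keeps the tilted-density product finite in the tails
      stats::integrate(function(z)
        z^k * exp(tilt * z - z^2 / 2 - log(2 * pi) / 2) * w(z),
        -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-10,
        subdivisions = 400L)$value
    },
    gamma11 = {
      if (tilt >= 1)
        stop("divergent moment: Gamma(1,1) requires gamma < 1")
      stats::integrate(function(z) z^k * exp((tilt - 1) * z) * w(z),
                       0, Inf, rel.tol = 1e-12, abs.tol = 1e-10,
                       subdivisions = 400L)$value
    })
}

#' Weighted covariate moments, unconditional and given follow-up
#'
#' Computes \eqn{s_k(\gamma) = E(Z^k e^{\gamma Z})} for \eqn{k = 0, 1, 2}
#' and their starred analogues conditional on at least one follow-up
#' assessment, \eqn{s_k^*(\gamma) = E(Z^k e^{\gamma Z} \mid N(\tau) > 0)}.
#' With a time-invariant covariate and baseline intensity the assessment
#' count is \eqn{N(\tau) \mid Z \sim \mathrm{Poisson}(\Lambda_0 e^{\gamma Z})},
#' so \eqn{P(N(\tau) > 0 \mid Z) = 1 - e^{-\Lambda_0 e^{\gamma Z}}} and the
#' starred moments follow from the Poisson zero-count identity.  Bernoulli
#' moments are exact sums; Normal and Gamma moments use adaptive quadrature
#' to absolute tolerance `1e-10`.
#'
#' @param dist a [z_dist()] (or its name).
#' @param gamma scalar log intensity ratio.
#' @param Lambda0 cumulative baseline intensity \eqn{\lambda_0 \tau > 0}.
#' @param p Bernoulli success probability when `dist` is given by name.
#' @return An object of class `"s_moments"`: list with `s0, s1, s2`,
#'   `s0_star, s1_star, s2_star`, `p_followup`, `dist`, `gamma`, `Lambda0`.
#' @examples
#' s_moments("bernoulli", gamma = 0, Lambda0 = 1)
#' @export
s_moments <- function(dist, gamma, Lambda0, p = 0.5) {
  dist <- as_z_dist(dist, p = p)
  stopifnot(Lambda0 > 0)
  s <- vapply(0:2, function(k) zmom(dist, k, tilt = gamma), 0)
  pf <- zmom(dist, 0, tilt = 0, gamma0 = gamma, Lambda0 = Lambda0,
             conditional = TRUE)
  ss <- vapply(0:2, function(k)
    zmom(dist, k, tilt = gamma, gamma0 = gamma, Lambda0 = Lambda0,
         conditional = TRUE) / pf, 0)
  structure(
    list(s0 = s[1], s1 = s[2], s2 = s[3],
         s0_star = ss[1], s1_star = ss[2], s2_star = ss[3],
         p_followup = pf, dist = dist, gamma = gamma, Lambda0 = Lambda0),
    class = "s_moments")
}

#' @export
print.s_moments <- function(x, ...) {
  cat(sprintf("Weighted moments, %s, gamma = %g, Lambda0 = %g\n",
              x$dist$name, x$gamma, x$Lambda0))
  cat(sprintf("  s0 = %.6g   s1 = %.6g   s2 = %.6g\n", x$s0, x$s1, x$s2))
  cat(sprintf("  s0* = %.6g  s1* = %.6g  s2* = %.6g  (P(N > 0) = %.4f)\n",
              x$s0_star, x$s1_star, x$s2_star, x$p_followup))
  invisible(x)
}

#' Probability of no follow-up assessments
#'
#' For a time-invariant covariate value `z` the number of assessments is
#' Poisson with mean \eqn{\lambda_0 \tau e^{\gamma z}}, so
#' \eqn{P(N(\tau) = 0) = \exp(-\lambda_0 \tau e^{\gamma z})}.
#'
#' @param z covariate value(s).
#' @param gamma log intensity ratio.
#' @param lambda0 baseline intensity, `>= 0`.
#' @param tau follow-up horizon, `> 0`.
#' @return Probability vector.
#' @examples
#' no_followup_prob(0, gamma = 0, lambda0 = 0.5, tau = 2)  # exp(-1)
#' @export
no_followup_prob <- function(z, gamma, lambda0, tau) {
  stopifnot(lambda0 >= 0, tau > 0)
  exp(-lambda0 * tau * exp(gamma * z))
}

#' Analytic bias of the intensity coefficient under follow-up-only fitting
#'
#' When the intensity covariate \eqn{Z} and baseline intensity are
#' time-invariant, dropping subjects with no follow-up changes the risk-set
#' composition of the partial likelihood while leaving the events untouched,
#' and the large-sample limit of \eqn{\hat\gamma^{FU}} can be computed
#' analytically.  Two evaluations are offered:
#'
#' \describe{
#'   \item{`order = "asymptotic"` (default)}{the exact population limit:
#'     the root \eqn{\gamma^*} of
#'     \eqn{m_1(\gamma^*)/m_0(\gamma^*) = s_1(\gamma_0)/s_0(\gamma_0)} with
#'     \eqn{m_k(\gamma) = E(Z^k e^{\gamma Z}(1 - e^{-\Lambda_0 e^{\gamma_0 Z}}))};
#'     the left side is the risk-set covariate average among subjects with
#'     follow-up, the right side the event-weighted covariate average, which
#'     the omission leaves unchanged.  The bias is \eqn{\gamma^* - \gamma_0}.}
#'   \item{`order = "first"`}{the one-step Taylor expansion of that fixed
#'     point about \eqn{\gamma_0}:
#'     \eqn{-(s_2^*/s_0^* - (s_1^*/s_0^*)^2)^{-1}(s_1^*/s_0^* - s_1/s_0)},
#'     whose denominator is the conditional variance of \eqn{Z} under the
#'     tilted follow-up distribution.}
#' }
#'
#' Both versions depend on \eqn{\lambda_0} and \eqn{\tau} only through
#' \eqn{\Lambda_0 = \lambda_0\tau}, vanish at \eqn{\gamma_0 = 0}, and decay
#' to zero as \eqn{\Lambda_0 \to \infty}.  For \eqn{\gamma_0 > 0} the bias
#' is negative: the subjects removed are disproportionately low-\eqn{Z}, so
#' the risk sets over-represent high \eqn{Z} and the coefficient is
#' attenuated.
#'
#' @param dist a [z_dist()] or its name.
#' @param gamma0 true log intensity ratio.
#' @param lambda0 baseline intensity, `> 0`.
#' @param tau follow-up horizon, `> 0`.
#' @param order `"asymptotic"` (exact population limit) or `"first"`
#'   (first-order Taylor value).
#' @param p Bernoulli success probability when `dist` is given by name.
#' @return Scalar bias \eqn{E(\hat\gamma^{FU}) - \gamma_0} (large-sample).
#' @seealso [mc_gamma_bias()] for the simulation oracle, [bias_curve()].
#' @examples
#' gamma_bias_closed_form("bernoulli", gamma0 = 0.5, lambda0 = 0.5, tau = 2)
#' @export
gamma_bias_closed_form <- function(dist, gamma0, lambda0, tau,
                                   order = c("asymptotic", "first"),
                                   p = 0.5) {
  order <- match.arg(order)
  dist <- as_z_dist(dist, p = p)
  stopifnot(lambda0 > 0, tau > 0)
  Lambda0 <- lambda0 * tau
  if (order == "first") {
    sm <- s_moments(dist, gamma0, Lambda0)
    r1s <- sm$s1_star / sm$s0_star
    v <- sm$s2_star / sm$s0_star - r1s^2
    if (v < 1e-12) stop("singular bracket: degenerate covariate distribution")
    return(-(r1s - sm$s1 / sm$s0) / v)
  }
  target <- zmom(dist, 1, tilt = gamma0) / zmom(dist, 0, tilt = gamma0)
  score <- function(g) {
    m0 <- zmom(dist, 0, tilt = g, gamma0 = gamma0, Lambda0 = Lambda0,
               conditional = TRUE)
    m1 <- zmom(dist, 1, tilt = g, gamma0 = gamma0, Lambda0 = Lambda0,
               conditional = TRUE)
    m1 / m0 - target
  }
  f0 <- score(gamma0)
  if (abs(f0) < 1e-10) return(0)  # below the quadrature resolution
  # risk-set average is increasing in g, so bracket downward from gamma0
  upper_cap <- if (dist$name == "gamma11") 1 - 1e-8 else Inf
  lo <- gamma0; hi <- gamma0
  step <- max(0.25, abs(gamma0))
  if (f0 > 0) {
    repeat {
      lo <- lo - step
      if (score(lo) < 0) break
      step <- step * 2
      if (lo < gamma0 - 60) stop("failed to bracket the asymptotic root")
    }
  } else {
    repeat {
      hi <- min(hi + step, upper_cap)
      if (score(hi) > 0) break
      if (hi >= upper_cap - 1e-12)
        stop("failed to bracket the asymptotic root")
      step <- step * 2
    }
  }
  root <- uniroot(score, c(lo, hi), tol = 1e-13)$root
  root - gamma0
}

#' First-order transfer of intensity-coefficient bias to the outcome model
#'
#' Evaluates the leading-order bias of the outcome-model coefficients when
#' the weights are built from a biased intensity coefficient:
#' \deqn{-\left(\int_0^\tau E(X'X)\,dt\right)^{-1}
#'   E\left[ m(Z)\, Z\, g(Z) \right],}
#' where \eqn{m(Z) = \int_0^\tau E(X'(Y - X\beta_0) \mid Z)\,dt} and
#' \eqn{g(Z) = E(\hat\gamma^{FU} - \gamma_0 \mid Z)}.  The outer expectation
#' over the covariate distribution is an exact sum (Bernoulli) or adaptive
#' quadrature (Normal, Gamma).
#'
#' @param xTx_integral the \eqn{p \times p} matrix \eqn{\int_0^\tau E(X'X)dt}.
#' @param cond_moment function of `z` returning the length-`p` vector
#'   \eqn{m(z)}.
#' @param gamma_bias_given_z function of `z` returning \eqn{g(z)}.
#' @param dist a [z_dist()] or its name.
#' @param p Bernoulli success probability when `dist` is given by name.
#' @return Length-`p` bias vector.
#' @export
beta_bias_first_order <- function(xTx_integral, cond_moment,
                                  gamma_bias_given_z, dist, p = 0.5) {
  dist <- as_z_dist(dist, p = p)
  xTx_integral <- as.matrix(xTx_integral)
  pdim <- nrow(xTx_integral)
  integrand <- function(z) cond_moment(z) * z * gamma_bias_given_z(z)
  ev <- switch(dist$name,
    bernoulli = (1 - dist$p) * integrand(0) + dist$p * integrand(1),
    normal01 = vapply(seq_len(pdim), function(j)
      stats::integrate(function(z)
        vapply(z, function(zz) integrand(zz)[j], 0) * stats::dnorm(z),
        -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value, 0),
    gamma11 = vapply(seq_len(pdim), function(j)
      stats::integrate(function(z)
        vapply(z, function(zz) integrand(zz)[j], 0) * exp(-z),
        0, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value, 0))
  drop(-solve(xTx_integral, ev))
}

#' Bias curves along the study-design axes
#'
#' Evaluates [gamma_bias_closed_form()] along one of four axes:
#' \describe{
#'   \item{`"lambda0"`}{vary the baseline intensity at fixed \eqn{\tau},
#'     \eqn{\gamma_0};}
#'   \item{`"tau"`}{vary the follow-up horizon at fixed \eqn{\lambda_0},
#'     \eqn{\gamma_0};}
#'   \item{`"lambda0_tau_fixed_product"`}{vary \eqn{\lambda_0} while
#'     \eqn{\tau} compensates to hold \eqn{\Lambda_0 = \lambda_0\tau} fixed
#'     (the curve is constant: the bias depends on the design only through
#'     \eqn{\Lambda_0});}
#'   \item{`"gamma_fixed_visits"`}{vary \eqn{\gamma_0} while \eqn{\lambda_0}
#'     is lowered to hold the expected number of assessments
#'     \eqn{\lambda_0 \tau E(e^{\gamma Z})} at its value under the base
#'     parameters.}
#' }
#'
#' @param axis one of the four axis names above.
#' @param dist a [z_dist()] or its name.
#' @param grid abscissa values (\eqn{\lambda_0}, \eqn{\tau}, or
#'   \eqn{\gamma_0} values depending on the axis).
#' @param gamma0,lambda0,tau base parameters.
#' @param order passed to [gamma_bias_closed_form()].
#' @param p Bernoulli success probability when `dist` is given by name.
#' @return An object of class `"bias_curve"`: a data frame with columns
#'   `axis`, `value`, `lambda0`, `tau`, `gamma0`, `bias`.
#' @examples
#' bias_curve("lambda0", "bernoulli", grid = c(0.1, 0.5, 0.9))
#' @export
bias_curve <- function(axis = c("lambda0", "tau", "lambda0_tau_fixed_product",
                                "gamma_fixed_visits"),
                       dist, grid, gamma0 = 0.5, lambda0 = 0.5, tau = 2,
                       order = c("asymptotic", "first"), p = 0.5) {
  axis <- match.arg(axis)
  order <- match.arg(order)
  dist <- as_z_dist(dist, p = p)
  stopifnot(is.numeric(grid), length(grid) >= 1, all(is.finite(grid)))
  pts <- switch(axis,
    lambda0 = data.frame(value = grid, lambda0 = grid, tau = tau,
                         gamma0 = gamma0),
    tau = data.frame(value = grid, lambda0 = lambda0, tau = grid,
                     gamma0 = gamma0),
    lambda0_tau_fixed_product = data.frame(
      value = grid, lambda0 = grid, tau = lambda0 * tau / grid,
      gamma0 = gamma0),
    gamma_fixed_visits = {
      visits <- lambda0 * zmom(dist, 0, tilt = gamma0)
      data.frame(value = grid,
                 lambda0 = visits / vapply(grid, function(g)
                   zmom(dist, 0, tilt = g), 0),
                 tau = tau, gamma0 = grid)
    })
  pts$bias <- mapply(function(l0, tv, g0)
    gamma_bias_closed_form(dist, g0, l0, tv, order = order),
    pts$lambda0, pts$tau, pts$gamma0)
  pts <- cbind(axis = axis, pts)
  class(pts) <- c("bias_curve", "data.frame")
  pts
}

#' @export
print.bias_curve <- function(x, ...) {
  cat(sprintf("Analytic bias of the FU intensity coefficient along `%s`\n",
              x$axis[1]))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
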