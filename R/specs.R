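#' Outcome-model specification
#'
#' Describes the marginal mean trajectory and the within-subject error
#' structure of the simulated disease-activity outcome
#' \deqn{Y_i(t) = \mu(t) + u_i + v_i t + \epsilon_i(t),}
#' where \eqn{(u_i, v_i)} is a bivariate Normal random intercept/slope pair
#' and \eqn{\epsilon_i(t)} is a Gaussian residual process with exponential
#' correlation and a nugget.
#'
#' Two data-generating mechanisms are supported:
#' \describe{
#'   \item{mechanism 1}{time-varying mean
#'     \eqn{\mu_{01}(t) = 3.3 + 4 X_1(t) + 10.5 X_2(t)} with
#'     \eqn{X_1(t) = 1/(1+t)^2} and \eqn{X_2(t) = \log(1+t)/(1+t)^2};}
#'   \item{mechanism 2}{constant mean \eqn{\mu_{02} = 3.3}.}
#' }
#'
#' The residual covariance convention is
#' \eqn{\mathrm{Cov}(\epsilon(s), \epsilon(t)) =
#' \sigma_\epsilon^2 (1 - \mathrm{nugget}) \exp(-|s-t|/\mathrm{range})}
#' for \eqn{s \neq t}, with \eqn{\sigma_\epsilon^2} on the diagonal, i.e. the
#' nugget is the proportion of the zero-lag variance that is uncorrelated
#' across arbitrarily close time points.
#'
#' @param mechanism 1 (time-varying mean) or 2 (constant mean).
#' @param beta0 optional length-3 coefficient vector (intercept, coefficient
#'   on \eqn{X_1(t)}, coefficient on \eqn{X_2(t)}); defaults to the
#'   mechanism's canonical values `c(3.3, 4, 10.5)` or `c(3.3, 0, 0)`.
#' @param sigma_u SD of the random intercept.
#' @param sigma_v SD of the random slope (per unit time).
#' @param rho_uv intercept-slope correlation, in (-1, 1).
#' @param sigma_eps residual SD.
#' @param range exponential-correlation range, in time units.
#' @param nugget proportion of residual variance that is uncorrelated,
#'   in \[0, 1).
#'
#' @return An object of class `"outcome_spec"`.
#' @seealso [visit_spec()], [simulate_cohort()], [mean_trajectory()]
#' @examples
#' spec <- outcome_spec(mechanism = 1)
#' mean_trajectory(0:2, spec$beta0)
#' @export
outcome_spec <- function(mechanism = 1, beta0 = NULL,
                         sigma_u = 1.6, sigma_v = 1.2, rho_uv = -0.7,
                         sigma_eps = 1.5, range = 0.5, nugget = 0.4) {
  if (!mechanism %in% c(1, 2)) stop("`mechanism` must be 1 or 2")
  if (is.null(beta0)) {
    beta0 <- if (mechanism == 1) c(3.3, 4, 10.5) else c(3.3, 0, 0)
  }
  if (length(beta0) != 3L || !is.numeric(beta0) || anyNA(beta0))
    stop("`beta0` must be a numeric coefficient triple")
  # zero SDs are admitted so noise components can be switched off singly
  stopifnot(sigma_u >= 0, sigma_v >= 0, sigma_eps >= 0,
            abs(rho_uv) < 1, range > 0, nugget >= 0, nugget < 1)
  structure(
    list(mechanism = as.integer(mechanism), beta0 = as.numeric(beta0),
         sigma_u = sigma_u, sigma_v = sigma_v, rho_uv = rho_uv,
         sigma_eps = sigma_eps, range = range, nugget = nugget),
    class = "outcome_spec")
}

#' Visit-process specification
#'
#' Describes the proportional assessment-intensity model
#' \deqn{\lambda_i(t) = \lambda_0 \exp(\gamma_0 Z_i(t)),}
#' where by default \eqn{Z_i(t) = \log(1 + Y^+)} with \eqn{Y^+} the last
#' observed outcome clamped below at 0.  The clamp keeps the covariate
#' defined when a Normally-simulated outcome falls below \eqn{-1}; the
#' motivating disease-activity score is bounded below by zero.
#'
#' @param lambda0 baseline intensity (assessments per unit time), `>= 0`.
#' @param gamma0 log intensity ratio per unit of `Z`.
#' @param tau administrative follow-up horizon (time units), `> 0`.
#' @param covariate_map function mapping the last observed outcome to the
#'   intensity covariate `Z`; the default is `log(1 + pmax(y, 0))`.
#'
#' @return An object of class `"visit_spec"`.
#' @seealso [outcome_spec()], [simulate_cohort()]
#' @export
visit_spec <- function(lambda0 = 0.5, gamma0 = 0.5, tau = 2,
                       covariate_map = NULL) {
  stopifnot(lambda0 >= 0, tau > 0, is.numeric(gamma0), length(gamma0) == 1L)
  if (is.null(covariate_map)) covariate_map <- function(y) log1p(pmax(y, 0))
  stopifnot(is.function(covariate_map))
  structure(
    list(lambda0 = lambda0, gamma0 = gamma0, tau = tau,
         covariate_map = covariate_map),
    class = "visit_spec")
}

#' Trajectory basis and mean trajectory
#'
#' `traj_basis()` evaluates the design row \eqn{(1, X_1(t), X_2(t))} with
#' \eqn{X_1(t) = 1/(1+t)^2}, \eqn{X_2(t) = \log(1+t)/(1+t)^2}.
#' `mean_trajectory()` evaluates \eqn{X(t)\beta} for a coefficient triple.
#'
#' @param t time(s), `>= 0`.
#' @return `traj_basis()`: a `length(t) x 3` matrix; `mean_trajectory()`:
#'   a numeric vector.
#' @examples
#' mean_trajectory(0, c(3.3, 4, 10.5))  # 7.3 at baseline
#' @export
traj_basis <- function(t) {
  cbind("(Intercept)" = rep(1, length(t)),
        X1 = 1 / (1 + t)^2,
        X2 = log(1 + t) / (1 + t)^2)
}

#' @rdname traj_basis
#' @param beta coefficient triple (intercept, coefficient on `X1`,
#'   coefficient on `X2`).
#' @export
mean_trajectory <- function(t, beta) {
  stopifnot(length(beta) == 3L)
  drop(traj_basis(t) %*% beta)
}

#' True area under the mean trajectory
#'
#' Integrates the data-generating mean \eqn{\mu(t)} over \eqn{[0, \tau]} by
#' adaptive quadrature.  Under mechanism 2 this equals \eqn{3.3\tau}
#' exactly; under mechanism 1 it matches the exact antiderivative used by
#' [auc_from_beta()].
#'
#' @param tau upper limit of integration, `> 0`.
#' @param mechanism 1 or 2, or an [outcome_spec()].
#' @return The integral, a scalar.
#' @export
true_auc <- function(tau, mechanism = 1) {
  stopifnot(tau > 0)
  beta <- if (inherits(mechanism, "outcome_spec")) mechanism$beta0
          else outcome_spec(mechanism)$beta0
  stats::integrate(function(t) mean_trajectory(t, beta), 0, tau,
                   rel.tol = 1e-12, abs.tol = 1e-12)$value
}

#' @export
print.outcome_spec <- function(x, ...) {
  cat(sprintf(
    "Outcome model (mechanism %d): beta0 = (%g, %g, %g)\n", x$mechanism,
    x$beta0[1], x$beta0[2], x$beta0[3]))
  cat(sprintf(
    "  random effects: sigma_u = %g, sigma_v = %g, rho = %g\n",
    x$sigma_u, x$sigma_v, x$rho_uv))
  cat(sprintf(
    "  residuals: sigma_eps = %g, range = %g, nugget = %g\n",
    x$sigma_eps, x$range, x$nugget))
  invisible(x)
}

#' @export
print.visit_spec <- function(x, ...) {
  cat(sprintf(
    "Visit process: lambda0 = %g, gamma0 = %g, tau = %g\n",
    x$lambda0, x$gamma0, x$tau))
  invisible(x)
}
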