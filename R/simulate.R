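#' Waiting time to the next assessment
#'
#' Draws the gap to the next visit for a subject whose last observed outcome
#' is `last_outcome`.  Because the intensity covariate changes only at
#' visits, the intensity is constant between visits and the gap is exactly
#' exponential with rate
#' \eqn{\lambda_0 \exp(\gamma_0 Z)}, \eqn{Z} = `covariate_map(last_outcome)`;
#' no thinning is needed.
#'
#' @param last_outcome the outcome value at the most recent assessment
#'   (the baseline outcome before any follow-up visit has occurred).
#' @param spec a [visit_spec()].
#' @return A single exponential waiting time; `Inf` when `lambda0 == 0`.
#' @examples
#' simulate_visit_gap(3, visit_spec(lambda0 = 0))  # Inf
#' @export
simulate_visit_gap <- function(last_outcome, spec) {
  stopifnot(inherits(spec, "visit_spec"), is.finite(last_outcome))
  if (spec$lambda0 == 0) return(Inf)
  rate <- spec$lambda0 * exp(spec$gamma0 * spec$covariate_map(last_outcome))
  rexp(1L, rate)
}

#' Draw an outcome at a new time, conditional on the residual history
#'
#' Returns \eqn{\mu(t) + u + v t + \epsilon(t)} where \eqn{\epsilon(t)} is
#' drawn from the Gaussian conditional distribution given the residuals
#' already realised at earlier times, under the exponential-correlation
#' covariance of the [outcome_spec()].
#'
#' @param t assessment time, `>= 0` and later than all history times.
#' @param history a list with numeric components `times` and `resid`
#'   holding the residual process realised so far (possibly empty).
#' @param u,v the subject's random intercept and slope.
#' @param spec an [outcome_spec()].
#' @return A list with elements `outcome`, `resid` (the new residual), and
#'   `history` (the input history with the new pair appended).
#' @export
sample_outcome_at <- function(t, history, u, v, spec) {
  stopifnot(inherits(spec, "outcome_spec"), is.finite(t), t >= 0)
  times <- history$times
  if (length(times) && (any(t <= times) || is.unsorted(times, strictly = TRUE)))
    stop("history times must be strictly increasing and earlier than `t`")
  s2 <- spec$sigma_eps^2
  if (s2 == 0) {
    eps <- 0
  } else if (!length(times)) {
    eps <- rnorm(1L, 0, spec$sigma_eps)
  } else {
    cv <- s2 * (1 - spec$nugget) * exp(-abs(t - times) / spec$range)
    D <- abs(outer(times, times, "-"))
    S <- s2 * (1 - spec$nugget) * exp(-D / spec$range)
    diag(S) <- s2
    sol <- solve(S, cbind(history$resid, cv))
    cmean <- sum(cv * sol[, 1L])
    cvar <- max(s2 - sum(cv * sol[, 2L]), 0)
    eps <- rnorm(1L, cmean, sqrt(cvar))
  }
  list(outcome = mean_trajectory(t, spec$beta0) + u + v * t + eps,
       resid = eps,
       history = list(times = c(times, t), resid = c(history$resid, eps)))
}

#' Simulate a cohort with outcome-dependent assessment times
#'
#' Generates `n` subjects.  For each, a random intercept/slope pair is drawn,
#' the baseline outcome is simulated at \eqn{t = 0}, and then visit-gap
#' sampling (intensity driven by the last observed outcome) alternates with
#' outcome sampling (conditional on the residual history) until the horizon
#' \eqn{\tau} is passed.  The baseline measurement is observed for everyone
#' but does not count as a follow-up assessment; subjects whose first gap
#' exceeds \eqn{\tau} are retained with an empty visit list.
#'
#' One root seed spawns an independent seed per subject, so a cohort is
#' reproducible subject-by-subject regardless of execution order.
#'
#' @param n number of subjects, `>= 1`.
#' @param outcome_spec an [outcome_spec()].
#' @param visit_spec a [visit_spec()].
#' @param seed integer root seed.
#' @return An object of class `"iiw_cohort"`: a list with `subjects` (each a
#'   list with `subject_id`, `baseline_y`, `visit_times`, `visit_outcomes`,
#'   `u`, `v`), the two specs, the seed, and `n_clamped`, the number of
#'   intensity-covariate evaluations at which a negative outcome was clamped
#'   to zero.  Use [as.data.frame()] for the long visits format.
#' @examples
#' coh <- simulate_cohort(5, outcome_spec(2), visit_spec(tau = 2), seed = 1)
#' head(as.data.frame(coh))
#' @export
simulate_cohort <- function(n, outcome_spec, visit_spec, seed) {
  stopifnot(n >= 1, inherits(outcome_spec, "outcome_spec"),
            inherits(visit_spec, "visit_spec"))
  set.seed(seed)
  subj_seeds <- sample.int(2147483646L, n)
  os <- outcome_spec; vs <- visit_spec
  tau <- vs$tau
  chol_uv <- local({
    su <- os$sigma_u; sv <- os$sigma_v; r <- os$rho_uv
    matrix(c(su, 0, r * sv, sqrt(1 - r^2) * sv), 2L, 2L, byrow = TRUE)
  })
  n_clamped <- 0L
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subj_seeds[i])
    uv <- drop(chol_uv %*% rnorm(2L))
    u <- uv[1L]; v <- uv[2L]
    base <- sample_outcome_at(0, list(times = numeric(), resid = numeric()),
                              u, v, os)
    hist <- base$history
    y_last <- base$outcome
    t_cur <- 0
    vt <- numeric(); vy <- numeric()
    repeat {
      if (y_last < 0) n_clamped <- n_clamped + 1L
      gap <- simulate_visit_gap(y_last, vs)
      t_cur <- t_cur + gap
      if (t_cur > tau) break
      draw <- sample_outcome_at(t_cur, hist, u, v, os)
      hist <- draw$history
      y_last <- draw$outcome
      vt <- c(vt, t_cur); vy <- c(vy, y_last)
    }
    subjects[[i]] <- list(subject_id = i, baseline_y = base$outcome,
                          visit_times = vt, visit_outcomes = vy,
                          u = u, v = v)
  }
  structure(list(subjects = subjects, outcome_spec = os, visit_spec = vs,
                 seed = seed, n = n, n_clamped = n_clamped),
            class = "iiw_cohort")
}

#' @export
print.iiw_cohort <- function(x, ...) {
  nv <- vapply(x$subjects, function(s) length(s$visit_times), 0L)
  cat(sprintf("Simulated cohort: %d subjects, %d follow-up assessments\n",
              x$n, sum(nv)))
  cat(sprintf("  zero-follow-up subjects: %d (%.1f%%)\n",
              sum(nv == 0L), 100 * mean(nv == 0L)))
  cat(sprintf("  lambda0 = %g, gamma0 = %g, tau = %g, seed = %d\n",
              x$visit_spec$lambda0, x$visit_spec$gamma0, x$visit_spec$tau,
              x$seed))
  invisible(x)
}

#' Long visits data frame for a simulated cohort
#'
#' One row per assessment, including a `time = 0` baseline row for every
#' subject; a subject with no follow-up contributes only its baseline row.
#'
#' @param x an `"iiw_cohort"`.
#' @param ... unused.
#' @return A data frame with columns `subject_id`, `time`, `outcome`.
#' @export
as.data.frame.iiw_cohort <- function(x, ...) {
  nv <- vapply(x$subjects, function(s) length(s$visit_times), 0L)
  data.frame(
    subject_id = rep.int(vapply(x$subjects, `[[`, 0L, "subject_id"), nv + 1L),
    time = unlist(lapply(x$subjects, function(s) c(0, s$visit_times)),
                  use.names = FALSE),
    outcome = unlist(lapply(x$subjects,
                            function(s) c(s$baseline_y, s$visit_outcomes)),
                     use.names = FALSE))
}
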