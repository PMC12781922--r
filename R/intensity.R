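#' Fit the proportional assessment-intensity model
#'
#' Maximises the Andersen-Gill partial likelihood (Breslow tie handling) on
#' counting-process data.  Under `scheme = "EV"` everyone contributes their
#' at-risk intervals; under `scheme = "FU"` every subject with zero events
#' is removed entirely (all of their rows) before fitting, reproducing the
#' common practice of dropping patients with no follow-up assessments.
#' Dropping those subjects changes the risk sets but never the event times,
#' which is the source of the omission bias this package studies.
#'
#' A subject is at risk on the half-open interval `(start, stop]`, so no
#' interval is double-counted at a visit time.  The censored tail interval
#' after a subject's last visit is always included: it carries risk-set
#' information even though it carries no event.
#'
#' @param rows a counting-process data frame with columns `subject_id`,
#'   `start`, `stop`, `event` and one or more covariate columns (any column
#'   not among the first four is treated as a covariate).
#' @param scheme `"EV"` (everyone) or `"FU"` (follow-up only).
#' @param tol convergence tolerance passed to the partial-likelihood
#'   maximiser.
#' @param max_iter maximum Newton iterations.
#' @return An object of class `"intensity_fit"` with components `gamma`
#'   (named coefficient vector), `vcov` (observed-information covariance),
#'   `loglik`, `converged`, `n_iter`, `scheme`, `n_subjects`, `n_events`,
#'   `flags` (character vector of fitter warnings, e.g. separation), and
#'   the underlying `coxph` fit.
#' @seealso [compute_weights()], [build_counting_process()]
#' @export
fit_intensity <- function(rows, scheme = c("EV", "FU"),
                          tol = 1e-9, max_iter = 50L) {
  scheme <- match.arg(scheme)
  rows <- as.data.frame(rows)
  need <- c("subject_id", "start", "stop", "event")
  if (!all(need %in% names(rows)))
    stop("counting-process data must have columns subject_id, start, stop, event")
  zcols <- setdiff(names(rows), need)
  if (!length(zcols)) stop("no covariate columns found")
  if (scheme == "FU") {
    ev_by_subj <- tapply(rows$event, rows$subject_id, sum)
    keep <- names(ev_by_subj)[ev_by_subj > 0]
    rows <- rows[rows$subject_id %in% keep, , drop = FALSE]
  }
  if (!nrow(rows) || sum(rows$event) == 0) stop("empty event set")
  fml <- stats::reformulate(zcols, response = quote(Surv(start, stop, event)))
  flags <- character()
  fit <- withCallingHandlers(
    coxph(fml, data = rows, ties = "breslow",
          control = coxph.control(eps = tol, iter.max = max_iter)),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- fit$iter < max_iter &&
    !any(grepl("infinite|converge|singular", flags, ignore.case = TRUE))
  structure(
    list(gamma = coef(fit), vcov = vcov(fit),
         loglik = unname(fit$loglik[2L]),
         converged = converged, n_iter = fit$iter, scheme = scheme,
         n_subjects = length(unique(rows$subject_id)),
         n_events = sum(rows$event), flags = flags, fit = fit),
    class = "intensity_fit")
}

#' @export
print.intensity_fit <- function(x, ...) {
  cat(sprintf("Assessment-intensity fit (scheme %s): %d subjects, %d events\n",
              x$scheme, x$n_subjects, x$n_events))
  se <- sqrt(diag(as.matrix(x$vcov)))
  tab <- cbind(`log intensity ratio` = x$gamma, SE = se)
  print(round(tab, 4))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.intensity_fit <- function(object, ...) object$gamma

#' @export
vcov.intensity_fit <- function(object, ...) object$vcov

#' @export
logLik.intensity_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$gamma), class = "logLik")
}

#' Inverse-intensity weights at the observed assessments
#'
#' The weight attached to the assessment of subject \eqn{i} at time \eqn{t}
#' is \eqn{\exp(-Z_i(t)\hat\gamma)} — exactly the factor appearing in the
#' weighted estimating equations.  No baseline-hazard term enters and no
#' stabilisation is applied, so the baseline intensity never needs to be
#' estimated for weighting.
#'
#' @param fit an [fit_intensity()] result.
#' @param rows the counting-process data whose `event = 1` rows are the
#'   observed assessments.
#' @return A data frame with columns `subject_id`, `time` (the assessment
#'   time), and `weight`.
#' @export
compute_weights <- function(fit, rows) {
  stopifnot(inherits(fit, "intensity_fit"))
  if (!fit$converged) stop("intensity fit did not converge; refusing weights")
  rows <- as.data.frame(rows)
  ev <- rows[rows$event == 1, , drop = FALSE]
  zcols <- names(fit$gamma)
  if (!all(zcols %in% names(ev))) stop("missing covariate column at event times")
  zm <- as.matrix(ev[, zcols, drop = FALSE])
  if (anyNA(zm)) stop("missing covariate value at an event time")
  data.frame(subject_id = ev$subject_id, time = ev$stop,
             weight = exp(-drop(zm %*% fit$gamma)))
}

#' Breslow cumulative baseline intensity (diagnostic)
#'
#' The weights never require \eqn{\Lambda_0(t)}; this estimator is provided
#' only to inspect the fitted assessment process.
#'
#' @param fit an [fit_intensity()] result.
#' @return A data frame with columns `time` and `cumhaz`.
#' @export
baseline_cumhaz <- function(fit) {
  stopifnot(inherits(fit, "intensity_fit"))
  bh <- basehaz(fit$fit, centered = FALSE)
  data.frame(time = bh$time, cumhaz = bh$hazard)
}
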