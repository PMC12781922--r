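#' Counting-process representation of a cohort
#'
#' Expands each subject into Andersen-Gill at-risk intervals
#' \eqn{(0, T_{i1}], (T_{i1}, T_{i2}], \ldots, (T_{iN_i}, \tau]} with
#' `event = 1` on every interval except the final censored one.  The
#' intensity covariate `z` on an interval is `covariate_map` applied to the
#' outcome observed at the interval's left endpoint (the baseline outcome on
#' the first interval).  A subject with no follow-up assessments contributes
#' the single censored row \eqn{(0, \tau]}.
#'
#' @param paths an `"iiw_cohort"` from [simulate_cohort()], or a long visits
#'   data frame with columns `subject_id`, `time`, `outcome` containing a
#'   `time = 0` baseline row per subject.
#' @param visit_spec a [visit_spec()]; supplies \eqn{\tau} and the covariate
#'   map.
#' @return A data frame with columns `subject_id`, `start`, `stop`, `event`,
#'   `z`.
#' @examples
#' coh <- simulate_cohort(4, outcome_spec(2), visit_spec(), seed = 1)
#' build_counting_process(coh, visit_spec())
#' @export
build_counting_process <- function(paths, visit_spec) {
  stopifnot(inherits(visit_spec, "visit_spec"))
  tau <- visit_spec$tau
  cmap <- visit_spec$covariate_map
  if (inherits(paths, "iiw_cohort")) {
    subjects <- paths$subjects
  } else {
    df <- as.data.frame(paths)
    need <- c("subject_id", "time", "outcome")
    if (!all(need %in% names(df)))
      stop("long data must have columns subject_id, time, outcome")
    subjects <- lapply(split(df, df$subject_id), function(d) {
      d <- d[order(d$time), , drop = FALSE]
      if (anyDuplicated(d$time))
        stop(sprintf("duplicate visit times for subject %s",
                     d$subject_id[1]))
      if (d$time[1] != 0)
        stop(sprintf("subject %s has no baseline (time = 0) row",
                     d$subject_id[1]))
      list(subject_id = d$subject_id[1], baseline_y = d$outcome[1],
           visit_times = d$time[-1], visit_outcomes = d$outcome[-1])
    })
  }
  parts <- lapply(subjects, function(s) {
    ts <- s$visit_times
    if (anyDuplicated(ts))
      stop(sprintf("duplicate visit times for subject %s", s$subject_id))
    if (length(ts) && (any(ts <= 0) || any(ts > tau)))
      stop(sprintf("subject %s has visit times outside (0, tau]",
                   s$subject_id))
    start <- c(0, ts)
    stop_ <- c(ts, tau)
    event <- c(rep(1, length(ts)), 0)
    z <- cmap(c(s$baseline_y, s$visit_outcomes))
    keep <- stop_ > start  # drop a zero-length tail if a visit lands on tau
    list(id = rep(s$subject_id, sum(keep)), start = start[keep],
         stop = stop_[keep], event = event[keep], z = z[keep])
  })
  pull <- function(f) unlist(lapply(parts, `[[`, f), use.names = FALSE)
  data.frame(subject_id = pull("id"), start = pull("start"),
             stop = pull("stop"), event = pull("event"), z = pull("z"))
}
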