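# Independent oracles and shared fixtures.

# Breslow partial log-likelihood computed by brute force from counting-process
# rows (single covariate).  A subject is at risk at an event time t when
# start < t <= stop on one of its rows.
pl_loglik <- function(rows, gamma) {
  ev <- rows[rows$event == 1, , drop = FALSE]
  sum(vapply(seq_len(nrow(ev)), function(k) {
    t_e <- ev$stop[k]
    at_risk <- rows$start < t_e & t_e <= rows$stop
    gamma * ev$z[k] - log(sum(exp(gamma * rows$z[at_risk])))
  }, 0))
}

# Dense grid search of the partial likelihood.
grid_gamma_hat <- function(rows, lo = -3, hi = 3, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(g) pl_loglik(rows, g), 0)
  grid[which.max(ll)]
}

# Worked three-subject example: A (Z = 1) has events at 0.5 and 1.5,
# B (Z = 0) at 1.0, C (Z = 0) has none; tau = 2.  The EV estimate solves
# 2 - 3 e^g / (e^g + 2) = 0 (g = log 4); dropping C gives
# 2 - 3 e^g / (e^g + 1) = 0 (g = log 2).
fixture_three_subjects <- function() {
  data.frame(
    subject_id = c("A", "A", "A", "B", "B", "C"),
    start = c(0, 0.5, 1.5, 0, 1, 0),
    stop = c(0.5, 1.5, 2, 1, 2, 2),
    event = c(1, 1, 0, 1, 0, 0),
    z = c(1, 1, 1, 0, 0, 0))
}

# A tiny deterministic long-format cohort containing a zero-follow-up
# subject (id 3).
fixture_long_visits <- function() {
  data.frame(
    subject_id = c(1, 1, 1, 2, 2, 3),
    time = c(0, 0.5, 1.5, 0, 1, 0),
    outcome = c(2, 3, 1, 4, 2, 5))
}
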