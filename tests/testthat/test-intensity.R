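test_that("counting-process construction partitions follow-up and conserves
          events", {
  vs <- visit_spec(tau = 2)
  long <- fixture_long_visits()
  cp <- build_counting_process(long, vs)

  # zero-visit subject contributes a single censored row over (0, tau]
  r3 <- cp[cp$subject_id == 3, ]
  expect_equal(nrow(r3), 1L)
  expect_equal(unlist(r3[, c("start", "stop", "event")]),
               c(start = 0, stop = 2, event = 0))

  # visits at 0.5 and 1.5 give (0,.5] e=1, (.5,1.5] e=1, (1.5,2] e=0
  r1 <- cp[cp$subject_id == 1, ]
  expect_equal(r1$start, c(0, 0.5, 1.5))
  expect_equal(r1$stop, c(0.5, 1.5, 2))
  expect_equal(r1$event, c(1, 1, 0))
  # covariate on each interval is log(1 + outcome at the left endpoint)
  expect_equal(r1$z, log1p(c(2, 3, 1)))

  expect_equal(sum(cp$event), sum(long$time > 0))

  dup <- rbind(long, data.frame(subject_id = 1, time = 0.5, outcome = 9))
  expect_error(build_counting_process(dup, vs), "duplicate")
})

test_that("Andersen-Gill fit matches the closed-form worked example under
          both inclusion schemes", {
  cp <- fixture_three_subjects()
  ev <- fit_intensity(cp, scheme = "EV")
  expect_equal(unname(coef(ev)), log(4), tolerance = 1e-6)
  expect_true(ev$converged)
  expect_identical(ev$scheme, "EV")

  fu <- fit_intensity(cp, scheme = "FU")
  expect_equal(unname(coef(fu)), log(2), tolerance = 1e-6)
  expect_identical(fu$n_subjects, 2L)

  # omission changes risk sets, never the event times
  cp_fu <- cp[cp$subject_id != "C", ]
  expect_identical(cp$stop[cp$event == 1], cp_fu$stop[cp_fu$event == 1])
})

test_that("the Newton solution matches a dense grid search of the partial
          likelihood", {
  cp <- fixture_three_subjects()
  expect_equal(unname(coef(fit_intensity(cp, "EV"))),
               grid_gamma_hat(cp), tolerance = 2e-4)

  # a slightly larger simulated fixture, 5 subjects
  rows <- simulate_poisson_visits(5, z_dist("bernoulli", 0.5),
                                  gamma0 = 0.7, lambda0 = 0.8, tau = 2,
                                  seed = 14)
  fit <- fit_intensity(rows, "EV")
  expect_equal(unname(coef(fit)), grid_gamma_hat(rows),
               tolerance = 2e-4)
})

test_that("the estimate is invariant to monotone time transformations", {
  rows <- simulate_poisson_visits(60, z_dist("bernoulli", 0.5),
                                  gamma0 = 0.5, lambda0 = 0.5, tau = 2,
                                  seed = 31)
  g1 <- coef(fit_intensity(rows, "EV"))
  warped <- transform(rows, start = start^1.3, stop = stop^1.3)
  g2 <- coef(fit_intensity(warped, "EV"))
  expect_equal(unname(g1), unname(g2), tolerance = 1e-6)
})

test_that("FU and EV coincide when every subject has follow-up", {
  rows <- simulate_poisson_visits(40, z_dist("bernoulli", 0.5),
                                  gamma0 = 0.3, lambda0 = 3, tau = 2,
                                  seed = 8)
  ev_per_subject <- tapply(rows$event, rows$subject_id, sum)
  rows <- rows[rows$subject_id %in%
                 names(ev_per_subject)[ev_per_subject > 0], ]
  fe <- fit_intensity(rows, "EV")
  ff <- fit_intensity(rows, "FU")
  expect_identical(coef(fe), coef(ff))
  expect_identical(fe$loglik, ff$loglik)
})

test_that("inverse-intensity weights are exp(-Z gamma-hat)", {
  null_fit <- structure(list(gamma = c(z = 0), converged = TRUE),
                        class = "intensity_fit")
  cp <- fixture_three_subjects()
  w <- compute_weights(null_fit, cp)
  expect_identical(w$weight, rep(1, 3))
  expect_identical(w$time, cp$stop[cp$event == 1])

  half_fit <- structure(list(gamma = c(z = 0.5), converged = TRUE),
                        class = "intensity_fit")
  row <- data.frame(subject_id = 1, start = 0, stop = 1, event = 1,
                    z = log(1 + 3))
  expect_equal(compute_weights(half_fit, row)$weight, 0.5)

  wf <- compute_weights(half_fit, transform(cp, z = z * 7 - 3))
  expect_true(all(wf$weight > 0))

  row$z <- NA_real_
  expect_error(compute_weights(half_fit, row), "missing covariate")
})

test_that("degenerate inputs are refused with clear errors", {
  cp <- fixture_three_subjects()
  expect_error(fit_intensity(cp[cp$event == 0, ], "EV"), "empty event set")
  expect_error(fit_intensity(cp[, c("subject_id", "start", "stop", "event")],
                             "EV"), "covariate")
})
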