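# shared fixture: one protocol subject with noise-free observations
# generated from known individual parameters, optionally with a
# parameter change injected at the formulation conversion (t = 72 h)
make_adapt_fixture <- function(pop, eta = NULL, change = NULL) {
  s <- protocol_subject()
  if (is.null(eta)) eta <- numeric(length(pop$variable))
  params <- individual_params(pop, eta, s)
  timeline <- NULL
  if (!is.null(change)) {
    p2 <- params
    for (nm in names(change))
      p2 <- chronotac:::param_set(p2, nm, change[[nm]])
    timeline <- list(list(time = 72, params = p2))
  }
  tms <- sort(unique(c(0, s$observations$time)))
  sim <- if (pop$name == "pk") simulate_pk(s, params, tms,
                                           timeline = timeline)
    else simulate_pbpk(s, params, tms, timeline = timeline)
  s$observations$conc <- sim$conc[match(round(s$observations$time, 9),
                                        round(sim$time, 9))]
  list(subject = s, params = params, eta = eta)
}

test_that("liberation-time inversion from release data", {
  expect_equal(libt_from_release(0.4, 1.5), 225)
  expect_equal(libt_from_release(1, 100 / 60), 100)
  # inverse proportionality in the released fraction
  expect_equal(libt_from_release(0.2, 1.5), 2 * libt_from_release(0.4, 1.5))
  expect_error(libt_from_release(0, 1), "fraction")
  expect_error(libt_from_release(0.4, -1), "positive")
})

test_that("WLS adaptation is a no-op on perfect predictions", {
  pop <- population_model("pbpk")
  fx <- make_adapt_fixture(pop)
  cfg <- adapt_config("wls", parameters = "LibT", change_time = 72)
  res <- wls_adapt(fx$subject, pop, fx$params,
                   obs_times = 216 + c(0, 1, 4, 12, 24), config = cfg)
  expect_equal(unname(res$delta_params), 0, tolerance = 1e-6)
  expect_lt(res$objective, 1e-10)
})

test_that("one free parameter matches one observation exactly", {
  pop <- population_model("pbpk")
  fx <- make_adapt_fixture(pop, change = list(LibT = 276))  # slower release
  cfg <- adapt_config("wls", parameters = "LibT", change_time = 72)
  res <- wls_adapt(fx$subject, pop, fx$params, obs_times = 216,
                   config = cfg)
  # the injected liberation shift is recovered and C0 is matched on the
  # log scale
  expect_equal(unname(res$values["LibT"]), 276, tolerance = 0.05 * 276)
  expect_lt(sqrt(res$objective), 1e-3)
})

test_that("the WLS optimum location is invariant to the weight", {
  pop <- population_model("pbpk")
  fx <- make_adapt_fixture(pop, change = list(LibT = 300))
  r1 <- wls_adapt(fx$subject, pop, fx$params, obs_times = 216,
                  config = adapt_config("wls", "LibT", 72, W = 1))
  r2 <- wls_adapt(fx$subject, pop, fx$params, obs_times = 216,
                  config = adapt_config("wls", "LibT", 72, W = 7.3))
  expect_equal(unname(r1$values), unname(r2$values), tolerance = 1e-3)
  expect_equal(r2$objective, 7.3 * r1$objective, tolerance = 1e-2)
})

test_that("identifiability warning when parameters outnumber observations", {
  pop <- population_model("pbpk")
  fx <- make_adapt_fixture(pop)
  cfg <- adapt_config("wls", parameters = c("LibT", "Clih", "Kabs"),
                      change_time = 72)
  expect_warning(wls_adapt(fx$subject, pop, fx$params, obs_times = 216,
                           config = cfg), "identifiable")
})

test_that("Bayesian adaptation stays at the prior mode on perfect data", {
  # data generated at the prior mode (eta = 0): both the likelihood and
  # the prior are minimised there, so the increments vanish
  pop <- population_model("pbpk")
  fx <- make_adapt_fixture(pop)
  cfg <- adapt_config("bayes", parameters = c("Clih", "Bmax", "Kd"),
                      change_time = 216)
  res <- bayes_map_adapt(fx$subject, pop, fx$eta,
                         obs_times = 216 + c(0.5, 1, 2, 4, 8, 12, 24),
                         config = cfg)
  expect_lt(max(abs(res$delta_eta)), 1e-3)
})

test_that("Bayesian increments are clipped exactly at the absolute bound", {
  pop <- population_model("pbpk")
  # true clearance halved from day 2: a large shift the bound cannot span
  fx <- make_adapt_fixture(pop, change = list(Clih = 956.6 * 0.5))
  cfg <- adapt_config("bayes", parameters = "Clih", change_time = 72,
                      B = 0.1, B_params = "Clih")
  res <- bayes_map_adapt(fx$subject, pop, numeric(5),
                         obs_times = 216 + c(0, 1, 4, 12, 24),
                         config = cfg)
  expect_equal(unname(abs(res$delta_eta["Clih"])), 0.1, tolerance = 1e-6)
  expect_equal(unname(res$delta_eta["Clih"]), -0.1, tolerance = 1e-6)
})

test_that("noise-free clearance shifts are recovered within tight bounds", {
  pop <- population_model("pbpk")
  shift <- log(1.3)  # Clih increased 30% from day 2
  fx <- make_adapt_fixture(pop, change = list(Clih = 956.6 * 1.3))
  cfg <- adapt_config("bayes", parameters = "Clih", change_time = 72,
                      eta_m = 1)
  # the observations carry no residual noise, so the adaptation runs
  # with a matching (negligible) residual variance and the likelihood
  # dominates the prior
  pop0 <- pop; pop0$sigma2 <- 1e-8
  res <- bayes_map_adapt(fx$subject, pop0, numeric(5),
                         obs_times = 216 + c(0, 1, 2, 4, 8, 12, 24),
                         config = cfg)
  expect_equal(unname(res$delta_eta["Clih"]), shift, tolerance = 1e-3)
})

test_that("Bayes refuses structural constants", {
  pop <- population_model("pbpk")
  cfg <- adapt_config("bayes", parameters = "LibT", change_time = 72)
  fx <- make_adapt_fixture(pop)
  expect_error(bayes_map_adapt(fx$subject, pop, numeric(5), 216, cfg),
               "LibT")
})

test_that("procedure 1 isolates a pure liberation-time change", {
  pop <- population_model("pbpk")
  fx <- make_adapt_fixture(pop, change = list(LibT = 276))
  coh <- cohort(list(fx$subject))
  fit <- list(eta = matrix(0, 1, 5,
                           dimnames = list("p1", pop$variable)))
  res <- procedure1(coh, pop, fit,
                    stage2 = adapt_config("bayes",
                                          parameters = c("Clih", "Bmax", "Kd"),
                                          change_time = 216))
  row <- res$per_subject[[1]]
  expect_equal(unname(row["stage1_dLibT"]), 176, tolerance = 25)
  # stage 2 has nothing left to explain
  expect_lt(abs(row[["dClih"]]), 0.05 * 956.6)
  expect_lt(row[["rmse_c"]], 0.05)
})

test_that("procedure 2 recovers combined liberation and clearance shifts", {
  pop <- population_model("pbpk")
  fx <- make_adapt_fixture(pop, change = list(LibT = 276,
                                              Clih = 956.6 * 0.8))
  coh <- cohort(list(fx$subject))
  fit <- list(eta = matrix(0, 1, 5, dimnames = list("p1", pop$variable)))
  res <- procedure2(coh, pop, fit,
                    config = adapt_config("wls",
                                          parameters = c("LibT", "Clih",
                                                         "Kabs"),
                                          change_time = 72))
  row <- res$per_subject[[1]]
  expect_equal(unname(row["dLibT"]), 176, tolerance = 60)
  expect_equal(unname(row["dClih"]), 956.6 * (0.8 - 1),
               tolerance = 0.35 * 956.6 * 0.2)
  expect_lt(row[["rmse_c"]], 0.05)
  # no injected change -> increments essentially zero
  fx0 <- make_adapt_fixture(pop)
  coh0 <- cohort(list(fx0$subject))
  res0 <- procedure2(coh0, pop, fit,
                     config = adapt_config("wls", parameters = c("LibT"),
                                           change_time = 72))
  expect_lt(abs(res0$per_subject[[1]][["dLibT"]]), 5)
})
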