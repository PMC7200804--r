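test_that("individual parameters apply IIV and covariate links", {
  pop <- population_model("pk",
    links = list(covariate_link("Cld", "bsa", "exponential", 1.17, 1.30)))
  ref <- subject("ref", "M", 12.9, 42.85, 143.4, 0.35)  # BSA ~ 1.30
  ref$bsa <- 1.30
  p0 <- individual_params(pop, numeric(5), ref)
  expect_equal(p0$Cl, 5.41)
  expect_equal(p0$Cld, 46.5, tolerance = 1e-6)
  # exponential link: doubling the covariate multiplies by 2^1.17
  big <- ref; big$bsa <- 2.6
  p2 <- individual_params(pop, numeric(5), big)
  expect_equal(p2$Cld / p0$Cld, 2^1.17, tolerance = 1e-9)
  # eta on Cl acts exponentially
  p3 <- individual_params(pop, c(Cl = log(2)), ref)
  expect_equal(p3$Cl, 2 * 5.41)
  # linear links must keep parameters positive
  bad <- population_model("pk",
    links = list(covariate_link("Cl", "bw", "linear", -1, 10)))
  expect_error(individual_params(bad, numeric(5), ref), "non-positive")
})

test_that("FOCE equals the closed-form marginal likelihood on a
           linear-Gaussian model", {
  set.seed(11)
  X <- matrix(rnorm(12), 6, 2)
  pop <- lingauss_pop(X)
  ys <- replicate(4, drop(X %*% log(c(2, 0.5))) +
                       drop(X %*% (rnorm(2) * sqrt(c(0.2, 0.1)))) +
                       rnorm(6, 0, sqrt(0.05)), simplify = FALSE)
  coh <- cohort(lapply(seq_along(ys), function(i)
    response_subject(ys[[i]], id = paste0("s", i))))
  got <- foce_objective(pop, coh)
  want <- sum(vapply(ys, function(y)
    lingauss_m2ll(y, X, c(2, 0.5), c(0.2, 0.1), 0.05), numeric(1)))
  expect_equal(got$mvof, want, tolerance = 1e-6)
  expect_true(all(got$converged))
})

test_that("degenerate prior reduces FOCE to pooled least squares", {
  set.seed(12)
  X <- matrix(rnorm(10), 5, 2)
  pop <- lingauss_pop(X, omega2 = c(a = 0, b = 0), sigma2 = 0.05)
  y <- drop(X %*% log(c(2, 0.5))) + rnorm(5, 0, 0.3)
  coh <- cohort(list(response_subject(y)))
  got <- foce_objective(pop, coh)
  rss <- sum((y - drop(X %*% log(c(2, 0.5))))^2)
  expect_equal(got$mvof, 5 * log(2 * pi * 0.05) + rss / 0.05,
               tolerance = 1e-8)
  expect_equal(unname(got$eta[1, ]), c(0, 0))
})

test_that("the objective is additive over subjects", {
  set.seed(13)
  X <- matrix(rnorm(8), 4, 2)
  pop <- lingauss_pop(X)
  y <- drop(X %*% log(c(2, 0.5))) + rnorm(4, 0, 0.2)
  one <- cohort(list(response_subject(y, "a")))
  two <- cohort(list(response_subject(y, "a"), response_subject(y, "b")))
  m1 <- foce_objective(pop, one)$mvof
  m2 <- foce_objective(pop, two)$mvof
  expect_equal(m2, 2 * m1, tolerance = 1e-8)
})

test_that("fitting a linear-Gaussian population recovers its parameters", {
  set.seed(14)
  X <- matrix(rnorm(24, sd = 1.5), 12, 2)
  theta_true <- c(a = 2, b = 0.5)
  n <- 40
  ys <- replicate(n, drop(X %*% (log(theta_true) +
                                   rnorm(2) * sqrt(c(0.2, 0.1)))) +
                       rnorm(12, 0, sqrt(0.05)), simplify = FALSE)
  coh <- cohort(lapply(seq_len(n), function(i)
    response_subject(ys[[i]], id = paste0("s", i))))
  pop0 <- lingauss_pop(X, theta = c(a = 1.5, b = 0.8))
  fit <- fit_population(pop0, coh, control = list(maxit = 400))
  expect_lt(fit$mvof, foce_objective(pop0, coh)$mvof)  # optimizer contract
  expect_equal(unname(fit$theta["a"]), 2, tolerance = 0.15)
  expect_equal(unname(fit$theta["b"]), 0.5, tolerance = 0.15)
  expect_equal(unname(fit$sigma2), 0.05, tolerance = 0.5)
  # RSEs from the Hessian are finite at a clean optimum
  expect_true(all(is.finite(fit$rse_theta[c("a", "b")])))
})

test_that("shrinkage diagnostics match their definitions", {
  set.seed(15)
  X <- matrix(rnorm(40), 20, 2)
  pop <- lingauss_pop(X)
  ys <- replicate(30, drop(X %*% log(c(2, 0.5))) + rnorm(20, 0, 0.1),
                  simplify = FALSE)
  coh <- cohort(lapply(seq_len(30), function(i)
    response_subject(ys[[i]], paste0("s", i))))
  # all EBEs zero -> eta-shrinkage 1
  fake <- list(pop = pop,
               eta = matrix(0, 30, 2, dimnames = list(NULL, c("a", "b"))),
               cohort = coh)
  sh <- shrinkage(fake)
  expect_equal(unname(sh$eta), c(1, 1))
  # EBEs drawn from the prior at large n -> shrinkage near 0
  fake$eta[] <- rnorm(60) * sqrt(rep(c(0.2, 0.1), each = 30))
  sh2 <- shrinkage(fake)
  expect_lt(max(abs(sh2$eta)), 0.25)
  # perfectly standardised residuals -> eps-shrinkage ~ 0
  z <- rnorm(600)
  z <- (z - mean(z)) / sd(z)
  ys3 <- split(drop(X %*% log(c(2, 0.5))) +
                 sqrt(0.05) * z, rep(1:30, each = 20))
  coh3 <- cohort(lapply(seq_len(30), function(i)
    response_subject(ys3[[i]], paste0("s", i))))
  fake3 <- list(pop = pop, eta = matrix(0, 30, 2,
                                        dimnames = list(NULL, c("a", "b"))),
                cohort = coh3)
  expect_equal(shrinkage(fake3)$eps, 0, tolerance = 1e-8)
})

test_that("covariate selection accepts real effects and ignores null ones", {
  # linear-Gaussian surrogate: response scale set by parameter `a`,
  # which truly depends on body weight in the simulated data
  set.seed(16)
  X <- matrix(abs(rnorm(16, 1, 0.3)), 8, 2)
  n <- 24
  bws <- runif(n, 20, 60)
  subs <- lapply(seq_len(n), function(i) {
    th_a <- 2 * (bws[i] / 40)^1.0 * exp(rnorm(1, 0, sqrt(0.02)))
    th_b <- 0.5 * exp(rnorm(1, 0, sqrt(0.1)))
    y <- drop(X %*% log(c(th_a, th_b))) + rnorm(8, 0, sqrt(0.02))
    s <- response_subject(y, paste0("s", i))
    s$body_weight <- bws[i]
    s
  })
  coh <- cohort(subs)
  pop <- lingauss_pop(X, theta = c(a = 2, b = 0.5),
                      omega2 = c(a = 0.15, b = 0.1), sigma2 = 0.02)
  cand <- list(covariate_link("a", "bw", "exponential", coef = 0.3,
                              ref = 40),
               covariate_link("b", "bw", "exponential", coef = 0,
                              ref = 40))
  res <- covariate_stepwise(pop, coh, cand,
                            control = list(maxit = 250))
  picked <- vapply(res$accepted, `[[`, character(1), "param")
  expect_true("a" %in% picked)
  acc_row <- res$table[res$table$param == "a", ][1, ]
  expect_gt(acc_row$dmvof, 3.84)
  expect_equal(acc_row$coef, 1.0, tolerance = 0.35)
  # the null link on b must not clear the threshold rule
  expect_false("b" %in% picked)
  # empty candidate list leaves the model untouched
  res0 <- covariate_stepwise(pop, coh, list())
  expect_identical(res0$pop, pop)
  expect_equal(length(res0$accepted), 0)
})
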