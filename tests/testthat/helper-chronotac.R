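# Shared fixtures: small subjects and cohorts built in code.

# typical subject at the cohort mean covariates, fast-release q12h
typical_subject <- function(doses_until = 60, amt = 2.0, hct = 0.35) {
  times <- seq(0, doses_until, by = 12)
  subject("typ", "M", 12.9, 42.85, 143.4, hct,
          doses = data.frame(time = times, amt = amt,
                             formulation = "fast_release"))
}

# the full two-phase protocol for one subject (48-h run-in, day-1 q12h
# fast release, days 2-8 q24h prolonged release)
protocol_subject <- function(amt_half = 2.0, hct = 0.35, id = "p1") {
  doses <- rbind(
    data.frame(time = seq(0, 60, 12), amt = amt_half,
               formulation = "fast_release"),
    data.frame(time = 72 + 24 * (0:6), amt = 2 * amt_half,
               formulation = "prolonged_release"))
  obs <- data.frame(
    time = c(48 + c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 12.5, 13, 14, 15,
                    16, 18, 20, 24),
             216 + c(0, 0.5, 1, 1.5, 2, 2.5, 3, 4, 6, 8, 12, 15, 24)),
    conc = NA_real_, blq = FALSE)
  subject(id, "M", 12.9, 42.85, 143.4, hct, doses = doses,
          observations = obs)
}

# linear-Gaussian custom structural model: response = X %*% log(theta_i),
# exactly linear in eta, so the FOCE objective must equal the closed-form
# marginal -2 log-likelihood
lingauss_pop <- function(X, theta = c(a = 2, b = 0.5),
                         omega2 = c(a = 0.2, b = 0.1), sigma2 = 0.05) {
  population_model(
    structural = list(
      variable = names(theta),
      predict = function(th, subj) drop(X %*% log(th)),
      observed = function(subj) log(usable_obs(subj)$conc)),
    theta = theta, omega2 = omega2, sigma2 = sigma2,
    omega_fixed = character(0))
}

# subject holding an arbitrary response vector y (stored as exp(y) so the
# log-scale observation model returns y)
response_subject <- function(y, id = "r1") {
  subject(id, "M", 10, 30, 130, 0.35,
          doses = data.frame(time = 0, amt = 1,
                             formulation = "fast_release"),
          observations = data.frame(time = seq_along(y), conc = exp(y),
                                    blq = FALSE))
}

# closed-form marginal -2 log-likelihood of the linear-Gaussian model
lingauss_m2ll <- function(y, X, theta, omega2, sigma2) {
  mu <- drop(X %*% log(theta))
  V <- X %*% (omega2 * t(X)) + diag(sigma2, length(y))
  r <- y - mu
  length(y) * log(2 * pi) + determinant(V)$modulus[1] +
    drop(r %*% solve(V, r))
}
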