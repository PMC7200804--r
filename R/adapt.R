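# Individual model adaptation after formulation conversion.
#
# Two techniques: boundary-constrained Bayesian MAP re-estimation of the
# population random effects (increments limited to a weighted multiple
# of the previous state or to an absolute bound), and weighted least
# squares on log concentrations, which can also free structural
# constants (LibT, FDT, K_abs) that are not population parameters.
# Parameter changes act from their configured change time onward via the
# simulation timeline, so multi-stage procedures keep a full parameter
# history per subject.

#' Adaptation configuration
#'
#' @param technique `"wls"` or `"bayes"`.
#' @param parameters Parameters to adapt.  For `"bayes"` these must be
#'   population (random-effect) parameters; WLS can also free the
#'   structural constants `"LibT"`, `"FDT"` and `"Kabs"`.
#' @param change_time Time (h) at which the adapted values take effect.
#' @param W WLS weight (the optimum location is invariant to it).
#' @param W_b,eta_m Weighted boundary of the Bayesian increment:
#'   `|delta eta| <= W_b * max(|eta_0|, eta_m)`, i.e. a multiple of the
#'   previous state with `eta_m` as the minimal boundary value.
#' @param B Absolute boundary `|delta eta| <= B`; used for parameters
#'   listed in `B_params` (otherwise the weighted boundary applies).
#' @param B_params Parameters using the absolute boundary.
#' @param wls_bounds Named list of `c(lo, hi)` box constraints for WLS
#'   free parameters (natural scale; LibT in minutes).
#' @param optim_control Control options merged into the optimiser call
#'   (`stats::optim`, L-BFGS-B).
#' @return Object of class `tac_adapt_config`.
#' @export
adapt_config <- function(technique = c("wls", "bayes"), parameters,
                         change_time, W = 1, W_b = 1, eta_m = 0.5, B = 2,
                         B_params = character(0),
                         wls_bounds = list(), optim_control = list()) {
  technique <- match.arg(technique)
  stopifnot(W > 0, W_b > 0, eta_m > 0, B > 0)
  structure(list(technique = technique, parameters = parameters,
                 change_time = change_time, W = W, W_b = W_b,
                 eta_m = eta_m, B = B, B_params = B_params,
                 wls_bounds = wls_bounds, optim_control = optim_control),
            class = "tac_adapt_config")
}

#' Liberation time from in-vitro release data
#'
#' Inverts the zero-order liberation law: if a fraction of the dose is
#' released in a given time, the liberation rate constant per dose is
#' `fraction / time` and the liberation time its reciprocal,
#' `LibT = time(min) / fraction`.
#'
#' @param fraction Fraction of the dose released, in (0, 1].
#' @param release_time Release time, hours.
#' @return Liberation time in minutes.
#' @examples
#' libt_from_release(0.4, 1.5) # 225 min
#' @export
libt_from_release <- function(fraction, release_time) {
  if (any(fraction <= 0) || any(fraction > 1)) stop("fraction must be in (0, 1]")
  if (any(release_time <= 0)) stop("release_time must be positive")
  release_time * 60 / fraction
}

# get/set structural parameters by adaptation name (formulation-specific
# constants refer to the prolonged-release entry)
param_get <- function(params, name) {
  switch(name,
         LibT = unname(params$LibT[["prolonged_release"]]),
         FDT = unname(params$FDT[["prolonged_release"]]),
         r_chr = params$circadian$r_chr,
         t_chr = params$circadian$t_chr,
         params[[name]])
}

param_set <- function(params, name, value) {
  if (name == "LibT") params$LibT[["prolonged_release"]] <- value
  else if (name == "FDT") params$FDT[["prolonged_release"]] <- value
  else if (name == "r_chr")
    params$circadian <- circadian_profile(min(value, 1),
                                          params$circadian$t_chr,
                                          params$circadian$breakpoints)
  else if (name == "t_chr")
    params$circadian <- circadian_profile(params$circadian$r_chr, value,
                                          params$circadian$breakpoints)
  else params[[name]] <- value
  params
}

simulate_model <- function(pop, subj, params, times, timeline = NULL,
                           rtol = 1e-7) {
  if (pop$name == "pk")
    simulate_pk(subj, params, times, timeline = timeline, rtol = rtol,
                atol = rtol * 1e-2, restart = FALSE)
  else
    simulate_pbpk(subj, params, times, timeline = timeline, rtol = rtol,
                  atol = rtol * 1e-2, restart = FALSE)
}

# predicted log concentration at `otimes` given base params and a
# timeline of adaptations
adapt_predict <- function(pop, subj, params0, timeline, otimes) {
  tms <- sort(unique(c(0, otimes)))
  sim <- simulate_model(pop, subj, params0, tms, timeline = timeline)
  log(pmax(sim$conc[match(round(otimes, 9), round(sim$time, 9))], 1e-9))
}

#' Boundary-constrained Bayesian MAP adaptation
#'
#' Re-estimates the random effects of the adapted parameters by
#' maximising the posterior (population prior from Omega plus the
#' likelihood of the new observations), subject to the box constraint
#' that each increment `delta eta = eta - eta_0` stays within the
#' configured weighted or absolute boundary.  The adapted parameter set
#' takes effect at the configured change time.
#'
#' @param subj A [subject()].
#' @param pop A [population_model()].
#' @param eta0 The subject's random effects at the previous model state
#'   (empirical Bayes estimates of the population fit, possibly already
#'   adapted).
#' @param obs_times Observation times (h) to fit (subset of the
#'   subject's usable observations).
#' @param config An [adapt_config()] with `technique = "bayes"`.
#' @param base_timeline Parameter timeline of earlier adaptation stages.
#' @return `list(eta, delta_eta, delta_params, timeline, objective,
#'   converged)`; `delta_params` are natural-scale parameter increments.
#' @export
bayes_map_adapt <- function(subj, pop, eta0, obs_times, config,
                            base_timeline = NULL) {
  bad <- setdiff(config$parameters, pop$variable)
  if (length(bad))
    stop("not population parameters, cannot be Bayes-adapted: ",
         paste(bad, collapse = ", "))
  free <- config$parameters
  o <- usable_obs(subj)
  o <- o[o$time %in% obs_times, , drop = FALSE]
  if (!nrow(o)) stop("no usable observations at the requested times")
  y <- log(o$conc)
  ev <- setNames(numeric(length(pop$variable)), pop$variable)
  if (!is.null(names(eta0))) ev[names(eta0)] <- eta0 else
    ev[seq_along(eta0)] <- eta0
  eta0 <- ev
  params0 <- individual_params(pop, eta0, subj)
  # adapted values are layered onto the *current* parameter state so
  # that structural changes from earlier stages (e.g. a corrected
  # liberation time) are preserved
  params_base <- if (!is.null(base_timeline))
    base_timeline[[length(base_timeline)]]$params else params0
  oinv <- ifelse(pop$omega2 > 0, 1 / pop$omega2, 0)
  # weighted boundary: eta_m acts as the minimal boundary so the box
  # never collapses when the previous state sits at the population mode
  # (eta_0 = 0)
  bound <- vapply(free, function(p) {
    if (p %in% config$B_params) config$B
    else config$W_b * max(abs(eta0[p]), config$eta_m)
  }, numeric(1))
  adapted_value <- function(p, eta_p) {
    v <- unname(pop$theta[[p]]) * exp(eta_p)
    for (lk in pop$links)
      if (lk$param == p) v <- v * link_multiplier(lk, subj)
    v
  }
  make_timeline <- function(eta_free) {
    pnew <- params_base
    for (j in seq_along(free))
      pnew <- param_set(pnew, free[j], adapted_value(free[j], eta_free[j]))
    c(base_timeline,
      list(list(time = config$change_time, params = pnew)))
  }
  objfn <- function(eta_free) {
    tl <- make_timeline(eta_free)
    f <- adapt_predict(pop, subj, params0, tl, o$time)
    eta <- eta0; eta[free] <- eta_free
    sum((y - f)^2) / pop$sigma2 + sum(oinv * eta^2)
  }
  lo <- eta0[free] - bound; hi <- eta0[free] + bound
  ctrl <- modifyList(list(maxit = 100, factr = 1e9),
                     config$optim_control)
  opt <- optim(eta0[free], objfn, method = "L-BFGS-B", lower = lo,
               upper = hi, control = ctrl)
  eta_new <- eta0; eta_new[free] <- opt$par
  tl_new <- make_timeline(opt$par)
  params_new <- tl_new[[length(tl_new)]]$params
  dpar <- vapply(free, function(p)
    param_get(params_new, p) - param_get(params_base, p), numeric(1))
  list(eta = eta_new, delta_eta = eta_new - eta0,
       delta_params = dpar, timeline = tl_new,
       objective = opt$value, converged = opt$convergence == 0)
}

#' Weighted least-squares adaptation
#'
#' Minimises `F_wse = W * sum_k (ln C_obs(t_k) - ln C_model(t_k))^2`
#' over the free parameters, which may include structural constants that
#' are not population parameters (`LibT`, `FDT`, `Kabs`).  Box
#' constraints come from `config$wls_bounds` (defaults: positive, within
#' a factor 50 of the current value).
#'
#' @inheritParams bayes_map_adapt
#' @param params0 The subject's current structural parameter set.
#' @param config An [adapt_config()] with `technique = "wls"`.
#' @return `list(values, delta_params, timeline, objective, converged)`.
#' @export
wls_adapt <- function(subj, pop, params0, obs_times, config,
                      base_timeline = NULL) {
  free <- config$parameters
  o <- usable_obs(subj)
  o <- o[o$time %in% obs_times, , drop = FALSE]
  if (!nrow(o)) stop("no usable observations at the requested times")
  if (length(free) > nrow(o))
    warning("more free parameters (", length(free), ") than observations (",
            nrow(o), "): adaptation is not identifiable")
  y <- log(o$conc)
  x0 <- vapply(free, function(p) param_get(params0, p), numeric(1))
  bounds <- t(vapply(free, function(p) {
    if (!is.null(config$wls_bounds[[p]])) config$wls_bounds[[p]]
    else c(param_get(params0, p) / 50, param_get(params0, p) * 50)
  }, numeric(2)))
  make_timeline <- function(x) {
    pnew <- params0
    for (j in seq_along(free)) pnew <- param_set(pnew, free[j], x[j])
    c(base_timeline,
      list(list(time = config$change_time, params = pnew)))
  }
  objfn <- function(x) {
    f <- adapt_predict(pop, subj, params0, make_timeline(x), o$time)
    config$W * sum((y - f)^2)
  }
  if (length(free) == 1L) {
    opt <- optimize(function(z) objfn(z), interval = c(bounds[1, 1],
                                                       bounds[1, 2]),
                    tol = 1e-4 * max(1, abs(x0)))
    par <- opt$minimum; val <- opt$objective; conv <- TRUE
  } else {
    ctrl <- modifyList(list(maxit = 200, factr = 1e9,
                            parscale = pmax(abs(x0), 1e-3)),
                       config$optim_control)
    op <- optim(x0, objfn, method = "L-BFGS-B", lower = bounds[, 1],
                upper = bounds[, 2], control = ctrl)
    par <- op$par; val <- op$value; conv <- op$convergence == 0
  }
  # keep the pre-adaptation values when they already fit (W-invariant
  # optimum can be flat)
  if (objfn(x0) <= val + 1e-12) { par <- x0; val <- objfn(x0); conv <- TRUE }
  names(par) <- free
  list(values = par, delta_params = par - x0,
       timeline = make_timeline(par), objective = val, converged = conv)
}

# bioavailability over a day window: cleared mass / dosed mass within it
window_F <- function(pop, subj, params0, timeline, from, to) {
  tms <- c(0, from, to)
  spec_states <- function(upto) {
    sim <- simulate_model(pop, subj, params0, c(0, upto),
                          timeline = timeline)
    attr(sim, "states")
  }
  s1 <- spec_states(from); s2 <- spec_states(to)
  din <- s2[["input"]] - s1[["input"]]
  if (din <= 0) return(NA_real_)
  (s2[["eliminated"]] - s1[["eliminated"]]) / din
}

adapt_metrics <- function(pop, subj, params0, timeline, day8_start = 216,
                          day1_start = 48) {
  o <- usable_obs(subj)
  d8 <- o[o$time >= day8_start & o$time <= day8_start + 24, , drop = FALSE]
  f <- adapt_predict(pop, subj, params0, timeline, d8$time)
  rmse <- rmse_log(d8$conc, exp(f))
  nca <- tryCatch(auc_logtrap(d8$time, d8$conc), error = function(e) NA)
  grid <- seq(day8_start, day8_start + 24, 0.1)
  sim <- simulate_model(pop, subj, params0, c(0, grid), timeline = timeline)
  simw <- sim[sim$time >= day8_start, ]
  dauc <- if (is.na(nca)) NA_real_ else
    sum(diff(simw$time) * (head(simw$conc, -1) + tail(simw$conc, -1)) / 2) -
      nca
  F1 <- window_F(pop, subj, params0, timeline, day1_start, day1_start + 24)
  F8 <- window_F(pop, subj, params0, timeline, day8_start, day8_start + 24)
  c(rmse_c = rmse, delta_auc24 = dauc, dF = 100 * (F8 - F1))
}

#' Adaptive procedure 1: release-rate correction, then day-8 refinement
#'
#' Stage 1 corrects the trough (C0) prediction error at the day-8
#' re-admission by WLS on a single release-rate parameter (default
#' `LibT` for the PBPK model, `FDT` for the PK model), applied at the
#' formulation conversion (start of day 2).  Stage 2 then adapts the
#' model to the remaining day-8 observations (Bayesian or WLS), applied
#' at the start of day 8.  Remaining increments after stage 1 quantify
#' intra-patient parameter variability beyond the formulation effect.
#'
#' @param coh Cohort with day-8 observations.
#' @param pop A [population_model()].
#' @param fit The phase-1 [fit_population()] result (supplies each
#'   subject's empirical Bayes state).
#' @param stage1_param Release-rate parameter adapted in stage 1.
#' @param stage2 An [adapt_config()] for stage 2.
#' @param conversion_time,day8_start Protocol times, h.
#' @return Object of class `tac_adapt_result`: per-subject increments
#'   and accuracy metrics.
#' @export
procedure1 <- function(coh, pop, fit,
                       stage1_param = if (pop$name == "pbpk") "LibT" else "FDT",
                       stage2 = adapt_config("bayes",
                                             parameters = pop$variable[1:3],
                                             change_time = 216),
                       conversion_time = 72, day8_start = 216) {
  rows <- list()
  for (i in seq_along(coh$subjects)) {
    subj <- coh$subjects[[i]]
    eta0 <- fit$eta[i, ]
    params0 <- individual_params(pop, eta0, subj)
    o <- usable_obs(subj)
    c0 <- o$time[abs(o$time - day8_start) < 1e-9]
    s1 <- NULL
    tl <- NULL
    if (!length(c0)) {
      warning("subject ", subj$id, ": no C0 at day-8 admission, stage 1 skipped")
    } else {
      cfg1 <- adapt_config("wls", parameters = stage1_param,
                           change_time = conversion_time)
      s1 <- wls_adapt(subj, pop, params0, c0, cfg1)
      tl <- s1$timeline
    }
    rest <- o$time[o$time > day8_start & o$time <= day8_start + 24]
    if (stage2$technique == "bayes") {
      s2 <- bayes_map_adapt(subj, pop, eta0, rest, stage2,
                            base_timeline = tl)
    } else {
      pbase <- if (is.null(tl)) params0 else tl[[length(tl)]]$params
      s2 <- wls_adapt(subj, pop, pbase, rest, stage2, base_timeline = tl)
    }
    met <- adapt_metrics(pop, subj, params0, s2$timeline,
                         day8_start = day8_start)
    rows[[subj$id]] <- c(
      if (!is.null(s1)) setNames(s1$delta_params,
                                 paste0("stage1_d", stage1_param)),
      setNames(s2$delta_params, paste0("d", names(s2$delta_params))),
      met)
  }
  structure(list(per_subject = rows, technique = stage2$technique,
                 procedure = 1L), class = "tac_adapt_result")
}

#' Adaptive procedure 2: single adjustment on all day-8 data
#'
#' Adapts the model using all day-8 measurements simultaneously, with
#' the parametric change applied at the formulation conversion (start of
#' day 2).
#'
#' @inheritParams procedure1
#' @param config An [adapt_config()]; its `change_time` is forced to the
#'   conversion time.
#' @return Object of class `tac_adapt_result`.
#' @export
procedure2 <- function(coh, pop, fit,
                       config = adapt_config("wls",
                                             parameters = if (pop$name == "pbpk")
                                               c("LibT", "Clih", "Kabs")
                                             else c("Cl", "Ka", "MTT", "FDT"),
                                             change_time = 72),
                       conversion_time = 72, day8_start = 216) {
  config$change_time <- conversion_time
  rows <- list()
  for (i in seq_along(coh$subjects)) {
    subj <- coh$subjects[[i]]
    eta0 <- fit$eta[i, ]
    params0 <- individual_params(pop, eta0, subj)
    o <- usable_obs(subj)
    d8 <- o$time[o$time >= day8_start & o$time <= day8_start + 24]
    res <- if (config$technique == "bayes")
      bayes_map_adapt(subj, pop, eta0, d8, config)
    else wls_adapt(subj, pop, params0, d8, config)
    met <- adapt_metrics(pop, subj, params0, res$timeline,
                         day8_start = day8_start)
    rows[[subj$id]] <- c(setNames(res$delta_params,
                                  paste0("d", names(res$delta_params))),
                         met)
  }
  structure(list(per_subject = rows, technique = config$technique,
                 procedure = 2L), class = "tac_adapt_result")
}

#' Summarise an adaptation result across the cohort
#'
#' @param object A `tac_adapt_result`.
#' @param ... Unused.
#' @return Data frame of mean and SD per reported quantity.
#' @export
summary.tac_adapt_result <- function(object, ...) {
  tab <- do.call(rbind, object$per_subject)
  data.frame(quantity = colnames(tab),
             mean = colMeans(tab, na.rm = TRUE),
             sd = apply(tab, 2, sd, na.rm = TRUE),
             row.names = NULL)
}

#' @export
print.tac_adapt_result <- function(x, ...) {
  cat(sprintf("adaptive procedure %d (%s), %d subjects\n", x$procedure,
              x$technique, length(x$per_subject)))
  print(summary(x), digits = 3)
  invisible(x)
}
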