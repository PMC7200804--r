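# Orchestration of the study's two phases on a cohort (measured or
# synthetic).  All randomness flows from a single seed through named
# sub-streams, so a manifest (seed + configuration) reproduces every
# reported number.

#' Phase 1: population fitting and evaluation
#'
#' Fits the population model to the day-1 (fast-release) observation
#' window and runs the evaluation battery: per-subject NCA and model
#' AUC24, shrinkage, a prediction-corrected VPC and the Monte Carlo
#' exposure study.
#'
#' @param coh A [cohort()] with day-1 observations.
#' @param model `"pk"` or `"pbpk"`.
#' @param pop0 Optional initial [population_model()]; defaults to the
#'   model's shipped initial estimates.
#' @param day1_window `c(from, to)` of the fitting window, h.
#' @param seed Integer seed.
#' @param n_replicas pcVPC replicas.
#' @param mc_n Monte Carlo runs per dose level (0 skips the Monte
#'   Carlo).
#' @param fit_control Passed to [fit_population()].
#' @param ... Passed to [fit_population()] (e.g. `estimate`,
#'   `estimate_theta`).
#' @return Object of class `tac_phase1`: fit, per-subject NCA table,
#'   vpc, Monte Carlo table and the manifest.
#' @export
run_phase1 <- function(coh, model = c("pk", "pbpk"), pop0 = NULL,
                       day1_window = c(48, 72), seed = 1,
                       n_replicas = 500, mc_n = 600,
                       fit_control = list(), ...) {
  model <- match.arg(model)
  if (is.null(pop0)) pop0 <- population_model(model)
  day1 <- observation_window(coh, day1_window[1], day1_window[2])
  fit <- fit_population(pop0, day1, control = fit_control, ...)
  nca <- do.call(rbind, lapply(day1$subjects, function(s) {
    o <- usable_obs(s)
    auc <- tryCatch(auc_logtrap(o$time, o$conc), error = function(e) NA)
    data.frame(id = s$id, nca_auc24 = auc)
  }))
  sim_auc <- vapply(seq_along(day1$subjects), function(i) {
    s <- day1$subjects[[i]]
    params <- individual_params(fit$pop, fit$eta[i, ], s)
    grid <- seq(day1_window[1], day1_window[2], 0.1)
    sim <- simulate_model(fit$pop, s, params, c(0, grid))
    w <- sim$time >= day1_window[1]
    sum(diff(sim$time[w]) *
          (head(sim$conc[w], -1) + tail(sim$conc[w], -1)) / 2)
  }, numeric(1))
  Fday1 <- vapply(seq_along(day1$subjects), function(i) {
    s <- day1$subjects[[i]]
    params <- individual_params(fit$pop, fit$eta[i, ], s)
    100 * window_F(fit$pop, s, params, NULL, day1_window[1], day1_window[2])
  }, numeric(1))
  nca$model_auc24 <- sim_auc
  nca$delta_auc <- sim_auc - nca$nca_auc24
  nca$F_pct <- Fday1
  vpc <- pcvpc(fit$pop, day1, n_replicas = n_replicas, seed = seed)
  mc <- if (mc_n > 0)
    monte_carlo_exposure(fit$pop, n = mc_n, seed = seed) else NULL
  structure(list(fit = fit, nca = nca, vpc = vpc, monte_carlo = mc,
                 manifest = list(model = model, seed = seed,
                                 day1_window = day1_window,
                                 n_replicas = n_replicas, mc_n = mc_n)),
            class = "tac_phase1")
}

#' @export
print.tac_phase1 <- function(x, ...) {
  cat("== phase 1 (", x$manifest$model, " model) ==\n", sep = "")
  print(x$fit)
  cat(sprintf("NCA AUC24 %.1f +/- %.1f; model AUC24 %.1f +/- %.1f; F %.1f +/- %.1f %%\n",
              mean(x$nca$nca_auc24, na.rm = TRUE),
              sd(x$nca$nca_auc24, na.rm = TRUE),
              mean(x$nca$model_auc24), sd(x$nca$model_auc24),
              mean(x$nca$F_pct), sd(x$nca$F_pct)))
  if (!is.null(x$monte_carlo)) print(x$monte_carlo, digits = 4)
  invisible(x)
}

#' Phase 2: adaptation after formulation conversion
#'
#' Runs adaptive procedures 1 and 2 with both techniques on the day-8
#' observations and assembles the day-1 / day-8 AUC24 comparison
#' (NCA vs adapted models).
#'
#' @param phase1 A [run_phase1()] result.
#' @param coh The full cohort including day-8 observations.
#' @param procedures Integer subset of `c(1, 2)`.
#' @param techniques Character subset of `c("bayes", "wls")`.
#' @param day8_window `c(from, to)` of the day-8 window, h.
#' @return Object of class `tac_phase2`: adaptation results per
#'   procedure/technique and the AUC comparison table.
#' @export
run_phase2 <- function(phase1, coh, procedures = c(1, 2),
                       techniques = c("bayes", "wls"),
                       day8_window = c(216, 240)) {
  fit <- phase1$fit
  pop <- fit$pop
  res <- list()
  for (pr in procedures) for (te in techniques) {
    key <- sprintf("procedure%d_%s", pr, te)
    res[[key]] <- if (pr == 1) {
      st2 <- if (te == "bayes")
        adapt_config("bayes", parameters = pop$variable[1:3],
                     change_time = day8_window[1])
      else
        adapt_config("wls",
                     parameters = if (pop$name == "pbpk")
                       c("Clih", "Kabs", "LibT") else c("Cl", "Ka", "MTT"),
                     change_time = day8_window[1])
      procedure1(coh, pop, fit, stage2 = st2, day8_start = day8_window[1])
    } else {
      cfg <- if (te == "bayes")
        adapt_config("bayes", parameters = pop$variable[1:3],
                     change_time = 72)
      else
        adapt_config("wls",
                     parameters = if (pop$name == "pbpk")
                       c("LibT", "Clih", "Kabs")
                     else c("Cl", "Ka", "MTT", "FDT"),
                     change_time = 72)
      procedure2(coh, pop, fit, config = cfg, day8_start = day8_window[1])
    }
  }
  nca8 <- vapply(coh$subjects, function(s) {
    o <- usable_obs(s)
    o <- o[o$time >= day8_window[1] & o$time <= day8_window[2], ]
    tryCatch(auc_logtrap(o$time, o$conc), error = function(e) NA_real_)
  }, numeric(1))
  auc_tab <- data.frame(
    day = c(1, 8),
    nca_mean = c(mean(phase1$nca$nca_auc24, na.rm = TRUE),
                 mean(nca8, na.rm = TRUE)),
    nca_sd = c(sd(phase1$nca$nca_auc24, na.rm = TRUE),
               sd(nca8, na.rm = TRUE)))
  structure(list(adaptations = res, auc_comparison = auc_tab,
                 manifest = c(phase1$manifest,
                              list(procedures = procedures,
                                   techniques = techniques))),
            class = "tac_phase2")
}

#' @export
print.tac_phase2 <- function(x, ...) {
  cat("== phase 2 adaptations ==\n")
  for (nm in names(x$adaptations)) {
    cat("--", nm, "--\n")
    print(x$adaptations[[nm]])
  }
  cat("AUC24 comparison (NCA):\n")
  print(x$auc_comparison, digits = 4)
  invisible(x)
}
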