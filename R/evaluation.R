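# Model-evaluation battery: log-trapezoidal NCA, log-scale RMSE, model
# vs NCA AUC differences, prediction-corrected visual predictive check,
# and Monte Carlo exposure simulation.

#' Log-trapezoidal AUC
#'
#' Non-compartmental AUC over a window using the log-trapezoidal rule:
#' each interval contributes `dt * (C1 - C2) / log(C1 / C2)`, falling
#' back to the arithmetic trapezoid when the two concentrations are
#' (nearly) equal.
#'
#' @param times Sampling times, h.
#' @param conc Concentrations, ng/ml; must be positive inside the
#'   window.
#' @param window Optional `c(t0, t1)` restricting the integration.
#' @return AUC in ng/ml*h.
#' @examples
#' auc_logtrap(c(0, 12, 24), c(5, 5, 5)) # 120
#' @export
auc_logtrap <- function(times, conc, window = NULL) {
  if (length(times) != length(conc)) stop("length mismatch")
  o <- order(times)
  times <- times[o]; conc <- conc[o]
  if (!is.null(window)) {
    keep <- times >= window[1] & times <= window[2]
    times <- times[keep]; conc <- conc[keep]
  }
  if (length(times) < 2) stop("need at least two samples in the window")
  if (any(conc <= 0)) stop("non-positive concentration in the AUC window")
  dt <- diff(times)
  c1 <- conc[-length(conc)]; c2 <- conc[-1]
  same <- abs(c1 - c2) < 1e-12 * pmax(c1, c2)
  seg <- ifelse(same, dt * (c1 + c2) / 2,
                dt * (c1 - c2) / log(c1 / c2))
  sum(seg)
}

#' Root mean square error of log concentrations
#'
#' `sqrt(mean((log C_obs - log C_pred)^2))` over paired positive series.
#'
#' @param observed,predicted Positive concentration vectors of equal
#'   length.
#' @return RMSE on the log scale.
#' @export
rmse_log <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (any(observed <= 0) || any(predicted <= 0))
    stop("concentrations must be positive")
  sqrt(mean((log(observed) - log(predicted))^2))
}

#' Model-minus-NCA AUC difference
#'
#' Integrates the model-predicted curve (arithmetic trapezoid on the
#' simulation grid, which is exact in the dense-grid limit) over the
#' window and subtracts the NCA value.
#'
#' @param sim A `tac_sim` (dense grid recommended).
#' @param nca NCA AUC value for the same window (e.g. from
#'   [auc_logtrap()]).
#' @param window `c(t0, t1)` integration window.
#' @return Difference in ng/ml*h; `NA` with a warning if the window
#'   carries no exposure.
#' @export
delta_auc <- function(sim, nca, window) {
  w <- sim$time >= window[1] & sim$time <= window[2]
  tt <- sim$time[w]; cc <- sim$conc[w]
  if (length(tt) < 2 || all(cc == 0)) {
    warning("degenerate window: no exposure")
    return(NA_real_)
  }
  model_auc <- sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2)
  model_auc - nca
}

#' Prediction-corrected visual predictive check
#'
#' Observations are prediction-corrected by scaling with the bin-median
#' population prediction over the subject's population prediction
#' (random effects at zero), binned at the protocol sampling times.
#' `n_replicas` cohorts are then simulated from the model (new random
#' effects and residual noise), corrected the same way, and the 95%
#' confidence band of each percentile (5/50/95) is computed across
#' replicas, stratified by dose/BSA.
#'
#' @param pop A fitted [population_model()].
#' @param coh Cohort with observations.
#' @param n_replicas Number of simulated replicas (default 500).
#' @param strata_break Dose/BSA threshold (mg/m^2) separating the
#'   low-dose stratum; `NULL` for a single stratum.
#' @param seed Integer seed.
#' @return List of `tac_vpc` results, one per non-empty stratum: per-bin
#'   observed percentiles and simulated 95% CIs.
#' @export
pcvpc <- function(pop, coh, n_replicas = 500, strata_break = 0.9,
                  seed = 1) {
  set.seed(seed + 2000L)
  if (n_replicas < 2) {
    warning("fewer than 2 replicas: confidence bands are degenerate")
  }
  subs <- coh$subjects
  # population predictions (eta = 0) per subject at its observation times
  pred0 <- lapply(subs, function(s) {
    f <- pop_predict(pop, s, numeric(length(pop$variable)))
    if (pop$residual == "additive_log") exp(f) else f
  })
  # stratum per subject: dose normalised by BSA on the first admission day
  strat <- vapply(subs, function(s) {
    d <- s$doses
    day1 <- d$amt[d$formulation == "fast_release"]
    amt <- if (length(day1)) 2 * day1[length(day1)] else d$amt[1]
    amt / s$bsa
  }, numeric(1))
  stratum <- if (is.null(strata_break)) rep("all", length(subs)) else
    ifelse(strat < strata_break,
           sprintf("D/BSA < %.1f", strata_break),
           sprintf("D/BSA >= %.1f", strata_break))
  obs_tab <- do.call(rbind, lapply(seq_along(subs), function(i) {
    o <- usable_obs(subs[[i]])
    data.frame(subject = i, bin = o$time, conc = o$conc,
               pred = unname(pred0[[i]]), stratum = unname(stratum[i]))
  }))
  qs <- c(0.05, 0.5, 0.95)
  out <- list()
  for (st in unique(stratum)) {
    tab <- obs_tab[obs_tab$stratum == st, ]
    if (!nrow(tab)) { warning("empty stratum ", st, ", skipped"); next }
    med_pred <- tapply(tab$pred, tab$bin, median)
    tab$pc <- tab$conc * med_pred[as.character(tab$bin)] / tab$pred
    obs_pct <- do.call(rbind, tapply(tab$pc, tab$bin, quantile, probs = qs))
    bins <- as.numeric(rownames(obs_pct))
    idx <- which(stratum == st)
    sim_pct <- array(NA_real_, c(n_replicas, length(bins), 3))
    for (r in seq_len(n_replicas)) {
      rep_tab <- do.call(rbind, lapply(idx, function(i) {
        s <- subs[[i]]
        eta <- rnorm(length(pop$variable)) * sqrt(pop$omega2)
        f <- pop_predict(pop, s, eta)
        cc <- if (pop$residual == "additive_log")
          exp(f + rnorm(length(f), 0, sqrt(pop$sigma2)))
        else f * (1 + rnorm(length(f), 0, sqrt(pop$sigma2)))
        o <- usable_obs(s)
        data.frame(bin = o$time, conc = unname(cc),
                   pred = unname(pred0[[i]]))
      }))
      med_r <- tapply(rep_tab$pred, rep_tab$bin, median)
      rep_tab$pc <- rep_tab$conc * med_r[as.character(rep_tab$bin)] /
        rep_tab$pred
      sim_pct[r, , ] <- do.call(rbind, tapply(rep_tab$pc, rep_tab$bin,
                                              quantile, probs = qs))
    }
    ci_lo <- apply(sim_pct, c(2, 3), quantile, probs = 0.025, na.rm = TRUE)
    ci_hi <- apply(sim_pct, c(2, 3), quantile, probs = 0.975, na.rm = TRUE)
    res <- data.frame(
      bin = bins,
      obs_p5 = obs_pct[, 1], obs_p50 = obs_pct[, 2], obs_p95 = obs_pct[, 3],
      lo_p5 = ci_lo[, 1], hi_p5 = ci_hi[, 1],
      lo_p50 = ci_lo[, 2], hi_p50 = ci_hi[, 2],
      lo_p95 = ci_lo[, 3], hi_p95 = ci_hi[, 3])
    rownames(res) <- NULL
    out[[st]] <- structure(list(stratum = st, bins = res,
                                n_replicas = n_replicas,
                                degenerate = n_replicas < 2),
                           class = "tac_vpc")
  }
  out
}

#' Fraction of pcVPC bins whose observed percentiles fall inside the
#' simulated confidence bands
#'
#' @param vpc A single `tac_vpc` element from [pcvpc()].
#' @return Fraction in `[0, 1]` over all bins and the three percentiles.
#' @export
vpc_coverage <- function(vpc) {
  b <- vpc$bins
  inside <- c(b$obs_p5 >= b$lo_p5 & b$obs_p5 <= b$hi_p5,
              b$obs_p50 >= b$lo_p50 & b$obs_p50 <= b$hi_p50,
              b$obs_p95 >= b$lo_p95 & b$obs_p95 <= b$hi_p95)
  mean(inside)
}

#' Monte Carlo exposure simulation
#'
#' Samples virtual subjects (demographics from the cohort specification,
#' random effects from the population model), administers the phase-1
#' twice-daily regimen at each dose level for `horizon` hours starting
#' from zero drug, and evaluates the AUC over the final `window` hours,
#' the bioavailability `F`, and the time spent above a concentration
#' threshold.
#'
#' Dose levels are in mg/kg.  With `dose_mode = "normalised"` (default)
#' each administration is the level scaled by the 60-kg reference
#' (0.042 mg/kg -> 2.5 mg per administration); with `"per_kg"` the
#' administered amount is the level times the subject's sampled weight.
#'
#' @param pop A [population_model()] (built-in structural models).
#' @param spec A [cohort_spec()] used as the demographic sampler.
#' @param dose_levels Dose levels, mg/kg.
#' @param n Simulations per dose level (default 600).
#' @param horizon Simulated duration, h.
#' @param window Final window used for the AUC, h.
#' @param threshold Tolerability threshold, ng/ml.
#' @param dose_mode `"normalised"` or `"per_kg"`.
#' @param seed Integer seed.
#' @param dt Evaluation grid step, h.
#' @return Data frame with one row per dose level: mean and SD of
#'   `AUC24`, `F` (%) and hours above the threshold, plus the number of
#'   failed runs (dropped).
#' @export
monte_carlo_exposure <- function(pop, spec = cohort_spec(),
                                 dose_levels = c(0.025, 0.042, 0.05),
                                 n = 600, horizon = 36, window = 24,
                                 threshold = 20,
                                 dose_mode = c("normalised", "per_kg"),
                                 seed = 1, dt = 0.1) {
  dose_mode <- match.arg(dose_mode)
  stopifnot(pop$name %in% c("pk", "pbpk"))
  grid <- seq(0, horizon, dt)
  w <- grid >= horizon - window
  rows <- list()
  for (lev in dose_levels) {
    set.seed(seed + round(1e4 * lev))
    auc <- Fv <- tab <- rep(NA_real_, n)
    failed <- 0L
    for (i in seq_len(n)) {
      zb <- rnorm(1)
      zh <- spec$bw_height_cor * zb + sqrt(1 - spec$bw_height_cor^2) * rnorm(1)
      bw <- min(max(spec$bw[1] + spec$bw[2] * zb, spec$bw[3]), spec$bw[4])
      ht <- min(max(spec$height[1] + spec$height[2] * zh, spec$height[3]),
                spec$height[4])
      s <- subject(i, if (runif(1) < spec$male_fraction) "M" else "F",
                   rtruncnorm1(1, spec$age[1], spec$age[2], spec$age[3],
                               spec$age[4]),
                   bw, ht, runif(1, spec$hct_range[1], spec$hct_range[2]),
                   doses = data.frame(
                     time = seq(0, horizon - 6, 12),
                     amt = if (dose_mode == "normalised") lev * 60
                           else lev * bw,
                     formulation = "fast_release"))
      eta <- rnorm(length(pop$variable)) * sqrt(pop$omega2)
      params <- individual_params(pop, eta, s)
      sim <- tryCatch({
        if (pop$name == "pk")
          simulate_pk(s, params, grid, rtol = 1e-6, atol = 1e-8,
                      restart = FALSE)
        else
          simulate_pbpk(s, params, grid, rtol = 1e-6, atol = 1e-8,
                        restart = FALSE)
      }, error = function(e) NULL)
      if (is.null(sim)) { failed <- failed + 1L; next }
      cc <- sim$conc[w]
      auc[i] <- sum(diff(grid[w]) * (head(cc, -1) + tail(cc, -1)) / 2)
      Fv[i] <- 100 * sim$F[nrow(sim)]
      tab[i] <- dt * sum(cc > threshold)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      dose_mg_kg = lev,
      auc24_mean = mean(auc, na.rm = TRUE), auc24_sd = sd(auc, na.rm = TRUE),
      F_mean = mean(Fv, na.rm = TRUE), F_sd = sd(Fv, na.rm = TRUE),
      t_above_mean = mean(tab, na.rm = TRUE),
      t_above_sd = sd(tab, na.rm = TRUE),
      n = n, failed = failed)
  }
  do.call(rbind, rows)
}
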