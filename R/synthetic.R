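# Virtual paediatric renal-transplant cohort generator.
#
# Emulates the clinical protocol: a week of stable twice-daily
# fast-release dosing (the last 48 h of which are simulated as run-in, so
# the first hospital admission sits at t = 48 h), intensive day-1
# sampling (18 points over 24 h), conversion to once-daily
# prolonged-release at 1:1 daily dose on day 2, and day-8 re-admission
# sampling (13 points).  Demographics follow the published cohort
# summaries (truncated normals); drift specifications inject the
# formulation-conversion liberation-time shift and week-scale
# intra-patient parameter drift that the adaptation procedures are meant
# to recover.

#' Cohort specification
#'
#' Demographic distributions, dosing plan and sampling plans of the
#' virtual cohort.  Defaults reproduce the study protocol: age
#' 12.9 +/- 4.17 y on `[4, 17]`, body weight 42.85 +/- 15.42 kg on
#' `[15.1, 63.8]`, height 143.4 +/- 18.16 cm on `[105, 168]`, 57% male;
#' day-1 sampling at 0, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 12.5, 13, 14,
#' 15, 16, 18, 20, 24 h after the morning dose and day-8 sampling at 0,
#' 0.5, 1, 1.5, 2, 2.5, 3, 4, 6, 8, 12, 15, 24 h; assay range 2-30
#' ng/ml (values above 30 are retained, mimicking dilution).
#'
#' The daily dose rule is mg/kg rounded to the available 0.5-mg
#' strengths (half the daily amount per administration on day 1).
#' Height and weight are drawn with a Gaussian-copula correlation so
#' derived BSA values stay realistic; haematocrit is uniform on a
#' paediatric range.
#'
#' @param n Number of subjects.
#' @param age,bw,height `c(mean, sd, min, max)` of the truncated normal.
#' @param male_fraction Probability of male sex.
#' @param hct_range Haematocrit range (uniform).
#' @param bw_height_cor Correlation of the underlying normals.
#' @param daily_mg_per_kg Daily dose rule before rounding.
#' @param dose_rounding Rounding granularity, mg.
#' @param day1_times,day8_times Sampling offsets (h) after the morning
#'   administration of days 1 and 8.
#' @param lloq,uloq Assay quantification limits, ng/ml.
#' @param run_in_h Hours of stable dosing simulated before the first
#'   admission (admission at `t = run_in_h`).
#' @return Object of class `tac_cohort_spec`.
#' @export
cohort_spec <- function(n = 21,
                        age = c(12.9, 4.17, 4, 17),
                        bw = c(42.85, 15.42, 15.1, 63.8),
                        height = c(143.4, 18.16, 105, 168),
                        male_fraction = 0.57,
                        hct_range = c(0.33, 0.45),
                        bw_height_cor = 0.7,
                        daily_mg_per_kg = 0.076,
                        dose_rounding = 0.5,
                        day1_times = c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12,
                                       12.5, 13, 14, 15, 16, 18, 20, 24),
                        day8_times = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 4, 6, 8,
                                       12, 15, 24),
                        lloq = 2, uloq = 30, run_in_h = 48) {
  for (v in list(age, bw, height))
    if (!(length(v) == 4 && v[3] < v[4] && v[2] > 0))
      stop("distribution spec must be c(mean, sd, min, max) with min < max")
  structure(list(n = n, age = age, bw = bw, height = height,
                 male_fraction = male_fraction, hct_range = hct_range,
                 bw_height_cor = bw_height_cor,
                 daily_mg_per_kg = daily_mg_per_kg,
                 dose_rounding = dose_rounding,
                 day1_times = day1_times, day8_times = day8_times,
                 lloq = lloq, uloq = uloq, run_in_h = run_in_h),
            class = "tac_cohort_spec")
}

#' Intra-patient drift specification
#'
#' Parameter changes injected at the formulation conversion, emulating
#' both the prolonged-release liberation effect and week-scale
#' intra-patient variability.  Each entry is `c(mean, sd)` of an
#' additive normal shift (truncated so the parameter stays positive).
#' Default conversion effects are the printed single-parameter
#' adaptation estimates (LibT +176 +/- 225.4 min for the
#' prolonged-release liberation; FDT +0.34 +/- 0.50 h for the
#' compartmental analogue).  Week-scale intra-patient variability of
#' clearance and absorption defaults to mean-zero shifts of roughly
#' 15% (clearance) and 25% (absorption) coefficient of variation, the
#' magnitude reported for stable tacrolimus patients; the
#' multi-parameter adaptation increments are too collinear to serve as
#' generating values.
#'
#' @param libt_shift LibT shift, minutes (PBPK).
#' @param kabs_shift K_abs shift, 1/h (PBPK).
#' @param clih_shift Cl_ih shift, 1/h (PBPK).
#' @param fdt_shift FDT shift, hours (PK).
#' @param cl_shift Cl shift, L/h (PK).
#' @param ka_shift Ka shift, ml/h (PK).
#' @param mtt_shift MTT shift, hours (PK).
#' @param drift_time Time (h) at which the shifts apply; default start
#'   of day 2 (72 h with the default 48-h run-in).
#' @return Object of class `tac_drift_spec`.
#' @export
drift_spec <- function(libt_shift = c(176, 225.4),
                       kabs_shift = c(0, 1.1),
                       clih_shift = c(0, 145),
                       fdt_shift = c(0.34, 0.5),
                       cl_shift = c(0, 0.8),
                       ka_shift = c(0, 3.5),
                       mtt_shift = c(0, 0.1),
                       drift_time = 72) {
  structure(list(libt_shift = libt_shift, kabs_shift = kabs_shift,
                 clih_shift = clih_shift, fdt_shift = fdt_shift,
                 cl_shift = cl_shift, ka_shift = ka_shift,
                 mtt_shift = mtt_shift, drift_time = drift_time),
            class = "tac_drift_spec")
}

# emulated dose titration: rescale the per-administration amount (both
# formulations, keeping the 1:1 daily conversion) until the subject's
# noise-free day-1 AUC24 approaches the target; exposure is close to
# linear in dose, so two passes suffice before rounding to strengths
titrate_doses <- function(subj, pop, params, target, rounding = 0.5,
                          run_in = 48) {
  day1_auc <- function(s) {
    grid <- seq(run_in, run_in + 24, 0.25)
    sim <- if (pop$name == "pk")
      simulate_pk(s, params, c(0, grid), rtol = 1e-6, atol = 1e-8,
                  restart = FALSE)
    else simulate_pbpk(s, params, c(0, grid), rtol = 1e-6, atol = 1e-8,
                       restart = FALSE)
    cc <- sim$conc[sim$time >= run_in]
    sum(diff(grid) * (head(cc, -1) + tail(cc, -1)) / 2)
  }
  half <- subj$doses$amt[subj$doses$formulation == "fast_release"][1]
  for (pass in 1:2) {
    auc <- day1_auc(subj)
    if (!is.finite(auc) || auc <= 0) break
    half <- half * target / auc
    half_r <- max(rounding, round(half / rounding) * rounding)
    fast <- subj$doses$formulation == "fast_release"
    subj$doses$amt[fast] <- half_r
    subj$doses$amt[!fast] <- 2 * half_r
    half <- half_r
  }
  subj
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(max(n, 10), mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a virtual cohort (no concentrations)
#'
#' Draws covariates and lays out the dosing and sampling skeleton of the
#' two-phase protocol.  Deterministic given the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A [cohort()] whose subjects carry doses and observation
#'   records with `conc = NA` (fill with [simulate_observations()]).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  set.seed(seed)
  n <- spec$n
  # correlated weight/height via Gaussian copula, then truncation
  draw_bw_ht <- function() {
    repeat {
      zb <- rnorm(1); zh <- spec$bw_height_cor * zb +
        sqrt(1 - spec$bw_height_cor^2) * rnorm(1)
      b <- spec$bw[1] + spec$bw[2] * zb
      h <- spec$height[1] + spec$height[2] * zh
      if (b >= spec$bw[3] && b <= spec$bw[4] &&
          h >= spec$height[3] && h <= spec$height[4])
        return(c(b, h))
    }
  }
  run_in <- spec$run_in_h
  subs <- lapply(seq_len(n), function(i) {
    bh <- draw_bw_ht()
    age <- rtruncnorm1(1, spec$age[1], spec$age[2], spec$age[3], spec$age[4])
    sex <- if (runif(1) < spec$male_fraction) "M" else "F"
    hct <- runif(1, spec$hct_range[1], spec$hct_range[2])
    daily <- bh[1] * spec$daily_mg_per_kg
    half <- max(spec$dose_rounding,
                round(daily / 2 / spec$dose_rounding) * spec$dose_rounding)
    full <- 2 * half  # once-daily conversion is 1:1 on the daily dose
    fast_times <- seq(0, run_in + 12, by = 12)       # run-in + day 1 (q12h)
    slow_times <- run_in + 24 + 24 * (0:6)           # days 2-8 (q24h)
    doses <- rbind(
      data.frame(time = fast_times, amt = half, formulation = "fast_release"),
      data.frame(time = slow_times, amt = full,
                 formulation = "prolonged_release"))
    obs <- data.frame(
      time = c(run_in + spec$day1_times, run_in + 168 + spec$day8_times),
      conc = NA_real_, blq = FALSE)
    subject(sprintf("S%02d", i), sex, age, bh[1], bh[2], hct,
            doses = doses, observations = obs)
  })
  cohort(subs)
}

#' Simulate observations for a cohort
#'
#' Draws each subject's random effects from the population model,
#' applies the drift timeline, simulates the structural model over the
#' full protocol and adds residual noise on the log scale.  Values at or
#' below the lower quantification limit are flagged BLQ; values above
#' the upper limit are retained (dilution).
#'
#' @param coh A [generate_cohort()] result (or any cohort whose
#'   observation times are set).
#' @param pop A [population_model()] (built-in structural models only).
#' @param drift Optional [drift_spec()].
#' @param seed Integer seed.
#' @param noise Add residual noise (disable to obtain noise-free
#'   profiles).
#' @param spec The [cohort_spec()] supplying assay limits.
#' @param titrate_auc24 Emulated therapeutic drug monitoring: before the
#'   study week, each subject's dose is assumed titrated to a stable
#'   day-1 exposure, so the per-administration amount is rescaled
#'   (and rounded to the available strengths) until the subject's
#'   predicted day-1 AUC24 approaches this target (ng/ml*h).  `NULL`
#'   keeps the mg/kg doses of [generate_cohort()].
#' @return The cohort with concentrations filled in; per-subject truth
#'   (eta draws, drift multipliers and parameter timelines) in
#'   `attr(, "truth")`.
#' @export
simulate_observations <- function(coh, pop, drift = NULL, seed = 1,
                                  noise = TRUE, spec = cohort_spec(),
                                  titrate_auc24 = 200) {
  set.seed(seed + 1000L)
  stopifnot(pop$name %in% c("pk", "pbpk"))
  truth <- list()
  for (i in seq_along(coh$subjects)) {
    subj <- coh$subjects[[i]]
    eta <- rnorm(length(pop$variable)) * sqrt(pop$omega2)
    params <- individual_params(pop, eta, subj)
    if (!is.null(titrate_auc24))
      subj <- titrate_doses(subj, pop, params, titrate_auc24,
                            spec$dose_rounding, run_in = spec$run_in_h)
    timeline <- NULL
    dr <- NULL
    if (!is.null(drift)) {
      p2 <- params
      # additive shift truncated so the parameter keeps a positive floor
      shifted <- function(value, shift, floor) {
        max(value + rnorm(1, shift[1], shift[2]), floor)
      }
      if (pop$name == "pbpk") {
        libt <- shifted(p2$LibT[["prolonged_release"]],
                        drift$libt_shift, 10)
        kabs <- shifted(p2$Kabs, drift$kabs_shift, 0.2)
        clih <- shifted(p2$Clih, drift$clih_shift, 100)
        dr <- c(libt_shift = libt - p2$LibT[["prolonged_release"]],
                kabs_shift = kabs - p2$Kabs,
                clih_shift = clih - p2$Clih)
        p2$LibT[["prolonged_release"]] <- libt
        p2$Kabs <- kabs
        p2$Clih <- clih
      } else {
        fdt <- shifted(p2$FDT[["prolonged_release"]], drift$fdt_shift, 0.1)
        cl <- shifted(p2$Cl, drift$cl_shift, 0.3)
        ka <- shifted(p2$Ka, drift$ka_shift, 1)
        mtt <- shifted(p2$MTT, drift$mtt_shift, 0.1)
        dr <- c(fdt_shift = fdt - p2$FDT[["prolonged_release"]],
                cl_shift = cl - p2$Cl, ka_shift = ka - p2$Ka,
                mtt_shift = mtt - p2$MTT)
        p2$FDT[["prolonged_release"]] <- fdt
        p2$Cl <- cl
        p2$Ka <- ka
        p2$MTT <- mtt
      }
      timeline <- list(list(time = drift$drift_time, params = p2))
    }
    tms <- sort(unique(c(0, subj$observations$time)))
    sim <- if (pop$name == "pk")
      simulate_pk(subj, params, tms, timeline = timeline)
    else simulate_pbpk(subj, params, tms, timeline = timeline)
    cc <- sim$conc[match(round(subj$observations$time, 9),
                         round(sim$time, 9))]
    if (noise) cc <- exp(log(pmax(cc, 1e-12)) + rnorm(length(cc), 0,
                                                      sqrt(pop$sigma2)))
    subj$observations$conc <- cc
    subj$observations$blq <- cc <= spec$lloq
    coh$subjects[[i]] <- subj
    truth[[subj$id]] <- list(eta = setNames(eta, pop$variable),
                             drift = dr, params = params,
                             timeline = timeline)
  }
  attr(coh, "truth") <- truth
  coh
}
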