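# Reduced whole-body PBPK model.
#
# Gut lumen (zero-order liberation over LibT with a competing first-order
# loss K_elib and first-order chronomodulated absorption K_abs), gut
# tissue perfused by the portal flow, flow-limited liver / kidney / fat /
# others with venous equilibration through Poulin-Theil partition
# coefficients, and a whole-blood pool in which red-blood-cell binding is
# a saturable equilibrium (B_max, K_d).  Hepatic elimination acts on the
# unbound plasma concentration in the liver venous outflow,
# `fu_p * C_p,vl`, scaled by the total intrinsic clearance
# `Cl_ih * V_l` and the circadian waveform.

#' Poulin-Theil tissue:plasma partition coefficient
#'
#' Computes `R_t` (tissue:plasma) from the solubility of the drug in
#' neutral lipids, phospholipids and water, weighting lipid solubility by
#' the octanol-water partition coefficient.  For non-adipose tissues the
#' tissue unbound fraction defaults to the standard assumption that
#' interstitial protein binding is half as strong as in plasma,
#' `fu_t = 1 / (1 + 0.5 (1 - fu_p)/fu_p)`; for adipose the unbound
#' fraction is 1.
#'
#' @param logP Octanol-water log partition coefficient of the drug.
#' @param fu_p Unbound plasma fraction in (0, 1].
#' @param tissue,plasma Named lists or vectors with composition fractions
#'   `f_neutral_lipid`, `f_phospholipid`, `f_water` (each in `[0, 1]`).
#' @param adipose Logical: use the adipose variant.
#' @param fu_t Optional override of the tissue unbound fraction.
#' @return `list(R_t, fu_t)`.
#' @export
poulin_theil_partition <- function(logP, fu_p, tissue, plasma,
                                   adipose = FALSE, fu_t = NULL) {
  comp <- function(x) {
    v <- unlist(x)[c("f_neutral_lipid", "f_phospholipid", "f_water")]
    if (anyNA(v) || any(v < 0) || any(v > 1))
      stop("composition fractions must lie in [0, 1]")
    if (sum(v) == 0) stop("degenerate composition: all fractions zero")
    v
  }
  tw <- comp(tissue); pw <- comp(plasma)
  P <- 10^logP
  sol <- function(v) P * (v[1] + 0.3 * v[2]) + (v[3] + 0.7 * v[2])
  if (is.null(fu_t))
    fu_t <- if (adipose) 1 else 1 / (1 + 0.5 * (1 - fu_p) / fu_p)
  R_t <- (sol(tw) / sol(pw)) * fu_p / fu_t
  list(R_t = unname(R_t), fu_t = unname(fu_t))
}

#' Liberation-dependent gut-lumen loss rate constant
#'
#' The first-order rate constant of the tacrolimus fraction that escapes
#' absorption scales linearly with the liberation time:
#' `K_elib(LibT) = K_elib(LibT = 100) * LibT / 100`.  Slower liberation
#' leaves more undissolved drug in transit, hence greater loss.
#'
#' @param LibT Liberation time, minutes (> 0).
#' @param K_elib_ref Loss rate constant at `LibT = 100` min, 1/h.
#' @param LibT_ref Reference liberation time, minutes.
#' @return Loss rate constant, 1/h.
#' @examples
#' k_elib(200, 0.5) # == 1.0
#' @export
k_elib <- function(LibT, K_elib_ref, LibT_ref = 100) {
  if (any(LibT <= 0)) stop("LibT must be positive")
  K_elib_ref * LibT / LibT_ref
}

#' Whole-blood concentration from the red-blood-cell binding model
#'
#' Equilibrium mixing of the plasma and red-blood-cell pools: the
#' RBC-bound concentration follows a saturable law
#' `B_max * C_u / (K_d + C_u)`, plasma total is `C_u / fu_p`, and whole
#' blood mixes the two pools by haematocrit.
#'
#' @param C_u Unbound concentration, ug/L.
#' @param B_max Maximum RBC binding capacity, ug/L.
#' @param K_d RBC dissociation constant, ug/L.
#' @param haematocrit Haematocrit fraction.
#' @param fu_p Unbound plasma fraction.
#' @return `list(whole_blood, rbc_bound, plasma_total)` in ng/ml
#'   (= ug/L).
#' @examples
#' blood_partition(1.6, B_max = 11.0, K_d = 1.6, haematocrit = 0.35,
#'                 fu_p = 0.012)$rbc_bound # half saturation: 5.5
#' @export
blood_partition <- function(C_u, B_max, K_d, haematocrit, fu_p) {
  stopifnot(C_u >= 0, B_max > 0, K_d > 0,
            haematocrit > 0, haematocrit < 1, fu_p > 0, fu_p <= 1)
  rbc <- B_max * C_u / (K_d + C_u)
  plasma <- C_u / fu_p
  list(whole_blood = (1 - haematocrit) * plasma + haematocrit * rbc,
       rbc_bound = rbc, plasma_total = plasma)
}

#' PBPK model parameter set
#'
#' Drug-specific parameters of the reduced whole-body model.  Defaults
#' are the fitted paediatric population means shipped with the package.
#' `LibT` is given per formulation in minutes, as reported for the
#' fast-release product; `K_elib_ref` anchors the liberation-dependent
#' loss (see [k_elib()]).
#'
#' @param Clih Intrinsic hepatic clearance per liver volume, 1/h
#'   (total intrinsic clearance is `Clih * V_liver`).
#' @param Bmax Maximum RBC binding capacity, ug/L.
#' @param Kd RBC binding dissociation constant, ug/L.
#' @param Kabs Gut absorption rate constant, 1/h (chronomodulated).
#' @param LibT Named numeric, liberation time per formulation, minutes.
#' @param K_elib_ref Gut-lumen loss rate constant at `LibT = 100` min,
#'   1/h.
#' @param fu_p Unbound plasma fraction.
#' @param logP Lipophilicity descriptor used by the Poulin-Theil method.
#'   Not a fitted quantity; a drug-database constant.
#' @param circadian A [circadian_profile()].
#' @return Object of class `pbpk_params`.
#' @export
pbpk_params <- function(Clih = 956.6, Bmax = 11.0, Kd = 1.6, Kabs = 4.5,
                        LibT = c(fast_release = 100, prolonged_release = 100),
                        K_elib_ref = 10.0, fu_p = 0.012, logP = 3.3,
                        circadian = circadian_profile(0.16, 0.7)) {
  vals <- c(Clih = Clih, Bmax = Bmax, Kd = Kd, Kabs = Kabs,
            K_elib_ref = K_elib_ref)
  if (any(vals <= 0)) stop("all PBPK parameters must be positive")
  if (any(LibT <= 0)) stop("LibT must be positive")
  if (!(fu_p > 0 && fu_p <= 1)) stop("fu_p must lie in (0, 1]")
  if (is.null(names(LibT))) names(LibT) <- FORMULATIONS[seq_along(LibT)]
  structure(list(Clih = Clih, Bmax = Bmax, Kd = Kd, Kabs = Kabs,
                 LibT = LibT, K_elib_ref = K_elib_ref, fu_p = fu_p,
                 logP = logP, circadian = circadian),
            class = "pbpk_params")
}

ref_table_cache <- new.env(parent = emptyenv())

ref_table <- function(name) {
  if (!is.null(ref_table_cache[[name]])) return(ref_table_cache[[name]])
  path <- system.file("extdata", paste0(name, ".csv"), package = "chronotac")
  tab <- read.csv(path)
  ref_table_cache[[name]] <- tab
  tab
}

#' Scale reference physiology to a subject
#'
#' Tissue volumes scale linearly with body weight from reference
#' fractions; blood flows scale with allometric cardiac output
#' `CO = 336 * (BW/70)^0.75` L/h, allocated by reference fractions.  The
#' "others" tissue receives the body volume (`BW / 1.05` L) and cardiac
#' output not assigned to a named tissue.  Female subjects carry a
#' slightly larger adipose fraction (+0.05).  Haematocrit is taken from
#' the subject.
#'
#' @param subj A [subject()].
#' @param reference Data frame of reference fractions; defaults to the
#'   packaged table (ICRP-style values for a 70-kg adult male).
#' @return Object of class `tac_physiology` with named `volumes` (L),
#'   `flows` (L/h), `haematocrit` and the cardiac output.
#' @export
scale_physiology <- function(subj, reference = NULL) {
  if (is.null(reference)) reference <- ref_table("reference_physiology")
  if (subj$age < 2)
    warning("age below 2 y is outside the supported covariate range")
  bw <- subj$body_weight
  frac <- setNames(reference$volume_frac_bw, reference$tissue)
  if (subj$sex == "F") frac["fat"] <- frac["fat"] + 0.05
  vols <- frac * bw
  body_volume <- bw / 1.05
  vols <- c(vols, others = unname(body_volume - sum(vols)))
  if (vols[["others"]] <= 0) stop("inconsistent reference volume fractions")
  co <- 336 * (bw / 70)^0.75
  ff <- setNames(reference$flow_frac_co, reference$tissue)
  flows <- c(gut = unname(ff[["gut"]]) * co,
             hepatic_artery = unname(ff[["liver"]]) * co,
             kidney = unname(ff[["kidney"]]) * co,
             fat = unname(ff[["fat"]]) * co)
  flows <- c(flows, others = unname(co - sum(flows)))
  structure(list(volumes = vols, flows = flows, cardiac_output = co,
                 haematocrit = subj$haematocrit, body_weight = bw),
            class = "tac_physiology")
}

# partition coefficients for the modelled tissues of one parameter set
pbpk_partitions <- function(params) {
  comp <- ref_table("tissue_composition")
  rownames(comp) <- comp$tissue
  cols <- c("f_neutral_lipid", "f_phospholipid", "f_water")
  plasma <- comp["plasma", cols]
  tiss <- c(gut = "gut", liver = "liver", kidney = "kidney",
            fat = "adipose", others = "others")
  vapply(tiss, function(tn) {
    poulin_theil_partition(params$logP, params$fu_p, comp[tn, cols], plasma,
                           adipose = comp[tn, "adipose"] == 1)$R_t
  }, numeric(1))
}

pbpk_state_names <- c("lumen", "gut", "liver", "kidney", "fat", "others",
                      "blood", "eliminated", "lost", "absorbed", "input")

pbpk_parms_head <- function(p, phys, R) {
  v <- phys$volumes; q <- phys$flows
  c(p$Kabs,
    k_elib(unname(p$LibT["fast_release"]), p$K_elib_ref),  # placeholder, per-phase below
    p$Clih * v[["liver"]],
    p$fu_p, phys$haematocrit, p$Bmax / 1000, p$Kd / 1000, v[["blood"]],
    p$circadian$r_chr, p$circadian$t_chr, p$circadian$breakpoints,
    v[["gut"]], v[["liver"]], v[["kidney"]], v[["fat"]], v[["others"]],
    R[["gut"]], R[["liver"]], R[["kidney"]], R[["fat"]], R[["others"]],
    q[["gut"]], q[["hepatic_artery"]], q[["kidney"]], q[["fat"]],
    q[["others"]])
}

#' Simulate the circadian reduced PBPK model
#'
#' Integrates the model over a subject's dosing history.  Liberation of
#' each dose is zero-order at rate `amt/LibT` for the formulation's
#' `LibT`; the lumen loses drug by `K_elib(LibT)` and feeds gut tissue by
#' `K_abs * f_w(t - t_chr)`.  The returned concentration is whole blood
#' (ng/ml); `F(t)` accumulates hepatically cleared mass over dosed mass.
#'
#' The gut-lumen loss constant follows the liberation time of the *last*
#' formulation dosed before each phase of the parameter timeline.
#'
#' @param subj A [subject()].
#' @param params A [pbpk_params()] object.
#' @param times Output times, h.
#' @param physiology Optional [scale_physiology()] result; computed from
#'   the subject when missing.
#' @param timeline Optional parameter timeline as in [simulate_pk()].
#' @param rtol,atol Solver tolerances.
#' @return A `tac_sim` data frame (`time`, `conc`, `F`) with `ledger` and
#'   `states` attributes.
#' @export
simulate_pbpk <- function(subj, params, times, physiology = NULL,
                          timeline = NULL, rtol = 1e-8, atol = 1e-10, restart = TRUE) {
  stopifnot(inherits(params, "pbpk_params"))
  if (is.null(physiology)) physiology <- scale_physiology(subj)
  times <- sort(unique(times))
  tl <- normalize_timeline(params, timeline)
  doses <- subj$doses[subj$doses$time < times[length(times)], , drop = FALSE]
  windows <- build_windows(doses, tl)
  R <- pbpk_partitions(params)
  tl_t <- vapply(tl, `[[`, numeric(1), "time")
  phases <- lapply(seq_along(tl), function(i) {
    p <- tl[[i]]$params
    head <- pbpk_parms_head(p, physiology, pbpk_partitions(p))
    # K_elib follows the formulation currently being dosed
    from <- max(tl_t[i], times[1])
    prior <- doses[doses$time <= from + 1e-9, , drop = FALSE]
    form <- if (nrow(prior)) prior$formulation[nrow(prior)] else
      if (nrow(doses)) doses$formulation[1] else "fast_release"
    head[2] <- k_elib(unname(p$LibT[form]), p$K_elib_ref)
    list(from = from, parms_head = head)
  })
  # additionally split phases at formulation switches so K_elib tracks them
  switches <- doses$time[c(FALSE, diff(as.integer(factor(
    doses$formulation, levels = FORMULATIONS))) != 0)]
  for (s in switches) {
    i <- max(which(tl_t <= s))
    p <- tl[[i]]$params
    head <- pbpk_parms_head(p, physiology, pbpk_partitions(p))
    form <- doses$formulation[max(which(doses$time <= s))]
    head[2] <- k_elib(unname(p$LibT[form]), p$K_elib_ref)
    phases <- c(phases, list(list(from = s, parms_head = head)))
  }
  ord <- order(vapply(phases, `[[`, numeric(1), "from"))
  phases <- phases[ord]
  y0 <- setNames(numeric(11), pbpk_state_names)
  st <- integrate_segments(y0, times, phases, windows, "pbpk", rtol, atol, restart = restart)
  colnames(st) <- pbpk_state_names
  vb <- physiology$volumes[["blood"]]
  conc <- 1000 * st[, "blood"] / vb
  Ft <- ifelse(st[, "input"] > 0, st[, "eliminated"] / st[, "input"],
               NA_real_)
  final <- st[nrow(st), ]
  ledger <- c(input = final[["input"]],
              absorbed = final[["absorbed"]],
              eliminated = final[["eliminated"]],
              lost = final[["lost"]],
              F_end = if (final[["input"]] > 0)
                final[["eliminated"]] / final[["input"]] else NA_real_,
              balance_rel_error = if (final[["input"]] > 0)
                abs(final[["input"]] -
                      sum(final[c("lumen", "gut", "liver", "kidney", "fat",
                                  "others", "blood", "eliminated",
                                  "lost")])) / final[["input"]] else 0)
  out <- new_tac_sim(fast_df(times, conc, Ft),
                     ledger, "pbpk", flagged = final[["input"]] == 0)
  attr(out, "states") <- final
  attr(out, "physiology") <- physiology
  out
}
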