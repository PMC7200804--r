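# Two-compartment disposition with a 3-segment
# compartmental-absorption-and-transit (CAT3) gut.
#
# Topology: zero-order dose input (duration FDT) into the stomach; serial
# transit stomach -> SI1 -> SI2 -> SI3 -> colon at rate k_t = 1/MTT per
# region; first-order absorption k_ta * f_w(t - t_chr) from each small
# intestine segment into the central compartment; no absorption from
# stomach or colon; central elimination Cl * f_w(t - t_chr) * C_c;
# inter-compartmental clearance Cld between central and peripheral.

#' CAT3 model parameter set
#'
#' Structural parameters of the circadian two-compartment/CAT3 model.
#' Defaults are the fitted paediatric renal-transplant population means
#' shipped with the package.
#'
#' `Ka` (ml/h) acts on the small-intestine fluid concentration; the
#' operative absorption rate constant is `k_ta = Ka / V_cat_si` (1/h).
#' Only the ratio matters, so `V_cat_si` is a fixed model constant, never
#' estimated.  `FDT` is the duration of the zero-order dose input and is
#' given per formulation; it is not a population parameter.
#'
#' @param Cl Systemic clearance, L/h (diurnal value; chronomodulated).
#' @param Cld Distribution clearance, L/h.
#' @param Vc,Vp Central and peripheral volumes, L.
#' @param Ka Absorption constant, ml/h (chronomodulated).
#' @param MTT Mean transit time per gut region, h; `k_t = 1/MTT`.
#' @param FDT Named numeric: zero-order input duration (h) per
#'   formulation.
#' @param V_cat_si Small-intestine fluid volume, L (per segment).
#' @param V_cat_s,V_cat_c Stomach and colon fluid volumes, L
#'   (bookkeeping only: no absorption occurs there).
#' @param circadian A [circadian_profile()].
#' @return Object of class `pk_params`.
#' @export
pk_params <- function(Cl = 5.41, Cld = 46.5, Vc = 23.0, Vp = 39.1,
                      Ka = 13.8, MTT = 0.72,
                      FDT = c(fast_release = 0.5, prolonged_release = 0.5),
                      V_cat_si = 0.065, V_cat_s = 0.05, V_cat_c = 0.3,
                      circadian = circadian_profile(0.29, 0.7)) {
  vals <- c(Cl = Cl, Cld = Cld, Vc = Vc, Vp = Vp, Ka = Ka, MTT = MTT,
            V_cat_si = V_cat_si, V_cat_s = V_cat_s, V_cat_c = V_cat_c)
  if (any(vals <= 0)) stop("all PK parameters must be positive")
  if (any(FDT <= 0)) stop("FDT must be positive")
  if (is.null(names(FDT))) names(FDT) <- FORMULATIONS[seq_along(FDT)]
  structure(list(Cl = Cl, Cld = Cld, Vc = Vc, Vp = Vp, Ka = Ka, MTT = MTT,
                 FDT = FDT, V_cat_si = V_cat_si, V_cat_s = V_cat_s,
                 V_cat_c = V_cat_c, circadian = circadian),
            class = "pk_params")
}

pk_state_names <- c("stomach", "si1", "si2", "si3", "colon", "central",
                    "peripheral", "eliminated", "absorbed", "input")

# numeric parameter head in the layout the C code expects
pk_parms_head <- function(p) {
  c(1 / p$MTT,                      # kt
    p$Ka / (p$V_cat_si * 1000),     # kta = Ka (ml/h) / V_cat,si (ml)
    p$Cl, p$Cld, p$Vc, p$Vp,
    p$circadian$r_chr, p$circadian$t_chr, p$circadian$breakpoints)
}

#' CAT3 model derivatives
#'
#' Pure-R right-hand side of the PK/CAT3 model, exposed for inspection
#' and testing; [simulate_pk()] integrates the identical compiled
#' version.
#'
#' @param state Named numeric vector of compartment amounts (mg), in the
#'   order `stomach, si1, si2, si3, colon, central, peripheral,
#'   eliminated, absorbed, input`.
#' @param t Time, h.
#' @param params A [pk_params()] object.
#' @param active_doses `data.frame(time, amt, formulation)` of doses; a
#'   dose contributes the zero-order rate `amt/FDT` while
#'   `t` lies in `[time, time + FDT)`.
#' @return Named derivative vector, mg/h.
#' @export
pk_rhs <- function(state, t, params, active_doses = NULL) {
  p <- params
  fwv <- waveform(t - p$circadian$t_chr, p$circadian)
  rate <- 0
  if (!is.null(active_doses) && nrow(active_doses)) {
    dur <- vapply(active_doses$formulation,
                  function(f) unname(p$FDT[f]), numeric(1))
    on <- t >= active_doses$time & t < active_doses$time + dur
    rate <- sum(active_doses$amt[on] / dur[on])
  }
  kt <- 1 / p$MTT
  kta <- p$Ka / (p$V_cat_si * 1000) * fwv
  cc <- state["central"] / p$Vc
  cp <- state["peripheral"] / p$Vp
  absr <- kta * (state["si1"] + state["si2"] + state["si3"])
  elim <- p$Cl * fwv * cc
  d <- c(
    stomach    = rate - kt * state[["stomach"]],
    si1        = kt * state[["stomach"]] - (kt + kta) * state[["si1"]],
    si2        = kt * state[["si1"]] - (kt + kta) * state[["si2"]],
    si3        = kt * state[["si2"]] - (kt + kta) * state[["si3"]],
    colon      = kt * state[["si3"]],
    central    = unname(absr + p$Cld * (cp - cc) - elim),
    peripheral = unname(p$Cld * (cc - cp)),
    eliminated = unname(elim),
    absorbed   = unname(absr),
    input      = rate
  )
  d
}

#' Simulate the circadian PK/CAT3 model
#'
#' Integrates the model over a subject's dosing history and returns the
#' predicted whole-blood concentration `C_c` (ng/ml), the running
#' absolute bioavailability `F(t)` (cumulative cleared mass over
#' cumulative dosed mass), and a mass-balance ledger.
#'
#' @param subj A [subject()].
#' @param params A [pk_params()] object.
#' @param times Output times, h; must cover the doses of interest.
#' @param timeline Optional list of `list(time =, params =)` parameter
#'   changes used by the adaptation procedures; each entry replaces the
#'   parameter set from its change time onward.
#' @param rtol,atol Solver tolerances (relative; absolute in mg).
#' @return A `tac_sim` data frame with columns `time`, `conc` (ng/ml) and
#'   `F`, plus attributes `ledger` (final mass accounting) and `states`
#'   (final compartment amounts).
#' @export
simulate_pk <- function(subj, params, times, timeline = NULL,
                        rtol = 1e-8, atol = 1e-10, restart = TRUE) {
  stopifnot(inherits(params, "pk_params"))
  times <- sort(unique(times))
  tl <- normalize_timeline(params, timeline)
  doses <- subj$doses[subj$doses$time < times[length(times)], , drop = FALSE]
  windows <- build_windows(doses, tl)
  phases <- lapply(tl, function(e)
    list(from = max(e$time, times[1]), parms_head = pk_parms_head(e$params)))
  y0 <- setNames(numeric(10), pk_state_names)
  st <- integrate_segments(y0, times, phases, windows, "pk", rtol, atol, restart = restart)
  colnames(st) <- pk_state_names
  if (length(tl) == 1L) {
    vc <- params$Vc
  } else {
    # Vc can change along the timeline; use the phase in effect at each time
    tl_t <- vapply(tl, `[[`, numeric(1), "time")
    vc <- vapply(times, function(tt)
      tl[[max(which(tl_t <= tt + 1e-12))]]$params$Vc, numeric(1))
  }
  conc <- 1000 * st[, "central"] / vc
  Ft <- ifelse(st[, "input"] > 0, st[, "eliminated"] / st[, "input"],
               NA_real_)
  final <- st[nrow(st), ]
  ledger <- c(input = final[["input"]],
              absorbed = final[["absorbed"]],
              eliminated = final[["eliminated"]],
              colon = final[["colon"]],
              F_end = if (final[["input"]] > 0)
                final[["eliminated"]] / final[["input"]] else NA_real_,
              balance_rel_error = if (final[["input"]] > 0)
                abs(final[["input"]] -
                      sum(final[c("stomach", "si1", "si2", "si3", "colon",
                                  "central", "peripheral", "eliminated")])) /
                  final[["input"]] else 0)
  out <- new_tac_sim(fast_df(times, conc, Ft),
                     ledger, "pk", flagged = final[["input"]] == 0)
  attr(out, "states") <- final
  out
}
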