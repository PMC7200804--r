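# Shared ODE integration machinery.
#
# Dose inputs are zero-order windows, so the vector field is discontinuous
# at window edges (and at parameter-timeline change points during
# adaptation).  Integration is split into smooth segments and lsoda is
# restarted at each boundary; requested output times are collected along
# the way.

MAXDOSE <- 40L
PK_NP <- 12L + 1L + 3L * MAXDOSE
PBPK_NP <- 29L + 1L + 3L * MAXDOSE

# dose block: ndose, then (start, duration, rate) triples, padded
dose_block <- function(windows, np_head, np_total) {
  nd <- windows$n
  if (nd > MAXDOSE) stop("more than ", MAXDOSE, " dose events")
  block <- numeric(np_total - np_head)
  block[1] <- nd
  if (nd)
    block[1 + seq_len(3 * nd)] <- as.numeric(rbind(windows$start,
                                                   windows$dur,
                                                   windows$rate))
  block
}

# integrate one model over [min(times), max(times)]; phases is a list of
# (from, parms_head) with parms constant inside a phase.  Returns the
# matrix of states at `times`.
#
# With restart = TRUE the solver is restarted at every dose-window edge
# and phase change (exact handling of the discontinuous input).  With
# restart = FALSE a phase is integrated in a single lsoda call with the
# edges inserted as output points; the step-size control absorbs the
# kinks (relative error ~1e-6 at rtol 1e-6), which is ample for the
# inner loops of estimation and an order of magnitude faster.
integrate_segments <- function(y0, times, phases, windows, model,
                               rtol, atol, restart = TRUE) {
  spec <- switch(model,
    pk   = list(func = "chronotac_pk_derivs", init = "chronotac_pk_init",
                np_head = 12L, np = PK_NP),
    pbpk = list(func = "chronotac_pbpk_derivs", init = "chronotac_pbpk_init",
                np_head = 29L, np = PBPK_NP))
  t0 <- times[1]
  tend <- times[length(times)]
  edges <- sort(unique(c(t0, tend,
                         windows$start, windows$start + windows$dur,
                         vapply(phases, `[[`, numeric(1), "from"))))
  edges <- edges[edges >= t0 & edges <= tend]
  blk <- dose_block(windows, spec$np_head, spec$np)
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0))
  out[1, ] <- y0
  y <- y0
  phase_from <- vapply(phases, `[[`, numeric(1), "from")
  if (!restart) {
    # one lsoda call per phase, edges inserted as output points
    cuts <- sort(unique(c(t0, phase_from[phase_from > t0 & phase_from < tend],
                          tend)))
    for (i in seq_len(length(cuts) - 1L)) {
      a <- cuts[i]; b <- cuts[i + 1L]
      ph <- phases[[max(which(phase_from <= a + 1e-12))]]
      tseq <- sort(unique(c(a, b, times[times > a & times < b],
                            edges[edges > a & edges < b])))
      sol <- deSolve::lsoda(y = y, times = tseq, func = spec$func,
                            parms = c(ph$parms_head, blk),
                            dllname = "chronotac", initfunc = spec$init,
                            rtol = rtol, atol = atol, maxsteps = 50000)
      if (attr(sol, "istate")[1] < 0)
        stop(sprintf("ODE solver failed in the %s model near t = %.3f h",
                     model, sol[nrow(sol), 1]))
      idx <- match(round(times, 9), round(tseq, 9))
      take <- which(!is.na(idx) & times > a)
      out[take, ] <- sol[idx[take], -1, drop = FALSE]
      y <- sol[nrow(sol), -1]
    }
    return(out)
  }
  for (i in seq_len(length(edges) - 1L)) {
    a <- edges[i]; b <- edges[i + 1L]
    if (b <= a) next
    ph <- phases[[max(which(phase_from <= a + 1e-12))]]
    parms <- c(ph$parms_head, blk)
    inside <- which(times > a & times < b)
    tseq <- c(a, times[inside], b)
    sol <- deSolve::lsoda(y = y, times = tseq, func = spec$func,
                          parms = parms, dllname = "chronotac",
                          initfunc = spec$init, rtol = rtol, atol = atol,
                          maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("ODE solver failed in the %s model near t = %.3f h",
                   model, sol[nrow(sol), 1]))
    if (length(inside))
      out[inside, ] <- sol[1 + seq_along(inside), -1, drop = FALSE]
    y <- sol[nrow(sol), -1]
    hit <- which(abs(times - b) < 1e-12)
    if (length(hit)) out[hit, ] <- rep(y, each = length(hit))
  }
  out
}

# duration (h) of the zero-order input window of one dose, given the
# params in effect when the dose is given
input_duration <- function(params, formulation) {
  if (!is.null(params$FDT)) {
    unname(params$FDT[formulation])
  } else {
    unname(params$LibT[formulation]) / 60  # LibT stored in minutes
  }
}

# build zero-order input windows for a subject's doses under a parameter
# timeline (list of list(time, params); first entry must cover -Inf)
build_windows <- function(doses, timeline) {
  if (!nrow(doses))
    return(list(start = numeric(), dur = numeric(), rate = numeric(),
                n = 0L))
  if (length(timeline) == 1L) {
    dur <- input_duration(timeline[[1]]$params, doses$formulation)
  } else {
    tl_t <- vapply(timeline, `[[`, numeric(1), "time")
    dur <- vapply(seq_len(nrow(doses)), function(i) {
      p <- timeline[[max(which(tl_t <= doses$time[i] + 1e-12))]]$params
      input_duration(p, doses$formulation[i])
    }, numeric(1))
  }
  list(start = doses$time, dur = dur, rate = doses$amt / dur,
       n = nrow(doses))
}

normalize_timeline <- function(params, timeline) {
  base <- list(list(time = -Inf, params = params))
  if (is.null(timeline)) return(base)
  tl <- timeline[order(vapply(timeline, `[[`, numeric(1), "time"))]
  c(base, tl)
}

new_tac_sim <- function(df, ledger, model, flagged = FALSE) {
  structure(df, ledger = ledger, model = model, flagged = flagged,
            class = c("tac_sim", "data.frame"))
}

# cheap data.frame construction for the simulation hot path
fast_df <- function(time, conc, F) {
  structure(list(time = time, conc = conc, F = F),
            class = "data.frame",
            row.names = .set_row_names(length(time)))
}

#' @export
print.tac_sim <- function(x, ...) {
  led <- attr(x, "ledger")
  cat(sprintf("%s simulation: %d time points, F(end) = %s, mass balance error %.2e\n",
              attr(x, "model"), nrow(x),
              if (is.na(led["F_end"])) "undefined" else
                sprintf("%.1f%%", 100 * led["F_end"]),
              led["balance_rel_error"]))
  invisible(NextMethod())
}
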