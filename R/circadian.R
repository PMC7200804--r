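#' Circadian modulation profile
#'
#' The 24-h periodic waveform used to chronomodulate clearance and
#' absorption.  The waveform equals 1 during the diurnal phase
#' `[0, t1)`, descends linearly to `r_chr` over `[t1, t2)`, stays at
#' `r_chr` during the nocturnal phase `[t2, t3)` and returns linearly to 1
#' over `[t3, t4)`.  The phase parameter `t_chr` shifts the diurnal onset
#' so that model time 0 (the morning reference of the dataset) need not
#' coincide with the start of the diurnal phase.
#'
#' Only `r_chr` and `t_chr` carry inter-individual variability in the
#' population models; the breakpoints fix the shape.
#'
#' @param r_chr Nocturnal reduction factor, dimensionless in (0, 1].
#' @param t_chr Phase offset in hours: the diurnal phase starts at
#'   `t = t_chr`.
#' @param breakpoints Numeric vector `c(t1, t2, t3, t4)` in hours, with
#'   `0 < t1 < t2 < t3 < t4 <= 24`.  Defaults to `c(10, 12, 22, 24)`,
#'   i.e. 2-h transition ramps.
#' @return An object of class `circadian_profile`.
#' @examples
#' prof <- circadian_profile(r_chr = 0.29, t_chr = 0.7)
#' waveform(c(5, 11, 17), circadian_profile(0.29))
#' @export
circadian_profile <- function(r_chr, t_chr = 0, breakpoints = c(10, 12, 22, 24)) {
  stopifnot(is.numeric(r_chr), length(r_chr) == 1L,
            is.numeric(t_chr), length(t_chr) == 1L,
            is.numeric(breakpoints), length(breakpoints) == 4L)
  if (!(r_chr > 0 && r_chr <= 1))
    stop("`r_chr` must lie in (0, 1], got ", r_chr)
  if (!(breakpoints[1] > 0 && all(diff(breakpoints) > 0) && breakpoints[4] <= 24))
    stop("breakpoints must satisfy 0 < t1 < t2 < t3 < t4 <= 24")
  structure(
    list(r_chr = r_chr, t_chr = t_chr, breakpoints = as.numeric(breakpoints)),
    class = "circadian_profile"
  )
}

#' @export
print.circadian_profile <- function(x, ...) {
  cat(sprintf(
    "circadian profile: r_chr = %.3g, t_chr = %.3g h, breakpoints %s h\n",
    x$r_chr, x$t_chr, paste(x$breakpoints, collapse = "/")))
  invisible(x)
}

is_circadian_profile <- function(x) inherits(x, "circadian_profile")

#' Evaluate the 24-h periodic waveform
#'
#' Evaluates the unphased waveform `f_w(t)` of a [circadian_profile()].
#' The profile's phase `t_chr` is *not* applied here; phase handling
#' belongs to [modulate()].
#'
#' @param t Time in hours (any real; reduced modulo 24).
#' @param profile A [circadian_profile()].
#' @return Dimensionless factor in `[r_chr, 1]`, same length as `t`.
#' @export
waveform <- function(t, profile) {
  if (!is_circadian_profile(profile)) stop("`profile` must be a circadian_profile")
  bp <- profile$breakpoints
  r <- profile$r_chr
  u <- t %% 24
  out <- numeric(length(u))
  out[u < bp[1]] <- 1
  i <- u >= bp[1] & u < bp[2]
  out[i] <- 1 + (r - 1) * (u[i] - bp[1]) / (bp[2] - bp[1])
  out[u >= bp[2] & u < bp[3]] <- r
  i <- u >= bp[3] & u < bp[4]
  out[i] <- r + (1 - r) * (u[i] - bp[3]) / (bp[4] - bp[3])
  out[u >= bp[4]] <- 1
  out
}

#' Chronomodulate a model parameter
#'
#' Applies the circadian waveform to a positive base quantity:
#' `base * f_w(t - t_chr)`.  Used for clearance and absorption constants.
#'
#' @param base Positive scalar (or vector) in any unit.
#' @param t Time in hours.
#' @param profile A [circadian_profile()].
#' @return `base * f_w(t - t_chr)`, same units as `base`.
#' @examples
#' modulate(5.41, 17.7, circadian_profile(0.29, t_chr = 0.7)) # nocturnal plateau
#' @export
modulate <- function(base, t, profile) {
  if (any(base <= 0)) stop("`base` must be positive")
  base * waveform(t - profile$t_chr, profile)
}

#' Analytic mean of the waveform over one 24-h period
#'
#' Piecewise-linear average of `f_w`; used in diagnostics and tests.
#' @param profile A [circadian_profile()].
#' @return Scalar mean of the waveform over a period.
#' @export
waveform_mean <- function(profile) {
  bp <- profile$breakpoints
  r <- profile$r_chr
  (bp[1] +
     (bp[2] - bp[1]) * (1 + r) / 2 +
     (bp[3] - bp[2]) * r +
     (bp[4] - bp[3]) * (1 + r) / 2 +
     (24 - bp[4])) / 24
}

# compiled waveform (with phase) -- used to cross-check C against R
fw_compiled <- function(t, profile) {
  n <- length(t)
  .C("chronotac_fw_eval",
     as.double(t), as.double(profile$t_chr), as.double(profile$r_chr),
     as.double(profile$breakpoints), out = double(n), as.integer(n),
     PACKAGE = "chronotac")$out
}
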