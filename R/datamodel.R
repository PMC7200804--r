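# Core data types and the NONMEM-style event-table reader/writer.
#
# Unit conventions used throughout the package:
#   time            hours since the dataset reference (t = 0 is a morning
#                   reference; the first hospital admission sits at 48 h)
#   dose amounts    mg
#   volumes         L
#   concentrations  ng/ml whole blood (1 mg/L = 1000 ng/ml)
#   LibT            minutes (converted at the model boundary)

FORMULATIONS <- c("fast_release", "prolonged_release")

#' Body surface area by the Du Bois formula
#'
#' `BSA = 0.007184 * BW^0.425 * H^0.725` with body weight in kg and height
#' in cm.
#'
#' @param body_weight Body weight, kg (> 0).
#' @param height Height, cm (> 0).
#' @return Body surface area in m^2.
#' @examples
#' compute_bsa(42.85, 143.4) # ~1.30 m^2
#' @export
compute_bsa <- function(body_weight, height) {
  if (any(body_weight <= 0) || any(height <= 0))
    stop("body_weight and height must be positive")
  0.007184 * body_weight^0.425 * height^0.725
}

#' Construct a subject record
#'
#' A subject bundles covariates with the dosing history and the observed
#' whole-blood concentrations.  Doses and observations are sorted by time;
#' BSA is derived from weight and height (Du Bois).
#'
#' @param id Subject label.
#' @param sex `"M"` or `"F"`.
#' @param age Age in years.
#' @param body_weight Body weight, kg.
#' @param height Height, cm.
#' @param haematocrit Haematocrit as a fraction.
#' @param doses `data.frame(time, amt, formulation)`: hours, mg, and one of
#'   `"fast_release"` / `"prolonged_release"`.
#' @param observations `data.frame(time, conc, blq)`: hours, ng/ml, and a
#'   below-limit-of-quantification flag.  Flagged rows are excluded from
#'   all objective functions.
#' @return An object of class `tac_subject`.
#' @export
subject <- function(id, sex, age, body_weight, height, haematocrit,
                    doses = NULL, observations = NULL) {
  stopifnot(sex %in% c("M", "F"), age > 0, haematocrit > 0, haematocrit < 1)
  if (is.null(doses))
    doses <- data.frame(time = numeric(), amt = numeric(),
                        formulation = character())
  if (is.null(observations))
    observations <- data.frame(time = numeric(), conc = numeric(),
                               blq = logical())
  if (nrow(doses)) {
    if (any(doses$time < 0)) stop("dose times must be >= 0")
    if (any(doses$amt <= 0)) stop("dose amounts must be positive")
    if (!all(doses$formulation %in% FORMULATIONS))
      stop("unknown formulation; use one of: ",
           paste(FORMULATIONS, collapse = ", "))
    doses <- doses[order(doses$time), , drop = FALSE]
  }
  if (nrow(observations)) {
    if (is.null(observations$blq)) observations$blq <- FALSE
    if (any(observations$conc <= 0 & !observations$blq, na.rm = TRUE))
      stop("non-BLQ observations must have positive concentration")
    observations <- observations[order(observations$time), , drop = FALSE]
  }
  rownames(doses) <- rownames(observations) <- NULL
  structure(
    list(id = as.character(id), sex = sex, age = age,
         body_weight = body_weight, height = height,
         haematocrit = haematocrit,
         bsa = compute_bsa(body_weight, height),
         doses = doses, observations = observations),
    class = "tac_subject"
  )
}

#' Construct a cohort
#'
#' @param subjects List of [subject()] records with unique ids.
#' @param reference_clock_offset Clock time (h) corresponding to model
#'   time 0; default 8.5 places the morning dose at 08:30.
#' @return An object of class `tac_cohort`.
#' @export
cohort <- function(subjects, reference_clock_offset = 8.5) {
  if (!length(subjects)) stop("a cohort needs at least one subject")
  if (!all(vapply(subjects, inherits, logical(1), "tac_subject")))
    stop("all elements must be tac_subject records")
  ids <- vapply(subjects, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  names(subjects) <- ids
  structure(list(subjects = subjects,
                 reference_clock_offset = reference_clock_offset),
            class = "tac_cohort")
}

#' @export
print.tac_subject <- function(x, ...) {
  cat(sprintf("subject %s: %s, %.1f y, %.1f kg, %.0f cm, Hct %.2f, BSA %.2f m^2\n",
              x$id, x$sex, x$age, x$body_weight, x$height, x$haematocrit, x$bsa))
  cat(sprintf("  %d doses, %d observations (%d BLQ)\n",
              nrow(x$doses), nrow(x$observations), sum(x$observations$blq)))
  invisible(x)
}

#' @export
print.tac_cohort <- function(x, ...) {
  nobs <- sum(vapply(x$subjects, function(s) nrow(s$observations), integer(1)))
  cat(sprintf("tacrolimus cohort: %d subjects, %d observations\n",
              length(x$subjects), nobs))
  invisible(x)
}

#' @export
length.tac_cohort <- function(x) length(x$subjects)

#' Keep only observations inside a time window
#'
#' Utility used to restrict fitting or adaptation to, e.g., the day-1 or
#' day-8 monitoring windows.  Doses are kept untouched (the full dosing
#' history is always needed to simulate).
#'
#' @param x A `tac_cohort` or `tac_subject`.
#' @param from,to Window bounds in hours (inclusive).
#' @return Object of the same class with observations restricted.
#' @export
observation_window <- function(x, from = -Inf, to = Inf) {
  if (inherits(x, "tac_cohort")) {
    x$subjects <- lapply(x$subjects, observation_window, from = from, to = to)
    return(x)
  }
  o <- x$observations
  x$observations <- o[o$time >= from & o$time <= to, , drop = FALSE]
  rownames(x$observations) <- NULL
  x
}

#' Usable observations of a subject
#'
#' Observations that enter objective functions: positive concentration
#' and not flagged below the quantification limit.
#'
#' @param subj A [subject()].
#' @return The subject's observation data frame, restricted.
#' @export
usable_obs <- function(subj) {
  o <- subj$observations
  o[!o$blq & o$conc > 0, , drop = FALSE]
}

#' Read a NONMEM-style event table
#'
#' Parses a delimited text file with header columns `ID, TIME, DV, AMT,
#' EVID, FORM, SEX, AGE, BW, HT, HCT` into a [cohort()].  Dose records are
#' rows with `EVID = 1` (amount in `AMT`, formulation in `FORM` as
#' `fast_release`/`prolonged_release` or 0/1); observation records have
#' `EVID = 0` with the whole-blood concentration in `DV` (ng/ml).  Missing
#' cells are `"."`.  Observations at or below `lloq` are flagged BLQ and
#' excluded from all likelihoods downstream.
#'
#' @param path File path.
#' @param sep Field separator (default `","`).
#' @param lloq Lower limit of quantification, ng/ml (default 2).
#' @param reference_clock_offset Passed to [cohort()].
#' @return A `tac_cohort`.
#' @export
read_event_table <- function(path, sep = ",", lloq = 2,
                             reference_clock_offset = 8.5) {
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  strip.white = TRUE)
  need <- c("ID", "TIME", "DV", "AMT", "EVID", "FORM",
            "SEX", "AGE", "BW", "HT", "HCT")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
  raw$TIME <- num(raw$TIME); raw$DV <- num(raw$DV); raw$AMT <- num(raw$AMT)
  raw$EVID <- num(raw$EVID); raw$AGE <- num(raw$AGE); raw$BW <- num(raw$BW)
  raw$HT <- num(raw$HT); raw$HCT <- num(raw$HCT)
  if (any(raw$AMT < 0, na.rm = TRUE) || any(raw$DV < 0, na.rm = TRUE))
    stop("negative AMT or DV encountered")
  subs <- lapply(split(raw, factor(raw$ID, levels = unique(raw$ID))),
                 function(d) {
    if (is.unsorted(d$TIME, strictly = FALSE)) {
      bad <- which(diff(d$TIME) < 0)[1] + 1L
      stop("times not sorted within subject ", d$ID[1],
           " (row ", rownames(d)[bad], ")")
    }
    dose <- d[d$EVID == 1, , drop = FALSE]
    obs  <- d[d$EVID == 0, , drop = FALSE]
    form <- dose$FORM
    form[form %in% c("0")] <- "fast_release"
    form[form %in% c("1")] <- "prolonged_release"
    subject(
      id = d$ID[1], sex = d$SEX[1], age = d$AGE[1],
      body_weight = d$BW[1], height = d$HT[1], haematocrit = d$HCT[1],
      doses = data.frame(time = dose$TIME, amt = dose$AMT,
                         formulation = form),
      observations = data.frame(time = obs$TIME, conc = obs$DV,
                                blq = obs$DV <= lloq)
    )
  })
  cohort(unname(subs), reference_clock_offset = reference_clock_offset)
}

#' Write a cohort as a NONMEM-style event table
#'
#' Inverse of [read_event_table()]: the written file round-trips to an
#' identical cohort.
#'
#' @param x A `tac_cohort`.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "tac_cohort"))
  rows <- lapply(x$subjects, function(s) {
    d <- data.frame(ID = s$id, TIME = s$doses$time, DV = NA_real_,
                    AMT = s$doses$amt, EVID = 1,
                    FORM = s$doses$formulation)
    o <- data.frame(ID = s$id, TIME = s$observations$time,
                    DV = s$observations$conc, AMT = NA_real_, EVID = 0,
                    FORM = NA_character_)
    ev <- rbind(d, o)
    ev <- ev[order(ev$TIME, ev$EVID), c("ID", "TIME", "DV",
                                        "AMT", "EVID", "FORM")]
    ev$SEX <- s$sex; ev$AGE <- s$age; ev$BW <- s$body_weight
    ev$HT <- s$height; ev$HCT <- s$haematocrit
    ev
  })
  tab <- do.call(rbind, rows)
  fmt <- function(v) {
    out <- vapply(v, function(z) {
      if (is.na(z)) "." else format(z, digits = 15, scientific = FALSE)
    }, character(1))
    out
  }
  for (cn in c("TIME", "DV", "AMT", "EVID", "AGE", "BW", "HT", "HCT"))
    tab[[cn]] <- fmt(tab[[cn]])
  tab$FORM[is.na(tab$FORM)] <- "."
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
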