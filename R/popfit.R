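# Nonlinear mixed-effects population estimation.
#
# Inter-individual variability is exponential (theta_i = theta * e^eta,
# eta ~ N(0, Omega) with diagonal Omega); the residual model is additive
# on log-concentration (default) or proportional on the natural scale
# (with interaction, FOCE-I).  The marginal -2 log-likelihood is
# approximated by first-order conditional estimation: for each subject
# the empirical Bayes mode eta-hat is found by a damped Gauss-Newton
# search, the model is linearised around it, and the subject contributes
#   n log(2 pi) + log|V| + r' V^-1 r,
#   V = G Omega G' + Sigma,   r = y - f(eta-hat) + G eta-hat,
# which is exact for models linear in eta with Gaussian errors.

#' Define a population model
#'
#' Couples a structural model (the circadian PK/CAT3 or PBPK model, or a
#' user-supplied function) with population parameters: fixed effects
#' `theta`, diagonal random-effect variances `omega2` for the variable
#' parameters, a residual model, and covariate links.
#'
#' Variable (random-effect) parameters are `Cl, Ka, MTT, r_chr, t_chr`
#' for the PK model and `Clih, Bmax, Kd, r_chr, t_chr` for the PBPK
#' model.  An `omega2` entry of zero removes that random effect.
#' Variances listed in `omega_fixed` are kept at their initial value
#' during estimation (used for the circadian phase variance, whose
#' reported uncertainty suggests it was not estimated).
#'
#' @param structural `"pk"`, `"pbpk"`, or a list with elements
#'   `variable` (character), `predict` (`function(theta_i, subj)`
#'   returning the response mean at the subject's usable observations)
#'   and optionally `observed` (`function(subj)`; defaults to
#'   log-concentration).
#' @param theta Named fixed-effect vector; defaults to the shipped
#'   paediatric estimates of the chosen structural model.
#' @param omega2 Named vector of random-effect variances.
#' @param sigma2 Residual variance (log scale for `additive_log`).
#' @param residual `"additive_log"` or `"proportional"`.
#' @param links List of covariate links, see [covariate_link()].
#' @param omega_fixed Character vector of `omega2` entries not updated
#'   during estimation.
#' @param template Structural parameter object supplying the fixed,
#'   non-population constants ([pk_params()] / [pbpk_params()]).
#' @return Object of class `tac_popmodel`.
#' @export
population_model <- function(structural = c("pk", "pbpk"),
                             theta = NULL, omega2 = NULL, sigma2 = NULL,
                             residual = c("additive_log", "proportional"),
                             links = list(), omega_fixed = "t_chr",
                             template = NULL) {
  residual <- match.arg(residual)
  if (is.character(structural)) {
    structural <- match.arg(structural)
    defs <- switch(structural,
      pk = list(
        variable = c("Cl", "Ka", "MTT", "r_chr", "t_chr"),
        theta = c(Cl = 5.41, Cld = 46.5, Vc = 23.0, Vp = 39.1,
                  Ka = 13.8, MTT = 0.72, r_chr = 0.29, t_chr = 0.7),
        omega2 = c(Cl = 0.10, Ka = 0.33, MTT = 0.05, r_chr = 0.003,
                   t_chr = 0.01),
        sigma2 = 0.027,
        template = pk_params()),
      pbpk = list(
        variable = c("Clih", "Bmax", "Kd", "r_chr", "t_chr"),
        theta = c(Clih = 956.6, Bmax = 11.0, Kd = 1.6, r_chr = 0.16,
                  t_chr = 0.7),
        omega2 = c(Clih = 0.114, Bmax = 0.004, Kd = 0.083, r_chr = 0.367,
                   t_chr = 0.01),
        sigma2 = 0.037,
        template = pbpk_params()))
    name <- structural
    variable <- defs$variable
    if (is.null(theta)) theta <- defs$theta
    if (is.null(omega2)) omega2 <- defs$omega2
    if (is.null(sigma2)) sigma2 <- defs$sigma2
    if (is.null(template)) template <- defs$template
    predict_fn <- NULL
    observed_fn <- NULL
  } else {
    name <- "custom"
    variable <- structural$variable
    predict_fn <- structural$predict
    observed_fn <- structural$observed
    if (is.null(sigma2)) sigma2 <- 0.027
    if (is.null(omega2)) omega2 <- setNames(rep(0.1, length(variable)),
                                            variable)
  }
  stopifnot(!is.null(names(theta)), all(variable %in% names(c(theta))),
            all(omega2 >= 0), sigma2 > 0)
  structure(list(name = name, variable = variable, theta = theta,
                 omega2 = omega2[variable], sigma2 = sigma2,
                 residual = residual, links = links,
                 omega_fixed = intersect(omega_fixed, variable),
                 template = template,
                 predict_fn = predict_fn, observed_fn = observed_fn),
            class = "tac_popmodel")
}

#' Covariate link definition
#'
#' Multiplicative covariate effect on a population parameter.  Forms:
#' exponential `(x/ref)^coef`, linear `1 + coef (x - ref)` (must stay
#' positive), categorical `1 + coef` when the covariate equals `level`.
#'
#' @param param Parameter name the link acts on.
#' @param covariate One of `"bsa"`, `"bw"`, `"age"`, `"height"`,
#'   `"bmi"`, `"sex"`, `"hct"`.
#' @param form `"exponential"`, `"linear"` or `"categorical"`.
#' @param coef Link coefficient.
#' @param ref Reference covariate value (median of the population).
#' @param level Reference level for categorical links.
#' @return A `tac_link` list.
#' @export
covariate_link <- function(param, covariate, form = "exponential",
                           coef = 0, ref = 1, level = "F") {
  structure(list(param = param, covariate = covariate, form = form,
                 coef = coef, ref = ref, level = level),
            class = "tac_link")
}

covariate_value <- function(subj, name) {
  switch(name,
         bsa = subj$bsa, bw = subj$body_weight, age = subj$age,
         height = subj$height, hct = subj$haematocrit,
         bmi = subj$body_weight / (subj$height / 100)^2,
         sex = subj$sex,
         stop("unknown covariate: ", name))
}

link_multiplier <- function(link, subj) {
  x <- covariate_value(subj, link$covariate)
  m <- switch(link$form,
    exponential = (x / link$ref)^link$coef,
    linear = 1 + link$coef * (x - link$ref),
    categorical = if (identical(x, link$level)) 1 + link$coef else 1,
    stop("unknown link form: ", link$form))
  if (m <= 0)
    stop("covariate link on ", link$param, " yields a non-positive multiplier")
  m
}

#' Individual structural parameters
#'
#' Applies exponential inter-individual variability and covariate
#' multipliers to the population means: `theta_i = theta * e^eta *
#' prod(link multipliers)`.
#'
#' @param pop A [population_model()].
#' @param eta Named (or positionally matched) random-effect vector over
#'   `pop$variable`.
#' @param subj A [subject()] supplying covariates.
#' @return For the built-in structural models, a [pk_params()] /
#'   [pbpk_params()] object; for custom models, the named `theta_i`
#'   vector.
#' @export
individual_params <- function(pop, eta, subj) {
  th <- pop$theta
  ev <- setNames(numeric(length(pop$variable)), pop$variable)
  if (!is.null(names(eta))) ev[names(eta)] <- eta else
    ev[seq_along(eta)] <- eta
  th[pop$variable] <- th[pop$variable] * exp(ev)
  for (lk in pop$links)
    th[lk$param] <- th[lk$param] * link_multiplier(lk, subj)
  if (pop$name == "custom") return(th)
  theta_to_params(pop, th)
}

# map a named theta vector onto the structural template (hot path: the
# template was validated at construction and theta * e^eta stays
# positive, so fields are set directly)
theta_to_params <- function(pop, th) {
  p <- pop$template
  nm <- names(th)
  if ("r_chr" %in% nm) {
    p$circadian$r_chr <- min(unname(th[["r_chr"]]), 1)
    p$circadian$t_chr <- unname(th[["t_chr"]])
  }
  for (field in setdiff(nm, c("r_chr", "t_chr")))
    p[[field]] <- unname(th[[field]])
  p
}

# Per-subject context for the estimation loops: observation vector,
# dose windows, solver time grid and the matching output rows are fixed
# across eta and theta proposals (FDT / LibT are not population
# parameters), so they are computed once.
make_ctx <- function(pop, subj) {
  o <- usable_obs(subj)
  if (!nrow(o)) stop("subject ", subj$id, " has no usable observations")
  y <- if (pop$residual == "additive_log") log(o$conc) else o$conc
  if (!is.null(pop$predict_fn))
    return(list(subj = subj, y = y, custom = TRUE))
  tend <- max(o$time)
  doses <- subj$doses[subj$doses$time < tend, , drop = FALSE]
  windows <- build_windows(doses, list(list(time = -Inf,
                                            params = pop$template)))
  edges <- unique(c(windows$start, windows$start + windows$dur))
  edges <- edges[edges > 0 & edges < tend]
  tseq <- sort(unique(c(0, o$time, edges)))
  spec <- if (pop$name == "pk")
    list(func = "chronotac_pk_derivs", init = "chronotac_pk_init",
         np_head = 12L, np = PK_NP, conc_col = 6L)
  else
    list(func = "chronotac_pbpk_derivs", init = "chronotac_pbpk_init",
         np_head = 29L, np = PBPK_NP, conc_col = 7L)
  phys <- if (pop$name == "pbpk") scale_physiology(subj) else NULL
  R <- if (pop$name == "pbpk") pbpk_partitions(pop$template) else NULL
  list(subj = subj, y = y, tseq = tseq,
       idx = match(round(o$time, 9), round(tseq, 9)),
       blk = dose_block(windows, spec$np_head, spec$np),
       spec = spec, phys = phys, R = R, custom = FALSE,
       ny = if (pop$name == "pk") 10L else 11L)
}

# fast prediction on the residual-model scale given a context
predict_ctx <- function(pop, ctx, eta, rtol = 1e-6) {
  if (ctx$custom) {
    th <- individual_params(pop, eta, ctx$subj)
    return(pop$predict_fn(th, ctx$subj))
  }
  params <- individual_params(pop, eta, ctx$subj)
  head <- if (pop$name == "pk") pk_parms_head(params)
    else {
      h <- pbpk_parms_head(params, ctx$phys, ctx$R)
      h[2] <- k_elib(unname(params$LibT[["fast_release"]]),
                     params$K_elib_ref)
      h
    }
  sol <- deSolve::lsoda(y = numeric(ctx$ny), times = ctx$tseq,
                        func = ctx$spec$func, parms = c(head, ctx$blk),
                        dllname = "chronotac", initfunc = ctx$spec$init,
                        rtol = rtol, atol = rtol * 1e-2, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed during estimation for subject ", ctx$subj$id)
  conc <- 1000 * sol[ctx$idx, 1L + ctx$spec$conc_col] /
    (if (pop$name == "pk") params$Vc else ctx$phys$volumes[["blood"]])
  conc <- pmax(conc, 1e-8)
  if (pop$residual == "additive_log") log(conc) else conc
}

# response (observed) vector of a subject on the residual-model scale
pop_observed <- function(pop, subj) {
  if (!is.null(pop$observed_fn)) return(pop$observed_fn(subj))
  o <- usable_obs(subj)
  if (pop$residual == "additive_log") log(o$conc) else o$conc
}

# model prediction on the residual-model scale for random effects eta
pop_predict <- function(pop, subj, eta, rtol = 1e-6) {
  if (!is.null(pop$predict_fn)) {
    th <- individual_params(pop, eta, subj)
    return(pop$predict_fn(th, subj))
  }
  params <- individual_params(pop, eta, subj)
  o <- usable_obs(subj)
  tms <- sort(unique(c(0, o$time)))
  sim <- if (pop$name == "pk")
    simulate_pk(subj, params, tms, rtol = rtol, atol = rtol * 1e-2,
                restart = FALSE)
  else
    simulate_pbpk(subj, params, tms, rtol = rtol, atol = rtol * 1e-2,
                  restart = FALSE)
  cc <- sim$conc[match(round(o$time, 9), round(sim$time, 9))]
  cc <- pmax(cc, 1e-8)
  if (pop$residual == "additive_log") log(cc) else cc
}

# forward-difference Jacobian of the context prediction wrt the active
# etas
ctx_jacobian <- function(pop, ctx, eta, f0, active, h = 1e-4) {
  G <- matrix(0, nrow = length(f0), ncol = length(eta))
  for (j in which(active)) {
    ej <- eta; ej[j] <- ej[j] + h
    G[, j] <- (predict_ctx(pop, ctx, ej) - f0) / h
  }
  G
}

# inner EBE search: damped Gauss-Newton on
#   g(eta) = (y - f)' W (y - f) + eta' Oinv eta
inner_map <- function(pop, ctx, eta0, max_iter = 10, tol = 1e-5) {
  y <- ctx$y
  active <- pop$omega2 > 0
  eta <- eta0
  eta[!active] <- 0
  oinv <- ifelse(active, 1 / pop$omega2, 0)
  s2 <- pop$sigma2
  f <- predict_ctx(pop, ctx, eta)
  wts <- function(f) if (pop$residual == "additive_log")
    rep(1 / s2, length(f)) else 1 / (s2 * pmax(f, 1e-8)^2)
  gval <- function(f, eta) sum(wts(f) * (y - f)^2) + sum(oinv * eta^2)
  g <- gval(f, eta)
  G <- NULL
  converged <- !any(active)
  if (converged)
    return(list(eta = eta, f = f,
                G = matrix(0, length(f), length(eta)), converged = TRUE))
  # The model Jacobian wrt eta changes slowly along the inner path, so
  # it is refreshed only on the first iteration, after large steps, or
  # when a stale-gradient step fails to descend.
  fresh <- FALSE
  for (it in seq_len(max_iter)) {
    if (!fresh || is.null(G)) {
      G <- ctx_jacobian(pop, ctx, eta, f, active)
      fresh <- TRUE
    }
    w <- wts(f)
    A <- crossprod(G, G * w) + diag(oinv, length(eta))
    b <- crossprod(G, w * (y - f)) - oinv * eta
    d <- tryCatch(drop(solve(A, b)), error = function(e) NULL)
    if (is.null(d)) break
    step <- 1
    improved <- FALSE
    repeat {
      eta_new <- eta + step * d
      f_new <- predict_ctx(pop, ctx, eta_new)
      g_new <- gval(f_new, eta_new)
      if (g_new <= g + 1e-12) { improved <- TRUE; break }
      if (step < 1 / 16) break
      step <- step / 2
    }
    if (improved) {
      eta <- eta_new; f <- f_new; g <- g_new
      moved <- sqrt(sum((step * d)^2))
      if (moved < tol) { converged <- TRUE; break }
      if (moved > 0.2) fresh <- FALSE
    } else {
      if (!fresh) { fresh <- FALSE; G <- NULL; next }  # retry refreshed
      converged <- TRUE  # no downhill step from a fresh gradient
      break
    }
  }
  if (is.null(G)) G <- ctx_jacobian(pop, ctx, eta, f, active)
  list(eta = eta, f = f, G = G, converged = converged)
}

#' FOCE objective function
#'
#' Computes the first-order conditional estimate of -2 log-likelihood
#' (the MVOF) for a population model on a cohort, together with the
#' per-subject empirical Bayes estimates of the random effects.  For the
#' proportional residual model the residual variance is recomputed at
#' the conditional estimates (FOCE with interaction).
#'
#' @param pop A [population_model()].
#' @param coh A [cohort()]; every subject needs at least one usable
#'   (non-BLQ) observation.
#' @param eta_init Optional matrix of starting random effects (subjects
#'   in rows) for warm starts.
#' @return `list(mvof, eta, converged, subject_ll)`; non-converged inner
#'   optimisations are flagged in `converged` and make the objective
#'   unreliable.
#' @export
foce_objective <- function(pop, coh, eta_init = NULL, ctxs = NULL) {
  subs <- coh$subjects
  if (is.null(ctxs)) ctxs <- lapply(subs, make_ctx, pop = pop)
  nv <- length(pop$variable)
  eta_mat <- matrix(0, nrow = length(subs), ncol = nv,
                    dimnames = list(names(subs), pop$variable))
  if (!is.null(eta_init)) eta_mat[] <- eta_init
  ll <- numeric(length(subs))
  conv <- logical(length(subs))
  omega <- pop$omega2
  for (i in seq_along(subs)) {
    y <- ctxs[[i]]$y
    fit <- inner_map(pop, ctxs[[i]], eta_mat[i, ])
    eta_mat[i, ] <- fit$eta
    conv[i] <- fit$converged
    G <- fit$G
    s2 <- pop$sigma2
    Sig <- if (pop$residual == "additive_log")
      diag(s2, length(y)) else diag(s2 * pmax(fit$f, 1e-8)^2, length(y))
    V <- G %*% (omega * t(G)) + Sig
    r <- y - fit$f + drop(G %*% fit$eta)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) { ll[i] <- 1e10; conv[i] <- FALSE; next }
    z <- backsolve(ch, r, transpose = TRUE)
    ll[i] <- length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2)
  }
  list(mvof = sum(ll), eta = eta_mat, converged = conv, subject_ll = ll)
}

#' Fit a population model by FOCE
#'
#' Minimises the FOCE objective over the chosen components.  Fixed
#' effects and variances are log-transformed to enforce positivity;
#' covariate-link coefficients are estimated on their natural scale.
#' Relative standard errors come from the numerical Hessian of the
#' objective at the optimum (`RSE(theta) = SE(theta)/theta * 100`;
#' `SE(omega2)/(2 omega2) * 100` for variances); a non-positive-definite
#' Hessian leaves them `NA`.
#'
#' @param pop Initial [population_model()].
#' @param coh Fitting cohort (restrict observations with
#'   [observation_window()] first if needed).
#' @param estimate Components to estimate: subset of
#'   `c("theta", "omega", "sigma")`.
#' @param estimate_theta Names of `theta` entries to estimate; defaults
#'   to all.
#' @param estimate_links Logical: estimate link coefficients.
#' @param control Passed to [stats::optim()] (Nelder-Mead); defaults to
#'   `maxit = 400`, `reltol = 1e-7`.
#' @param hessian Compute RSEs from the numerical Hessian.
#' @return Object of class `tac_fit`: updated population model, MVOF,
#'   estimates with RSEs, empirical Bayes `eta`, and shrinkage
#'   diagnostics.
#' @export
fit_population <- function(pop, coh, estimate = c("theta", "omega", "sigma"),
                           estimate_theta = NULL, estimate_links = FALSE,
                           control = list(), hessian = TRUE) {
  est_theta <- if ("theta" %in% estimate) {
    if (is.null(estimate_theta)) names(pop$theta) else estimate_theta
  } else character(0)
  est_omega <- if ("omega" %in% estimate)
    setdiff(names(pop$omega2)[pop$omega2 > 0], pop$omega_fixed) else
      character(0)
  est_sigma <- "sigma" %in% estimate
  nlink <- if (estimate_links) length(pop$links) else 0L
  x0 <- c(log(pop$theta[est_theta]),
          if (length(est_omega)) log(pop$omega2[est_omega]),
          if (est_sigma) log(pop$sigma2),
          if (nlink) vapply(pop$links, `[[`, numeric(1), "coef"))
  n_th <- length(est_theta); n_om <- length(est_omega)
  state <- new.env(parent = emptyenv())
  state$eta <- NULL
  ctxs <- lapply(coh$subjects, make_ctx, pop = pop)
  build <- function(x) {
    p <- pop
    if (n_th) p$theta[est_theta] <- exp(x[seq_len(n_th)])
    if (n_om) p$omega2[est_omega] <- exp(x[n_th + seq_len(n_om)])
    if (est_sigma) p$sigma2 <- exp(x[n_th + n_om + 1])
    if (nlink)
      for (j in seq_len(nlink))
        p$links[[j]]$coef <- x[n_th + n_om + est_sigma + j]
    p
  }
  obj <- function(x) {
    p <- build(x)
    res <- tryCatch(foce_objective(p, coh, eta_init = state$eta,
                                   ctxs = ctxs),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$mvof)) return(1e10)
    state$eta <- res$eta
    res$mvof
  }
  ctrl <- modifyList(list(maxit = 400, reltol = 1e-7), control)
  opt <- if (length(x0) > 1) {
    optim(x0, obj, method = "Nelder-Mead", control = ctrl)
  } else if (length(x0) == 1) {
    # Nelder-Mead is unreliable in one dimension; bracket on the
    # transformed scale instead
    optim(x0, obj, method = "Brent", lower = x0 - 4, upper = x0 + 4,
          control = list(maxit = ctrl$maxit))
  } else list(par = x0, value = obj(x0), convergence = 0)
  pop_hat <- build(opt$par)
  final <- foce_objective(pop_hat, coh, eta_init = state$eta, ctxs = ctxs)
  rse <- rep(NA_real_, length(opt$par))
  if (hessian && length(opt$par) > 0) {
    # freeze the inner warm starts at the optimum so the finite
    # differences see a smooth objective
    eta_hat <- final$eta
    obj_h <- function(x) {
      p <- build(x)
      res <- tryCatch(foce_objective(p, coh, eta_init = eta_hat,
                                     ctxs = ctxs),
                      error = function(e) NULL)
      if (is.null(res) || !is.finite(res$mvof)) return(1e10)
      res$mvof
    }
    H <- tryCatch(optimHess(opt$par, obj_h), error = function(e) NULL)
    if (!is.null(H)) {
      cov <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(cov) && all(diag(cov) > 0))
        rse <- sqrt(diag(cov)) * 100  # log-scale SE -> RSE% (delta method)
    }
  }
  names(rse) <- names(x0)
  rse_theta <- setNames(rep(NA_real_, length(pop$theta)), names(pop$theta))
  rse_theta[est_theta] <- rse[seq_len(n_th)]
  rse_omega <- setNames(rep(NA_real_, length(pop$omega2)), names(pop$omega2))
  if (n_om) rse_omega[est_omega] <- rse[n_th + seq_len(n_om)] / 2
  fit <- structure(
    list(pop = pop_hat, theta = pop_hat$theta, omega2 = pop_hat$omega2,
         sigma2 = pop_hat$sigma2,
         rse_theta = rse_theta, rse_omega2 = rse_omega,
         rse_sigma2 = if (est_sigma) unname(rse[n_th + n_om + 1] / 2)
           else NA_real_,
         mvof = final$mvof, eta = final$eta,
         inner_converged = final$converged,
         convergence = opt$convergence, cohort = coh),
    class = "tac_fit")
  fit$shrinkage <- shrinkage(fit)
  fit
}

#' @export
print.tac_fit <- function(x, ...) {
  cat("population", x$pop$name, "model fit (FOCE)\n")
  cat(sprintf("MVOF = %.2f\n", x$mvof))
  tab <- data.frame(
    parameter = names(x$theta),
    value = signif(unname(x$theta), 4),
    `RSE%` = round(unname(x$rse_theta), 1), check.names = FALSE)
  print(tab, row.names = FALSE)
  cat("interindividual variances:\n")
  tab2 <- data.frame(
    parameter = names(x$omega2), omega2 = signif(unname(x$omega2), 3),
    `RSE%` = round(unname(x$rse_omega2), 1), check.names = FALSE)
  print(tab2, row.names = FALSE)
  cat(sprintf("residual variance %.4g; eps-shrinkage %.3f\n",
              x$sigma2, x$shrinkage$eps))
  invisible(x)
}

#' Shrinkage diagnostics
#'
#' Eta-shrinkage per parameter, `1 - sd(eta-hat)/omega`, and
#' epsilon-shrinkage, `1 - sd(IWRES)` with individual weighted residuals
#' standardised by the residual model at the conditional estimates.
#' Parameters with `omega2 = 0` are reported `NA`.
#'
#' @param fit A `tac_fit` from [fit_population()].
#' @return `list(eta, eps, eps_by_subject)`.
#' @export
shrinkage <- function(fit) {
  pop <- fit$pop
  om <- sqrt(pop$omega2)
  eta_shr <- ifelse(om > 0, 1 - apply(fit$eta, 2, sd) / om, NA_real_)
  names(eta_shr) <- colnames(fit$eta)
  iw_all <- numeric(0)
  iw_sub <- numeric(length(fit$cohort$subjects))
  for (i in seq_along(fit$cohort$subjects)) {
    subj <- fit$cohort$subjects[[i]]
    y <- pop_observed(pop, subj)
    f <- pop_predict(pop, subj, fit$eta[i, ])
    iw <- if (pop$residual == "additive_log")
      (y - f) / sqrt(pop$sigma2) else (y - f) / (sqrt(pop$sigma2) * f)
    iw_all <- c(iw_all, iw)
    iw_sub[i] <- 1 - sd(iw)
  }
  list(eta = eta_shr, eps = 1 - sd(iw_all), eps_by_subject = iw_sub)
}

#' Forward stepwise covariate selection
#'
#' Evaluates each candidate link by refitting the model with its
#' coefficient free and comparing the objective drop and the reduction
#' in the linked parameter's inter-individual CV.  A candidate is
#' accepted when `dMVOF >= threshold`, or when `dMVOF >= near_fraction *
#' threshold` and the CV reduction reaches `cv_reduction` (minimum
#' clinical relevance).  Accepted links are added greedily (best first)
#' and the remaining candidates re-evaluated.
#'
#' @param pop Base [population_model()].
#' @param coh Fitting cohort.
#' @param candidates List of [covariate_link()] candidates (their `coef`
#'   is the starting value).
#' @param threshold Objective-drop acceptance threshold (3.84: chi^2, 1
#'   df, 5%).
#' @param near_fraction Fraction of `threshold` admissible when the CV
#'   criterion also holds.
#' @param cv_reduction Required relative CV reduction of the linked
#'   parameter.
#' @param ... Passed to [fit_population()].
#' @return `list(pop, accepted, table)` where `table` records per
#'   candidate the objective drop and CV reduction.
#' @export
covariate_stepwise <- function(pop, coh, candidates, threshold = 3.84,
                               near_fraction = 0.75, cv_reduction = 0.10,
                               ...) {
  if (!length(candidates))
    return(list(pop = pop, accepted = list(),
                table = data.frame()))
  base <- fit_population(pop, coh, hessian = FALSE, ...)
  accepted <- list()
  rows <- list()
  remaining <- candidates
  repeat {
    res <- lapply(remaining, function(lk) {
      p2 <- base$pop
      p2$links <- c(p2$links, list(lk))
      f2 <- tryCatch(
        fit_population(p2, coh, estimate_links = TRUE, hessian = FALSE, ...),
        error = function(e) NULL)
      if (is.null(f2)) return(NULL)
      dmv <- base$mvof - f2$mvof
      cv0 <- sqrt(base$omega2[lk$param])
      cv1 <- sqrt(f2$omega2[lk$param])
      cvr <- if (is.na(cv0) || cv0 == 0) 0 else 1 - cv1 / cv0
      list(fit = f2, dmvof = dmv, cv_red = cvr,
           coef = f2$pop$links[[length(f2$pop$links)]]$coef, link = lk)
    })
    keep <- !vapply(res, is.null, logical(1))
    res <- res[keep]; remaining <- remaining[keep]
    if (!length(res)) break
    for (r in res)
      rows[[length(rows) + 1L]] <- data.frame(
        param = r$link$param, covariate = r$link$covariate,
        form = r$link$form, coef = r$coef, dmvof = r$dmvof,
        cv_reduction = r$cv_red)
    ok <- vapply(res, function(r)
      r$dmvof >= threshold ||
        (r$dmvof >= near_fraction * threshold &&
           r$cv_red >= cv_reduction), logical(1))
    if (!any(ok)) break
    best <- which.max(vapply(res, `[[`, numeric(1), "dmvof") + ifelse(ok, 0, -Inf))
    accepted <- c(accepted, list(res[[best]]$link))
    base <- res[[best]]$fit
    remaining <- remaining[-best]
    if (!length(remaining)) break
  }
  list(pop = base$pop, accepted = accepted,
       table = if (length(rows)) do.call(rbind, rows) else data.frame())
}
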