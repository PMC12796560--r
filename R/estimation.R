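#' Fitting settings
#'
#' @param model structural model: \code{"three_cpt"} (7 structural
#'   parameters) or \code{"two_cpt"} (V1, V2, Cl, Cl2, Rss).
#' @param max_iter maximum EM iterations.
#' @param rel_tol relative convergence tolerance on the typical values.
#' @param omega_structure \code{"full"} (all covariances estimated) or
#'   \code{"diag"}.
#' @param omega_init initial random-effect variance placed on the
#'   diagonal of Omega.
#' @param polish optionally refine the typical values after EM by direct
#'   maximization of the Laplace marginal log-likelihood (off by
#'   default: on rich designs the EM fixed point lies on the Laplace-ML
#'   optimum and the refinement only adds runtime).
#' @param polish_iter optimizer iteration cap for the polish step.
#' @param verbose print the objective per iteration.
#' @return a list of settings for \code{\link{fit_population}}.
#' @export
fit_settings <- function(model = c("three_cpt", "two_cpt"), max_iter = 25L,
                         rel_tol = 1e-3, omega_structure = c("full", "diag"),
                         omega_init = 0.1, polish = FALSE, polish_iter = 250L,
                         verbose = FALSE) {
  list(model = match.arg(model), max_iter = as.integer(max_iter),
       rel_tol = rel_tol, omega_structure = match.arg(omega_structure),
       omega_init = omega_init, polish = polish,
       polish_iter = as.integer(polish_iter), verbose = verbose)
}

.model_pars <- function(model) {
  if (model == "three_cpt") .PARAM_NAMES else c("V1", "V2", "Cl", "Cl2", "Rss")
}

# complete a (possibly reduced) named parameter vector to disposition_params
.as_disposition <- function(v, model) {
  if (model == "two_cpt") v <- c(v, Cl3 = 0, V3 = 1)
  do.call(disposition_params, as.list(v[.PARAM_NAMES]))
}

# split a dataset into per-horse fitting structures.
# Drops below-LOQ observations and urine rows earlier than 24 h after the
# first dose (pre-equilibrium), per the analysis rules.  Precomputes the
# observation-by-dose time-offset matrix used by the fast predictor.
.prep_horses <- function(data) {
  out <- list()
  for (id in unique(data$ID)) {
    d <- data[data$ID == id, ]
    dt <- d[d$EVID == 1, ]
    if (!nrow(dt)) stop("horse ", id, " has no dose row", call. = FALSE)
    times <- sort(dt$TIME)
    reg <- structure(list(dose = dt$AMT[1L], times = times,
                          interval = if (length(times) > 1L) diff(times)[1L] else 24),
                     class = "dosing_regimen")
    obs <- d[d$EVID == 0 & !is.na(d$DV), ]
    if (!is.null(obs$BLOQ)) obs <- obs[!(obs$BLOQ %in% TRUE), ]
    obs <- obs[!(obs$MATRIX == "urine" & obs$TIME < times[1L] + 24), ]
    cov_cols <- intersect(.COVARIATE_COLS, names(d))
    h <- .make_horse(id, reg, obs$TIME, obs$DV, obs$MATRIX)
    h$covariates <- if (length(cov_cols)) d[1L, cov_cols, drop = FALSE] else NULL
    h$arm <- if (!is.null(d$ARM)) d$ARM[1L] else NA_character_
    out[[as.character(id)]] <- h
  }
  out
}

# fitting structure for one horse, with the precomputed dose-offset matrix
.make_horse <- function(id, regimen, time, dv, matrix) {
  trel <- outer(time, regimen$times, `-`)
  trel[trel < 0] <- NA              # doses after the observation contribute 0
  list(id = id, regimen = regimen, time = time, dv = dv, matrix = matrix,
       trel = trel, urine = matrix == "urine")
}

# lean macro-constant computation on a named parameter vector (no S3
# validation; the optimizer guards against non-finite output instead).
# Returns NULL on degenerate input.
.macro_fast <- function(v, model, dose) {
  V1 <- v[[1L]]
  if (model == "two_cpt") {
    # order: V1 V2 Cl Cl2 Rss
    k10 <- v[[3L]] / V1; kp <- v[[4L]] / V1; km <- v[[4L]] / v[[2L]]
    s <- k10 + kp + km
    disc <- s^2 - 4 * k10 * km
    if (disc <= 0) return(NULL)
    dq <- sqrt(disc)
    lam <- c((s + dq) / 2, (s - dq) / 2)
    co <- dose / V1 * c(lam[1L] - km, km - lam[2L]) / (lam[1L] - lam[2L])
  } else {
    # order: V1 V2 V3 Cl Cl2 Cl3 Rss
    k10 <- v[[4L]] / V1; k12 <- v[[5L]] / V1; k21 <- v[[5L]] / v[[2L]]
    k13 <- v[[6L]] / V1; k31 <- v[[6L]] / v[[3L]]
    E1 <- k10 + k12 + k13
    b2 <- E1 + k21 + k31
    b1 <- E1 * k21 + E1 * k31 + k21 * k31 - k12 * k21 - k13 * k31
    b0 <- E1 * k21 * k31 - k12 * k21 * k31 - k13 * k31 * k21
    rt <- polyroot(c(-b0, b1, -b2, 1))
    if (max(abs(Im(rt))) > 1e-7 * max(abs(Re(rt)))) return(NULL)
    lam <- sort(Re(rt), decreasing = TRUE)
    if (lam[3L] <= 0) return(NULL)
    co <- dose / V1 * c(
      (k21 - lam[1L]) * (k31 - lam[1L]) / ((lam[2L] - lam[1L]) * (lam[3L] - lam[1L])),
      (k21 - lam[2L]) * (k31 - lam[2L]) / ((lam[1L] - lam[2L]) * (lam[3L] - lam[2L])),
      (k21 - lam[3L]) * (k31 - lam[3L]) / ((lam[1L] - lam[3L]) * (lam[2L] - lam[3L])))
  }
  list(lambda = lam, coef = co)
}

# individual predictions at given eta for one horse (hot path)
.pred_horse <- function(horse, theta, eta, model) {
  v <- theta * exp(eta)
  mm <- .macro_fast(v, model, horse$regimen$dose)
  if (is.null(mm)) return(rep(NaN, length(horse$dv)))
  tr <- horse$trel
  f <- 0
  for (i in seq_along(mm$lambda))
    f <- f + mm$coef[i] * exp(-mm$lambda[i] * tr)
  f <- if (ncol(tr) > 1L) rowSums(f, na.rm = TRUE) else {
    f[is.na(f)] <- 0; as.numeric(f)
  }
  rss <- v[[length(v)]]
  f[horse$urine] <- f[horse$urine] * rss
  f
}

# -2/2-free penalized objective: -log p(y | eta) - log N(eta; 0, Omega)
# up to the constant 0.5*d*log(2pi) + 0.5*log|Omega| (added in .laplace_ll)
.map_objective <- function(eta, horse, theta, omega_inv, sigma, model) {
  f <- .pred_horse(horse, theta, eta, model)
  if (any(!is.finite(f)))
    return(1e10 * (1 + sum(eta^2)))   # ramp back toward the feasible region
  v <- .residual_var(f, horse$matrix, sigma)
  r <- horse$dv - f
  0.5 * sum(r^2 / v + log(2 * pi * v)) + 0.5 * drop(eta %*% omega_inv %*% eta)
}

# posterior mode of eta for one horse (bounded quasi-Newton from a warm
# start, with a derivative-free fallback for ill-scaled likelihoods)
.map_eta <- function(horse, theta, omega_inv, sigma, model, start = NULL) {
  d <- length(theta)
  if (is.null(start)) start <- rep(0, d)
  if (!length(horse$dv))
    return(list(eta = stats::setNames(rep(0, d), names(theta)), value = 0,
                convergence = 0L))
  fit <- stats::optim(start, .map_objective, horse = horse, theta = theta,
                      omega_inv = omega_inv, sigma = sigma, model = model,
                      method = "L-BFGS-B", lower = -6, upper = 6,
                      control = list(maxit = 200, factr = 1e3))
  if (fit$convergence != 0L || !is.finite(fit$value) || fit$value >= 1e9) {
    alt <- stats::optim(rep(0, d), .map_objective, horse = horse,
                        theta = theta, omega_inv = omega_inv, sigma = sigma,
                        model = model, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.finite(alt$value) && alt$value < fit$value) fit <- alt
  }
  list(eta = stats::setNames(fit$par, names(theta)), value = fit$value,
       convergence = fit$convergence)
}

# Gauss-Newton (first-order conditional) Hessian of the MAP objective:
# F' W F + Omega^-1 with F the prediction jacobian wrt eta at the mode
# and W the inverse residual variances.  Also returns F for reuse.
.map_hessian <- function(eta, horse, theta, omega_inv, sigma, model, h = 1e-4) {
  d <- length(eta)
  if (!length(horse$dv)) return(list(H = omega_inv, Fm = NULL))
  Fm <- matrix(0, length(horse$dv), d)
  for (j in seq_len(d)) {
    ej <- replace(numeric(d), j, h)
    Fm[, j] <- (.pred_horse(horse, theta, eta + ej, model) -
                  .pred_horse(horse, theta, eta - ej, model)) / (2 * h)
  }
  f <- .pred_horse(horse, theta, eta, model)
  w <- 1 / .residual_var(f, horse$matrix, sigma)
  list(H = crossprod(Fm * sqrt(w)) + omega_inv, Fm = Fm)
}

# per-horse Laplace contribution to the marginal log-likelihood
# (ldet_omega passed in to avoid recomputation)
.laplace_ll_horse <- function(horse, theta, oinv, ldet_omega, sigma, model,
                              start) {
  m <- .map_eta(horse, theta, oinv, sigma, model, start = start)
  H <- .map_hessian(m$eta, horse, theta, oinv, sigma, model)$H
  si <- .safe_inverse(H)
  list(ll = -m$value - 0.5 * si$logdet - 0.5 * ldet_omega,
       eta = m$eta, V = si$inv)
}

# make a symmetric matrix safely invertible; returns list(inv, logdet)
.safe_inverse <- function(H, floor = 1e-6) {
  e <- eigen(H, symmetric = TRUE)
  v <- pmax(e$values, floor)
  list(inv = e$vectors %*% ((1 / v) * t(e$vectors)), logdet = sum(log(v)))
}

# ML update of one matrix's residual sigmas given residuals r and ipred f
.update_sigma <- function(r, f, start) {
  if (length(r) < 3L) return(start)
  nll <- function(ls) {
    v <- (exp(ls[1]) * f)^2 + exp(ls[2])^2
    0.5 * sum(r^2 / v + log(v))
  }
  fit <- stats::optim(log(pmax(start, 1e-4)), nll, method = "Nelder-Mead",
                      control = list(maxit = 300))
  pmax(exp(fit$par), 1e-4)
}

#' Fit the joint plasma-urine population model
#'
#' Maximum-likelihood estimation of the nonlinear mixed-effects model by
#' an EM algorithm with mode (Laplace) approximation of the conditional
#' step -- the classical iterated two-stage scheme: the E-step computes
#' each horse's posterior-mode eta and its curvature, the M-step updates
#' the typical values (geometric mean shift), the full Omega (average of
#' mode outer products plus conditional covariances, projected to
#' positive semidefinite) and the matrix-specific residual sigmas by
#' direct likelihood maximization.  The marginal log-likelihood is
#' evaluated by the Laplace approximation at the optimum and the BIC as
#' \eqn{-2\ln L + k\ln n}.
#'
#' Below-LOQ rows and pre-equilibrium urine rows (< 24 h after the first
#' dose) are excluded from the likelihood.
#'
#' @param data a \code{"pk_dataset"} (ideally passed through
#'   \code{\link{censor_loq}} first).
#' @param init a \code{\link{population_params}} object with starting
#'   typical values and sigmas (e.g. from \code{\link{nca_initial_estimates}}
#'   via \code{\link{init_from_nca}}); its Omega is ignored in favour of
#'   \code{settings$omega_init} on the diagonal.
#' @param settings see \code{\link{fit_settings}}.
#' @return object of class \code{"fitted_model"}: \code{pop} (estimates),
#'   \code{logLik}, \code{k}, \code{n_obs}, \code{BIC}, \code{ebe}
#'   (per-horse posterior-mode etas), \code{ebe_var} (conditional
#'   covariances), \code{convergence}, \code{settings}, \code{horses}.
#' @export
fit_population <- function(data, init, settings = fit_settings()) {
  stopifnot(inherits(init, "population_params"))
  horses <- .prep_horses(data)
  model <- settings$model
  pn <- .model_pars(model)
  d <- length(pn)
  theta <- init$theta[pn]
  sigma <- init$sigma
  omega <- diag(settings$omega_init, d)
  dimnames(omega) <- list(pn, pn)
  nh <- length(horses)
  eta <- matrix(0, nh, d, dimnames = list(names(horses), pn))
  Vs <- vector("list", nh)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(settings$max_iter)) {
    oinv <- .safe_inverse(omega, floor = 1e-8)$inv
    obj <- 0
    for (i in seq_len(nh)) {
      m <- .map_eta(horses[[i]], theta, oinv, sigma, model, start = eta[i, ])
      eta[i, ] <- m$eta
      obj <- obj + m$value
      H <- .map_hessian(eta[i, ], horses[[i]], theta, oinv, sigma, model)$H
      Vs[[i]] <- .safe_inverse(H)$inv
    }
    trace <- c(trace, obj)
    # M-step
    mbar <- colMeans(eta)
    theta_new <- theta * exp(mbar)
    eta <- sweep(eta, 2, mbar)
    S <- Reduce(`+`, lapply(seq_len(nh), function(i)
      tcrossprod(eta[i, ]) + Vs[[i]])) / nh
    if (settings$omega_structure == "diag") S <- diag(diag(S))
    omega <- .nearest_psd((S + t(S)) / 2, warn = FALSE)
    dimnames(omega) <- list(pn, pn)
    ipred <- unlist(lapply(seq_len(nh), function(i)
      .pred_horse(horses[[i]], theta_new, eta[i, ], model)))
    dv <- unlist(lapply(horses, `[[`, "dv"))
    mat <- unlist(lapply(horses, `[[`, "matrix"))
    r <- dv - ipred
    for (m in c("plasma", "urine")) {
      sel <- mat == m
      if (sum(sel) >= 3L) {
        s <- .update_sigma(r[sel], ipred[sel],
                           sigma[paste0(m, c("_prop", "_add"))])
        sigma[paste0(m, c("_prop", "_add"))] <- s
      }
    }
    delta <- max(abs(log(theta_new / theta)))
    if (settings$verbose)
      message(sprintf("iter %d  obj %.3f  delta %.5f", it, obj, delta))
    theta <- theta_new
    if (delta < settings$rel_tol && it > 1L) { converged <- TRUE; break }
  }
  ldet_omega <- sum(log(pmax(eigen(omega, symmetric = TRUE,
                                   only.values = TRUE)$values, 1e-10)))
  oinv <- .safe_inverse(omega, floor = 1e-8)$inv
  # optional Laplace-ML polish of the typical values (Omega, sigma fixed).
  # The conditional modes are re-found from the fixed EM modes at every
  # evaluation so the objective is deterministic in theta.
  if (isTRUE(settings$polish)) {
    base_eta <- eta
    nll_theta <- function(lt) {
      th <- stats::setNames(exp(lt), pn)
      tot <- 0
      for (i in seq_len(nh))
        tot <- tot + .laplace_ll_horse(horses[[i]], th, oinv, ldet_omega,
                                       sigma, model, start = base_eta[i, ])$ll
      -tot
    }
    pol <- stats::optim(log(theta), nll_theta, method = "Nelder-Mead",
                        control = list(maxit = settings$polish_iter,
                                       reltol = 1e-8))
    theta <- stats::setNames(exp(pol$par), pn)
    if (settings$verbose)
      message(sprintf("polish: -logLik %.3f after %d evaluations",
                      pol$value, pol$counts[1L]))
  }
  # final conditional step and Laplace marginal log-likelihood
  ll <- 0
  for (i in seq_len(nh)) {
    r <- .laplace_ll_horse(horses[[i]], theta, oinv, ldet_omega, sigma, model,
                           start = eta[i, ])
    eta[i, ] <- r$eta
    Vs[[i]] <- r$V
    ll <- ll + r$ll
  }
  n_obs <- sum(lengths(lapply(horses, `[[`, "dv")))
  k <- d + (if (settings$omega_structure == "full") d * (d + 1) / 2 else d) + 4L
  pop <- .fitted_pop(theta, omega, sigma, model)
  structure(list(pop = pop, theta = theta, omega = omega, sigma = sigma,
                 model = model, logLik = ll, k = k, n_obs = n_obs,
                 BIC = -2 * ll + k * log(n_obs),
                 ebe = eta, ebe_var = Vs,
                 convergence = list(converged = converged,
                                    iterations = length(trace),
                                    objective_trace = trace),
                 settings = settings, horses = horses),
            class = "fitted_model")
}

# embed a reduced model's estimates in a full population_params object
.fitted_pop <- function(theta, omega, sigma, model) {
  if (model == "two_cpt") {
    th <- c(theta, Cl3 = 1e-8, V3 = 1)[.PARAM_NAMES]
    om <- matrix(0, 7, 7, dimnames = list(.PARAM_NAMES, .PARAM_NAMES))
    om[names(theta), names(theta)] <- omega
    population_params(th, om, sigma)
  } else population_params(theta, omega, sigma)
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("Population fit (%s, %d horses, %d observations)\n",
              x$model, nrow(x$ebe), x$n_obs))
  cat(sprintf("  logLik %.2f  k %d  BIC %.2f  %s after %d iterations\n",
              x$logLik, x$k, x$BIC,
              if (x$convergence$converged) "converged" else "NOT converged",
              x$convergence$iterations))
  cat("  theta:\n"); print(round(x$theta, 4))
  cat("  BSV CV%:\n"); print(round(cv_percent(diag(x$omega)), 1))
  cat("  sigma:\n"); print(round(x$sigma, 4))
  invisible(x)
}

#' Likelihood-ratio and BIC comparison of two fits
#'
#' @param fit_a the simpler (nested) model fit.
#' @param fit_b the richer model fit.
#' @return list with \code{lrt} (\eqn{-2(\ln L_a - \ln L_b)}), \code{df},
#'   \code{p_value} and \code{delta_BIC} (\code{BIC_a - BIC_b}; positive
#'   favours the richer model).  Refuses the LRT (returns the BIC delta
#'   only, with a message) when the fits are not nested.
#' @export
compare_models <- function(fit_a, fit_b) {
  nested <- fit_a$n_obs == fit_b$n_obs && fit_a$k <= fit_b$k &&
    all(names(fit_a$theta) %in% names(fit_b$theta))
  dbic <- fit_a$BIC - fit_b$BIC
  if (!nested) {
    message("fits are not nested; reporting the BIC difference only")
    return(list(lrt = NA_real_, df = NA_integer_, p_value = NA_real_,
                delta_BIC = dbic))
  }
  lrt <- max(-2 * (fit_a$logLik - fit_b$logLik), 0)
  df <- fit_b$k - fit_a$k
  p <- if (df > 0) stats::pchisq(lrt, df, lower.tail = FALSE) else 1
  list(lrt = lrt, df = df, p_value = p, delta_BIC = dbic)
}

#' Bootstrap precision of the population estimates
#'
#' Resamples horses with replacement, stratified by study arm, refits
#' the model on each replicate (warm-started at the original estimates)
#' and reports per-parameter standard errors, CV\% and 2.5/97.5
#' percentile confidence intervals, in the layout of the published
#' bootstrap table.  The regulatory chain (EPC/IPC/IUC at 1.1 mg/kg/24 h)
#' is propagated through each replicate.
#'
#' @param data a \code{"pk_dataset"}.
#' @param fit the original \code{\link{fit_population}} fit.
#' @param n_boot number of bootstrap replicates.
#' @param seed optional RNG seed.
#' @param settings settings for the replicate refits (defaults to the
#'   original settings with \code{max_iter = 6}).
#' @return list with \code{table} (parameter, estimate, se, cv_percent,
#'   lower, upper), \code{n_success} and \code{n_failed}.  Aborts when
#'   fewer than 80\% of replicates succeed.
#' @export
bootstrap_ci <- function(data, fit, n_boot = 50L, seed = NULL,
                         settings = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(settings)) {
    settings <- fit$settings
    settings$max_iter <- 6L
    settings$polish <- FALSE
  }
  arms <- if (!is.null(data$ARM)) data$ARM else rep("all", nrow(data))
  horse_arm <- tapply(arms, data$ID, `[`, 1L)
  ids_by_arm <- split(names(horse_arm), unlist(horse_arm))
  draw <- function() {
    new <- list(); nid <- 0L
    for (ids in ids_by_arm) for (id in sample(ids, length(ids), replace = TRUE)) {
      nid <- nid + 1L
      h <- data[data$ID == id, ]
      h$ID <- nid
      new[[nid]] <- h
    }
    out <- do.call(rbind, new)
    class(out) <- class(data)
    out
  }
  stat <- function(f) {
    rl <- regulatory_limits(f$pop)
    c(f$theta, f$sigma, EPC = rl$EPC, IPC = rl$IPC, IUC = rl$IUC)
  }
  reps <- list(); failed <- 0L
  for (b in seq_len(n_boot)) {
    r <- tryCatch(stat(fit_population(draw(), fit$pop, settings)),
                  error = function(e) NULL)
    if (is.null(r)) failed <- failed + 1L else reps[[length(reps) + 1L]] <- r
  }
  if (length(reps) < 0.8 * n_boot)
    stop("bootstrap aborted: only ", length(reps), "/", n_boot,
         " replicates converged", call. = FALSE)
  if (failed) message(failed, " bootstrap replicate(s) failed and were dropped")
  B <- do.call(rbind, reps)
  est <- stat(fit)
  tab <- data.frame(parameter = names(est), estimate = unname(est),
                    se = apply(B, 2, stats::sd),
                    cv_percent = 100 * apply(B, 2, stats::sd) / abs(unname(est)),
                    lower = apply(B, 2, stats::quantile, 0.025),
                    upper = apply(B, 2, stats::quantile, 0.975),
                    row.names = NULL)
  list(table = tab, n_success = length(reps), n_failed = failed)
}
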