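#' MAP-Bayesian estimate of one horse's parameters
#'
#' Conditions the population model on a horse's observed concentrations:
#' the posterior mode of the log-scale random effects minimizes the sum
#' of the residual negative log-likelihood (combined error model, matrix
#' specific) and the negative log of the multivariate-normal prior
#' \eqn{N(0, \Omega)}, by quasi-Newton search from \eqn{\eta = 0}.
#' Residual sigmas stay fixed at their population values.  With no
#' usable observations the prior mode (the typical horse) is returned.
#'
#' @param pop a \code{\link{population_params}} object (the prior).
#' @param observations one horse's rows of a \code{"pk_dataset"} (dose
#'   rows optional when \code{regimen} is given); may contain zero
#'   observation rows.  Observations below the LOQ are not usable; if
#'   all observations are censored the call fails with a clear message.
#' @param regimen a \code{\link{dosing_regimen}}; defaults to the dose
#'   rows of \code{observations}.
#' @return object of class \code{"bayesian_estimate"}: \code{eta_hat},
#'   \code{params} (individual \code{\link{disposition_params}}),
#'   \code{n_obs}, \code{regimen}, \code{flag} (\code{"ok"},
#'   \code{"prior-mode"} or \code{"optimizer-failure"}).
#' @export
map_estimate <- function(pop, observations, regimen = NULL) {
  stopifnot(inherits(pop, "population_params"))
  id <- if (nrow(observations)) unique(observations$ID)[1L] else "horse"
  if (is.null(regimen)) {
    dt <- observations[observations$EVID == 1, ]
    if (!nrow(dt)) stop("no dose rows and no regimen given", call. = FALSE)
    times <- sort(dt$TIME)
    regimen <- structure(list(dose = dt$AMT[1L], times = times,
                              interval = if (length(times) > 1L)
                                diff(times)[1L] else 24),
                         class = "dosing_regimen")
  }
  obs <- observations[observations$EVID == 0 & !is.na(observations$DV), ]
  n_raw <- nrow(obs)
  if (!is.null(obs$BLOQ)) obs <- obs[!(obs$BLOQ %in% TRUE), ]
  obs <- obs[!(obs$MATRIX == "urine" & obs$TIME < regimen$times[1L] + 24), ]
  if (n_raw > 0L && !nrow(obs))
    stop("all observations for horse ", id, " are below the LOQ (or ",
         "pre-equilibrium urine); cannot individualize from censored-only data",
         call. = FALSE)
  horse <- .make_horse(id, regimen, obs$TIME, obs$DV, obs$MATRIX)
  d <- length(pop$theta)
  flag <- "ok"
  if (!nrow(obs)) {
    eta <- stats::setNames(rep(0, d), .PARAM_NAMES)
    flag <- "prior-mode"
  } else {
    oinv <- .safe_inverse(pop$omega, floor = 1e-8)$inv
    m <- .map_eta(horse, pop$theta, oinv, pop$sigma, "three_cpt")
    eta <- m$eta
    if (!is.finite(m$value) || m$value >= 1e9) {
      warning("posterior-mode search failed; returning prior mode",
              call. = FALSE)
      eta <- stats::setNames(rep(0, d), .PARAM_NAMES)
      flag <- "optimizer-failure"
    }
  }
  params <- do.call(disposition_params, as.list(pop$theta * exp(eta)))
  structure(list(id = id, eta_hat = eta, params = params, n_obs = nrow(obs),
                 regimen = regimen, flag = flag),
            class = "bayesian_estimate")
}

#' @export
print.bayesian_estimate <- function(x, ...) {
  cat(sprintf("MAP-Bayesian estimate for horse %s (%d observations, %s)\n",
              x$id, x$n_obs, x$flag))
  cat("  eta:\n"); print(round(x$eta_hat, 3))
  invisible(x)
}

#' Individualized Bayesian withdrawal time (IBWT)
#'
#' Applies \code{\link{dt_model}} to the posterior-mode individual
#' curves for a plasma/urine screening-limit pair.
#'
#' @param estimate a \code{\link{map_estimate}} result.
#' @param sl one row of \code{\link{screening_limits}} (or a list with
#'   \code{plasma_SL} and \code{urine_SL}).
#' @return list with elements \code{plasma} and \code{urine}, each a
#'   \code{"detection_time"} result.
#' @export
ibwt <- function(estimate, sl) {
  stopifnot(inherits(estimate, "bayesian_estimate"))
  list(plasma = dt_model(estimate$params, estimate$regimen, "plasma",
                         sl$plasma_SL, id = estimate$id),
       urine = dt_model(estimate$params, estimate$regimen, "urine",
                        sl$urine_SL, id = estimate$id))
}

#' Evaluate a Bayesian sampling scenario against reference detection times
#'
#' For every horse of a cohort: reduce the data to the clinical sampling
#' scenario, compute the MAP-Bayesian estimate and its IBWT, and compare
#' with a reference DT -- by default the DT of the horse's true
#' generating parameters (synthetic cohorts carry them as the
#' \code{"truth"} attribute), or the per-horse interpolated DT from the
#' full data (\code{reference = "interpolated"}).
#'
#' @param cohort a \code{"pk_dataset"}.
#' @param scenario \code{"rich"}, \code{"rich72"} or \code{"sparse"}.
#' @param sl a screening-limit pair (row of \code{\link{screening_limits}}).
#' @param pop the population prior.
#' @param reference \code{"truth"} or \code{"interpolated"}.
#' @return list with \code{table} (per horse: reference and Bayesian DT
#'   per matrix, absolute errors) and \code{summary} (per matrix MAE and
#'   SD of the absolute error, h).
#' @export
scenario_eval <- function(cohort, scenario = c("rich", "sparse", "rich72"),
                          sl = screening_limits()[1L, ], pop,
                          reference = c("truth", "interpolated")) {
  scenario <- match.arg(scenario)
  reference <- match.arg(reference)
  truth <- attr(cohort, "truth")
  if (reference == "truth" && is.null(truth))
    stop("cohort carries no truth attribute; use reference = 'interpolated'",
         call. = FALSE)
  reduced <- scenario_sampling(cohort, scenario)
  rows <- list()
  for (id in unique(reduced$ID)) {
    horse_rows <- reduced[reduced$ID == id, ]
    est <- tryCatch(map_estimate(pop, horse_rows), error = function(e) NULL)
    if (is.null(est)) next
    bd <- ibwt(est, sl)
    if (reference == "truth") {
      tr <- truth[truth$ID == id, ]
      tp <- do.call(disposition_params, as.list(unlist(tr[.PARAM_NAMES])))
      rp <- dt_model(tp, est$regimen, "plasma", sl$plasma_SL, id = id)$DT
      ru <- dt_model(tp, est$regimen, "urine", sl$urine_SL, id = id)$DT
    } else {
      full <- cohort[cohort$ID == id, ]
      rp <- dt_interpolated(full, "plasma", sl$plasma_SL)$DT
      ru <- dt_interpolated(full, "urine", sl$urine_SL)$DT
    }
    rows[[length(rows) + 1L]] <-
      data.frame(ID = id, scenario = scenario,
                 ref_plasma = rp, bayes_plasma = bd$plasma$DT,
                 ref_urine = ru, bayes_urine = bd$urine$DT,
                 abs_err_plasma = abs(bd$plasma$DT - rp),
                 abs_err_urine = abs(bd$urine$DT - ru))
  }
  if (!length(rows)) {
    message("no horse qualified for the ", scenario, " scenario")
    return(list(table = NULL,
                summary = data.frame(matrix = c("plasma", "urine"),
                                     mae = NA_real_, sd = NA_real_, n = 0L)))
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  summ <- data.frame(
    matrix = c("plasma", "urine"),
    mae = c(mean(tab$abs_err_plasma, na.rm = TRUE),
            mean(tab$abs_err_urine, na.rm = TRUE)),
    sd = c(stats::sd(tab$abs_err_plasma, na.rm = TRUE),
           stats::sd(tab$abs_err_urine, na.rm = TRUE)),
    n = c(sum(!is.na(tab$abs_err_plasma)), sum(!is.na(tab$abs_err_urine))))
  list(table = tab, summary = summ)
}
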