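# shared fixtures, computed lazily and cached for the whole test run

.fx <- new.env()

fx_pop <- function() {
  if (is.null(.fx$pop)) .fx$pop <- flunixin_prior()
  .fx$pop
}

fx_typical <- function() do.call(disposition_params, as.list(fx_pop()$theta))

# two-arm cohort (rich Japanese LOQ + US arm) used by the estimation and
# diagnostics tests; one shared fit so the expensive step runs once
fx_cohort <- function() {
  if (is.null(.fx$cohort))
    .fx$cohort <- generate_cohort(flunixin_study_arms()[c(1, 3)], fx_pop(),
                                  seed = 7)
  .fx$cohort
}

fx_censored <- function() {
  if (is.null(.fx$censored))
    .fx$censored <- suppressWarnings(censor_loq(fx_cohort()))$data
  .fx$censored
}

fx_fit <- function() {
  if (is.null(.fx$fit)) {
    d <- fx_censored()
    init <- init_from_nca(nca_initial_estimates(d), d)
    .fx$fit <- fit_population(d, init, fit_settings(max_iter = 32))
  }
  .fx$fit
}

# one-arm design with a sampling schedule containing the 9 h clinical point
fx_rich_arm <- function(n, n_doses = 1L) {
  study_arm_design("rich-arm", "Japan", n, dose_mg_kg = 1.1,
                   n_doses = n_doses, interval = 24,
                   plasma_loq = 0.1, urine_loq = 3.0,
                   age_range = c(4, 10), bw_range = c(428, 506),
                   plasma_times = c(0.25, 1, 4, 9, 24, 48, 72, 96, 120, 168))
}

# random positive disposition parameter sets (log-normal spread around the
# published typicals) for the closed-form vs ODE checks
fx_random_params <- function(n, seed = 424242) {
  set.seed(seed)
  th <- fx_pop()$theta
  lapply(seq_len(n), function(i)
    do.call(disposition_params,
            as.list(th * exp(stats::rnorm(7, 0, 0.4)))))
}

# independent oracle: numerical integration of the three-compartment ODE
ode_plasma <- function(p, dose, times) {
  k10 <- p$Cl / p$V1; k12 <- p$Cl2 / p$V1
  k21 <- if (p$Cl2 > 0) p$Cl2 / p$V2 else 0
  k13 <- p$Cl3 / p$V1
  k31 <- if (p$Cl3 > 0) p$Cl3 / p$V3 else 0
  rhs <- function(t, y, parms)
    list(c(-(k10 + k12 + k13) * y[1] + k21 * y[2] + k31 * y[3],
           k12 * y[1] - k21 * y[2],
           k13 * y[1] - k31 * y[3]))
  out <- deSolve::ode(c(dose, 0, 0), c(0, times), rhs, NULL,
                      rtol = 1e-10, atol = 1e-10)
  out[-1, 2] / p$V1
}

# minimal hand-built dataset: one horse, explicit observation rows
make_records <- function(id, dose_time = 0, amt = 1.1e6, times, dvs,
                         matrix = "plasma", loq = 0.1) {
  dose <- data.frame(ID = id, TIME = dose_time, EVID = 1L, AMT = amt,
                     DV = NA_real_, MATRIX = NA_character_, LOQ = NA_real_,
                     BLOQ = NA)
  out <- if (length(times)) {
    rbind(dose, data.frame(ID = id, TIME = times, EVID = 0L, AMT = NA_real_,
                           DV = dvs, MATRIX = matrix, LOQ = loq,
                           BLOQ = dvs < loq))
  } else dose
  class(out) <- c("pk_dataset", "data.frame")
  out
}
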