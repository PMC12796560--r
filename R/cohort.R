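#' Study-arm design
#'
#' Describes one arm of a multi-country flunixin study: dose, regimen,
#' per-matrix limits of quantification, covariate ranges and sampling
#' schedules.  Sampling times are expressed in hours after the LAST
#' administration (for single-dose arms this is time after the dose).
#'
#' @param label arm label (unique).
#' @param country country of origin.
#' @param n_horses number of horses (>= 1).
#' @param dose_mg_kg dose in mg/kg, or \code{NULL} if \code{dose_mg}.
#' @param dose_mg fixed dose in mg/horse (converted via each horse's
#'   simulated body weight).
#' @param n_doses,interval regimen (IV bolus; q24h x 5 etc.).
#' @param plasma_loq,urine_loq limits of quantification (ng/mL).
#' @param age_range,bw_range covariate ranges (years; kg), drawn
#'   uniformly.
#' @param sex,breed character; \code{sex} is recycled over horses.
#' @param plasma_times,urine_times sampling schedules, h after last dose.
#' @return object of class \code{"study_arm_design"}.
#' @export
study_arm_design <- function(label, country, n_horses,
                             dose_mg_kg = NULL, dose_mg = NULL,
                             n_doses = 1L, interval = 24,
                             plasma_loq, urine_loq,
                             age_range, bw_range, sex = "female",
                             breed = "Thoroughbred",
                             plasma_times = c(0.083, 0.25, 0.5, 1, 2, 4, 6, 8,
                                              12, 24, 36, 48, 72, 96, 120, 144, 168),
                             urine_times = c(24, 36, 48, 72, 96, 120, 168)) {
  if (n_horses < 1) stop("n_horses must be >= 1", call. = FALSE)
  if (plasma_loq <= 0 || urine_loq <= 0) stop("LOQs must be positive", call. = FALSE)
  if (is.unsorted(plasma_times, strictly = TRUE) ||
      is.unsorted(urine_times, strictly = TRUE))
    stop("sampling schedules must be strictly increasing", call. = FALSE)
  structure(list(label = label, country = country, n_horses = as.integer(n_horses),
                 dose_mg_kg = dose_mg_kg, dose_mg = dose_mg,
                 n_doses = as.integer(n_doses), interval = interval,
                 plasma_loq = plasma_loq, urine_loq = urine_loq,
                 age_range = age_range, bw_range = bw_range,
                 sex = sex, breed = breed,
                 plasma_times = plasma_times, urine_times = urine_times),
            class = "study_arm_design")
}

#' The six packaged flunixin study arms
#'
#' Emulates the published four-country dataset: 10 + 10 Japanese mares
#' (single and q24h x 5 at 1.1 mg/kg, plasma LOQ 0.1, urine LOQ 3),
#' 16 + 11 US Thoroughbreds (1.1 mg/kg and 500 mg/horse single, LOQ
#' 1/0.5), 6 UK Thoroughbreds and 12 Australian Standardbred geldings --
#' 65 horses in total.
#'
#' @param plasma_times,urine_times optional replacement sampling
#'   schedules applied to every arm (h after last dose).
#' @return list of \code{\link{study_arm_design}} objects.
#' @export
flunixin_study_arms <- function(plasma_times = NULL, urine_times = NULL) {
  arms <- list(
    study_arm_design("japan-single", "Japan", 10, dose_mg_kg = 1.1,
                     plasma_loq = 0.1, urine_loq = 3.0,
                     age_range = c(4, 10), bw_range = c(428, 506),
                     sex = "female"),
    study_arm_design("japan-q24h", "Japan", 10, dose_mg_kg = 1.1,
                     n_doses = 5, interval = 24,
                     plasma_loq = 0.1, urine_loq = 3.0,
                     age_range = c(4, 9), bw_range = c(442, 530),
                     sex = "female"),
    study_arm_design("usa-single", "USA", 16, dose_mg_kg = 1.1,
                     plasma_loq = 1.0, urine_loq = 0.5,
                     age_range = c(5, 8), bw_range = c(491, 626),
                     sex = rep(c("female", "gelding"), each = 8)),
    study_arm_design("usa-fixed", "USA", 11, dose_mg = 500,
                     plasma_loq = 1.0, urine_loq = 0.5,
                     age_range = c(3, 8), bw_range = c(469, 592),
                     sex = c(rep("female", 3), rep("gelding", 8))),
    study_arm_design("uk-single", "UK", 6, dose_mg_kg = 1.1,
                     plasma_loq = 1.0, urine_loq = 0.5,
                     age_range = c(10, 22), bw_range = c(434, 537),
                     sex = c(rep("male", 4), rep("gelding", 2))),
    study_arm_design("australia-single", "Australia", 12, dose_mg_kg = 1.1,
                     plasma_loq = 1.0, urine_loq = 1.0,
                     age_range = c(4, 12), bw_range = c(421, 524),
                     sex = "gelding", breed = "Standardbred"))
  if (!is.null(plasma_times) || !is.null(urine_times))
    arms <- lapply(arms, function(a) {
      if (!is.null(plasma_times)) a$plasma_times <- plasma_times
      if (!is.null(urine_times)) a$urine_times <- urine_times
      a
    })
  arms
}

# regimen for one horse of an arm (needs BW for fixed mg/horse doses)
.arm_regimen <- function(arm, bw) {
  dosing_regimen(dose_mg_kg = arm$dose_mg_kg, dose_mg = arm$dose_mg,
                 bw_kg = bw, n_doses = arm$n_doses, interval = arm$interval)
}

#' Generate a synthetic multi-arm cohort
#'
#' One horse per ID: disposition parameters drawn with
#' \code{\link{sample_individual}}, covariates drawn uniformly from the
#' arm ranges, noise-free predictions at the scheduled times perturbed by
#' \code{\link{apply_residual_error}}, and below-LOQ flags set.  The
#' generating truth (parameters and etas per horse) is attached as
#' attribute \code{"truth"} for recovery experiments.
#'
#' @param designs list of \code{\link{study_arm_design}} objects.
#' @param pop a \code{\link{population_params}} object.
#' @param seed optional RNG seed (fixed seed gives an identical dataset).
#' @return a \code{"pk_dataset"} data.frame (see \code{\link{read_dataset}}
#'   for the column dialect) with attribute \code{"truth"}.
#' @export
generate_cohort <- function(designs, pop, seed = NULL) {
  if (inherits(designs, "study_arm_design")) designs <- list(designs)
  if (!length(designs)) stop("empty design list", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); truth <- list(); id <- 0L
  for (arm in designs) {
    pars <- sample_individual(pop, arm$n_horses)
    if (arm$n_horses == 1L) pars <- list(pars)
    eta <- attr(pars, "eta")
    if (is.null(eta)) eta <- attr(pars[[1L]], "eta")
    sexes <- rep(arm$sex, length.out = arm$n_horses)
    for (i in seq_len(arm$n_horses)) {
      id <- id + 1L
      age <- round(stats::runif(1, arm$age_range[1], arm$age_range[2]), 1)
      bw <- round(stats::runif(1, arm$bw_range[1], arm$bw_range[2]), 1)
      reg <- .arm_regimen(arm, bw)
      tlast <- reg$times[length(reg$times)]
      base <- data.frame(ID = id, ARM = arm$label, COUNTRY = arm$country,
                         BREED = arm$breed, SEX = sexes[i], AGE = age, BW = bw,
                         stringsAsFactors = FALSE)
      dose_rows <- cbind(base[rep(1, length(reg$times)), , drop = FALSE],
                         TIME = reg$times, EVID = 1L, AMT = reg$dose,
                         MATRIX = NA_character_, DV = NA_real_,
                         LOQ = NA_real_, BLOQ = NA)
      tp <- tlast + arm$plasma_times
      tu <- tlast + arm$urine_times
      cp <- plasma_concentration(pars[[i]], reg, tp)
      cu <- as.numeric(urine_concentration(pars[[i]], reg, tu))
      op <- suppressMessages(apply_residual_error(cp, "plasma", pop))
      ou <- suppressMessages(apply_residual_error(cu, "urine", pop))
      obs_rows <- cbind(base[rep(1, length(tp) + length(tu)), , drop = FALSE],
                        TIME = c(tp, tu), EVID = 0L, AMT = NA_real_,
                        MATRIX = rep(c("plasma", "urine"), c(length(tp), length(tu))),
                        DV = c(op, ou),
                        LOQ = rep(c(arm$plasma_loq, arm$urine_loq),
                                  c(length(tp), length(tu))))
      obs_rows$BLOQ <- obs_rows$DV < obs_rows$LOQ
      rows[[length(rows) + 1L]] <- rbind(dose_rows, obs_rows)
      truth[[length(truth) + 1L]] <-
        data.frame(ID = id, ARM = arm$label, c(pars[[i]]),
                   t(stats::setNames(eta[i, ], paste0("eta_", colnames(eta)))))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$ID, out$TIME, out$EVID,
                   match(out$MATRIX, c("plasma", "urine"))), ]
  rownames(out) <- NULL
  class(out) <- c("pk_dataset", "data.frame")
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Apply the below-LOQ exclusion rule
#'
#' Observations below their LOQ are removed when their matrix-wise
#' fraction is below 5\%; when the fraction reaches 5\% the rows are
#' retained with their \code{BLOQ} flag set and a warning is issued (the
#' likelihood machinery still excludes flagged rows).
#'
#' @param data a \code{"pk_dataset"}.
#' @return list with elements \code{data} (filtered dataset, truth
#'   attribute preserved) and \code{report} (per-matrix counts, fraction
#'   and action taken).
#' @export
censor_loq <- function(data) {
  truth <- attr(data, "truth")
  obs <- data$EVID == 0
  rep_rows <- list(); drop <- logical(nrow(data))
  for (m in c("plasma", "urine")) {
    sel <- obs & data$MATRIX == m
    n_total <- sum(sel)
    below <- sel & data$BLOQ
    n_below <- sum(below, na.rm = TRUE)
    frac <- if (n_total) n_below / n_total else 0
    action <- if (n_total == 0L) "no data"
      else if (n_below == 0L) "none"
      else if (frac < 0.05) "excluded"
      else "retained-flagged (>=5%)"
    if (action == "excluded") drop <- drop | (below %in% TRUE)
    if (action == "retained-flagged (>=5%)")
      warning(sprintf("%.1f%% of %s observations below LOQ; retained with flags",
                      100 * frac, m), call. = FALSE)
    rep_rows[[m]] <- data.frame(matrix = m, n_total = n_total,
                                n_below_loq = n_below, fraction = frac,
                                action = action)
  }
  out <- data[!drop, ]
  rownames(out) <- NULL
  class(out) <- class(data)
  attr(out, "truth") <- truth
  list(data = out, report = do.call(rbind, c(rep_rows, make.row.names = FALSE)))
}

# last administration time per horse
.last_dose_time <- function(data, id) {
  max(data$TIME[data$ID == id & data$EVID == 1])
}

#' Reduce a dataset to a clinical sampling scenario
#'
#' Emulates the sampling a veterinarian would realistically perform
#' before a Bayesian withdrawal-time estimate: \code{"rich"} keeps plasma
#' samples 9, 24 and 48 h after the last dose plus a urine sample at
#' 48 h; \code{"rich72"} replaces the 48 h samples by 72 h; \code{"sparse"}
#' keeps a single plasma sample 24 h after the last dose.  Horses missing
#' a required time (no observation within +/- 0.5 h) are excluded with a
#' message.
#'
#' @param data a \code{"pk_dataset"}.
#' @param scenario \code{"rich"}, \code{"rich72"} or \code{"sparse"}.
#' @return the reduced dataset (dose rows kept, truth subset preserved).
#' @export
scenario_sampling <- function(data, scenario = c("rich", "sparse", "rich72")) {
  scenario <- match.arg(scenario)
  req <- switch(scenario,
                rich = list(plasma = c(9, 24, 48), urine = 48),
                rich72 = list(plasma = c(9, 24, 72), urine = 72),
                sparse = list(plasma = 24, urine = numeric(0)))
  keep <- logical(nrow(data)); kept_ids <- c()
  for (id in unique(data$ID)) {
    tl <- .last_dose_time(data, id)
    sel <- rep(FALSE, nrow(data))
    ok <- TRUE
    for (m in names(req)) for (tt in req[[m]]) {
      cand <- which(data$ID == id & data$EVID == 0 & data$MATRIX == m &
                      abs(data$TIME - (tl + tt)) <= 0.5)
      if (!length(cand)) { ok <- FALSE } else sel[cand[1L]] <- TRUE
    }
    if (!ok) {
      message("horse ", id, " lacks a required ", scenario,
              "-scenario sample; excluded")
    } else {
      keep <- keep | sel | (data$ID == id & data$EVID == 1)
      kept_ids <- c(kept_ids, id)
    }
  }
  out <- data[keep, ]
  rownames(out) <- NULL
  class(out) <- class(data)
  truth <- attr(data, "truth")
  if (!is.null(truth)) attr(out, "truth") <- truth[truth$ID %in% kept_ids, ]
  out
}
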