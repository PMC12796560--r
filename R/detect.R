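.DT_QUANTILES <- c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)

# constructor for a detection-time result
.dt_result <- function(id, matrix, SL, method, DT, censored = "none") {
  structure(list(id = id, matrix = matrix, SL = SL, method = method,
                 DT = DT, censored = censored), class = "detection_time")
}

#' @export
print.detection_time <- function(x, ...) {
  cat(sprintf("DT[%s, %s, SL %g ng/mL, %s] = %s h%s\n", x$id, x$matrix, x$SL,
              x$method, ifelse(is.na(x$DT), "NC", format(round(x$DT, 2))),
              if (x$censored != "none") paste0(" (", x$censored, ")") else ""))
  invisible(x)
}

# concentration after the last dose, as a function of time since last dose
.post_last_curve <- function(params, regimen, matrix) {
  macro <- micro_to_macro(params, regimen$dose)
  tlast <- regimen$times[length(regimen$times)]
  shifts <- tlast - regimen$times            # >= 0
  mult <- if (matrix == "urine") params$Rss else 1
  function(dt) {
    v <- 0
    for (s in shifts) v <- v + .bolus_conc(macro, dt + s)
    mult * v
  }
}

#' Model-based detection time for one horse
#'
#' Finds the time after the last administration at which the noise-free
#' individual concentration curve falls below the screening limit.  The
#' curve after the last dose is strictly decreasing, so the crossing is
#' unique; it is located by bracketing and Brent root-finding to 0.01 h.
#'
#' @param params a \code{\link{disposition_params}} object.
#' @param regimen a \code{\link{dosing_regimen}} object.
#' @param matrix \code{"plasma"} or \code{"urine"} (urine uses the
#'   individual's Rss).
#' @param SL screening limit, ng/mL (> 0).
#' @param id identifier recorded in the result.
#' @return a \code{"detection_time"} result; DT = 0 with censoring flag
#'   \code{"never-above"} when the curve never exceeds the SL after the
#'   last dose.
#' @export
dt_model <- function(params, regimen, matrix = c("plasma", "urine"), SL,
                     id = "typical") {
  matrix <- match.arg(matrix)
  if (SL <= 0) stop("SL must be positive", call. = FALSE)
  f <- .post_last_curve(params, regimen, matrix)
  .dt_result(id, matrix, SL, "model", .dt_root(f, SL),
             if (f(0) <= SL) "never-above" else "none")
}

# root of curve(dt) = SL for a decreasing curve; 0 if already below
.dt_root <- function(f, SL) {
  if (f(0) <= SL) return(0)
  upper <- 48
  while (f(upper) > SL) {
    upper <- upper * 2
    if (upper > 1e6) stop("concentration never falls below SL", call. = FALSE)
  }
  stats::uniroot(function(t) f(t) - SL, c(0, upper), tol = 0.01)$root
}

#' Detection time by log-linear interpolation of observations
#'
#' Mirrors the NCA-engine approach: the DT is interpolated between the
#' last observation at or above the SL and the first later observation
#' below it, on the log-concentration scale (linear fallback when a
#' bracketing value is not positive).  With multiple dosing, only the
#' decline after the last dose can cross, so the last above-SL
#' observation is used.
#'
#' @param records one horse's rows of a \code{"pk_dataset"}.
#' @param matrix \code{"plasma"} or \code{"urine"}.
#' @param SL screening limit, ng/mL.
#' @return a \code{"detection_time"} result (method
#'   \code{"interpolated"}), measured from the last administration.
#'   Censoring flags: \code{"censored-low"} when no observation reaches
#'   the SL (the published tables' NC cells), \code{"censored-high"} when
#'   the concentration never falls below the SL within the sampling span.
#' @export
dt_interpolated <- function(records, matrix = c("plasma", "urine"), SL) {
  matrix <- match.arg(matrix)
  if (SL <= 0) stop("SL must be positive", call. = FALSE)
  id <- unique(records$ID)
  if (length(id) != 1L) stop("records must belong to a single horse", call. = FALSE)
  tlast <- max(records$TIME[records$EVID == 1])
  t0 <- min(records$TIME[records$EVID == 1])
  obs <- records[records$EVID == 0 & records$MATRIX == matrix & !is.na(records$DV), ]
  if (matrix == "urine") obs <- obs[obs$TIME >= t0 + 24, ]
  obs <- obs[order(obs$TIME), ]
  if (!nrow(obs))
    return(.dt_result(id, matrix, SL, "interpolated", NA_real_, "censored-low"))
  above <- which(obs$DV >= SL)
  if (!length(above))
    return(.dt_result(id, matrix, SL, "interpolated", NA_real_, "censored-low"))
  i <- max(above)
  if (i == nrow(obs))
    return(.dt_result(id, matrix, SL, "interpolated", NA_real_, "censored-high"))
  t1 <- obs$TIME[i]; t2 <- obs$TIME[i + 1L]
  c1 <- obs$DV[i]; c2 <- obs$DV[i + 1L]
  tc <- if (c1 > 0 && c2 > 0)
    t1 + (t2 - t1) * log(c1 / SL) / log(c1 / c2)
  else
    t1 + (t2 - t1) * (c1 - SL) / (c1 - c2)
  .dt_result(id, matrix, SL, "interpolated", max(tc - tlast, 0))
}

#' Cohort detection time under the EHSLC definition
#'
#' The cohort DT is the earliest scheduled sampling time (measured from
#' the last administration) from which onwards every horse's
#' observations are below the screening limit.  The returned value is by
#' construction an element of the sampling schedule.
#'
#' @param data a \code{"pk_dataset"} for one trial arm (shared schedule).
#' @param matrix \code{"plasma"} or \code{"urine"}.
#' @param SL screening limit, ng/mL.
#' @return a \code{"detection_time"} result with id \code{"cohort"};
#'   censored-high when concentrations are still above the SL at the last
#'   scheduled time.
#' @export
dt_ehslc <- function(data, matrix = c("plasma", "urine"), SL) {
  matrix <- match.arg(matrix)
  if (SL <= 0) stop("SL must be positive", call. = FALSE)
  obs <- data[data$EVID == 0 & data$MATRIX == matrix & !is.na(data$DV), ]
  tpost <- numeric(nrow(obs)); keep <- rep(TRUE, nrow(obs))
  for (id in unique(obs$ID)) {
    sel <- obs$ID == id
    tl <- .last_dose_time(data, id)
    t0 <- min(data$TIME[data$ID == id & data$EVID == 1])
    tpost[sel] <- obs$TIME[sel] - tl
    if (matrix == "urine") keep[sel] <- keep[sel] & obs$TIME[sel] >= t0 + 24
  }
  obs <- obs[keep & tpost >= 0, ]; tpost <- tpost[keep & tpost >= 0]
  if (!nrow(obs)) stop("no usable observations", call. = FALSE)
  grid <- sort(unique(round(tpost, 6)))
  tmax <- suppressWarnings(max(tpost[obs$DV >= SL]))
  if (!is.finite(tmax))
    return(.dt_result("cohort", matrix, SL, "ehslc", grid[1L]))
  later <- grid[grid > tmax + 1e-6]
  if (!length(later))
    return(.dt_result("cohort", matrix, SL, "ehslc", NA_real_, "censored-high"))
  .dt_result("cohort", matrix, SL, "ehslc", later[1L])
}

#' Monte Carlo detection-time study
#'
#' Simulates a virtual population by drawing individual parameters from
#' the population model, computes each horse's noise-free plasma and
#' urine detection times for every screening limit in the scenario set,
#' and summarizes the distributions by the 5/10/25/50/75/90/95-th
#' percentiles (type-7 quantiles).
#'
#' @param pop a \code{\link{population_params}} object.
#' @param regimen a \code{\link{dosing_regimen}} object.
#' @param sl_pairs data.frame as returned by
#'   \code{\link{screening_limits}}.
#' @param n number of virtual horses (5000 by default).
#' @param seed optional RNG seed; a fixed seed reproduces the study.
#' @return list with \code{summary} (one row per matrix x SL with
#'   percentile columns), \code{plasma} and \code{urine} (n x SL DT
#'   matrices), \code{pairs}, \code{n} and \code{seed}.
#' @export
mcs_population_dt <- function(pop, regimen, sl_pairs = screening_limits(),
                              n = 5000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eta <- draw_eta(pop$omega, n)
  psl <- sort(unique(sl_pairs$plasma_SL))
  usl <- sort(unique(sl_pairs$urine_SL))
  dt_p <- matrix(NA_real_, n, length(psl), dimnames = list(NULL, psl))
  dt_u <- matrix(NA_real_, n, length(usl), dimnames = list(NULL, usl))
  for (i in seq_len(n)) {
    par_i <- do.call(disposition_params, as.list(pop$theta * exp(eta[i, ])))
    fp <- .post_last_curve(par_i, regimen, "plasma")
    for (j in seq_along(psl)) dt_p[i, j] <- .dt_root(fp, psl[j])
    for (j in seq_along(usl)) dt_u[i, j] <- .dt_root(fp, usl[j] / par_i$Rss)
  }
  qrow <- function(x) stats::quantile(x, .DT_QUANTILES, type = 7, names = FALSE)
  summ <- rbind(
    data.frame(matrix = "plasma", SL = psl,
               t(vapply(seq_along(psl), function(j) qrow(dt_p[, j]),
                        numeric(length(.DT_QUANTILES))))),
    data.frame(matrix = "urine", SL = usl,
               t(vapply(seq_along(usl), function(j) qrow(dt_u[, j]),
                        numeric(length(.DT_QUANTILES))))))
  names(summ)[-(1:2)] <- paste0("p", 100 * .DT_QUANTILES)
  rownames(summ) <- NULL
  list(summary = summ, plasma = dt_p, urine = dt_u, pairs = sl_pairs,
       n = n, seed = seed)
}

#' Plasma-urine detection-time agreement
#'
#' Per-horse differences (plasma DT minus urine DT), their percentile
#' distribution and Bland-Altman limits of agreement
#' (mean difference +/- 1.96 SD).
#'
#' @param plasma_dts,urine_dts numeric vectors paired by horse.
#' @return list with \code{differences}, \code{quantiles},
#'   \code{mean_diff}, \code{loa} (lower/upper) and \code{means} (pair
#'   averages for a Bland-Altman plot).
#' @export
dt_agreement <- function(plasma_dts, urine_dts) {
  if (length(plasma_dts) != length(urine_dts))
    stop("plasma and urine DT vectors must be paired by horse", call. = FALSE)
  d <- plasma_dts - urine_dts
  md <- mean(d); s <- stats::sd(d)
  if (is.na(s)) s <- 0
  list(differences = d,
       quantiles = stats::quantile(d, .DT_QUANTILES, type = 7),
       mean_diff = md,
       loa = c(lower = md - 1.96 * s, upper = md + 1.96 * s),
       means = (plasma_dts + urine_dts) / 2)
}
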