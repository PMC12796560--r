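#' Effective plasma concentration (EPC)
#'
#' The Toutain approach defines the EPC as the average plasma
#' concentration sustaining the daily therapeutic dose rate:
#' EPC = dose per 24 h / clearance per 24 h.
#'
#' @param pop a \code{\link{population_params}} object (its typical
#'   clearance is used), or a single clearance value in mL/kg/h.
#' @param dose_per_24h daily dose in ng/kg (1.1 mg/kg = 1.1e6 ng/kg).
#' @return EPC in ng/mL.
#' @examples
#' compute_epc(flunixin_prior(), 1.1e6)  # ~967.8 ng/mL
#' @export
compute_epc <- function(pop, dose_per_24h) {
  cl <- if (inherits(pop, "population_params")) pop$theta[["Cl"]] else pop
  if (dose_per_24h < 0) stop("dose must be non-negative", call. = FALSE)
  dose_per_24h / (cl * 24)
}

#' Irrelevant plasma concentration (IPC)
#'
#' EPC divided by the uncertainty factor (500 by convention).
#'
#' @param epc effective plasma concentration, ng/mL.
#' @param uncertainty_factor positive divisor.
#' @return IPC in ng/mL.
#' @export
compute_ipc <- function(epc, uncertainty_factor = 500) {
  if (uncertainty_factor <= 0)
    stop("uncertainty factor must be positive", call. = FALSE)
  epc / uncertainty_factor
}

#' Irrelevant urine concentration (IUC)
#'
#' IPC multiplied by the typical pseudo-equilibrium urine-to-plasma
#' ratio.
#'
#' @param ipc irrelevant plasma concentration, ng/mL.
#' @param tvRss typical urine-to-plasma ratio.
#' @return IUC in ng/mL.
#' @export
compute_iuc <- function(ipc, tvRss) {
  if (ipc <= 0 || tvRss <= 0) stop("ipc and tvRss must be positive", call. = FALSE)
  ipc * tvRss
}

#' Full regulatory-limit chain
#'
#' Runs EPC -> IPC -> IUC for a daily dose and population model, and
#' proposes integer-rounded candidate screening limits (rounding is
#' applied only at the proposal step, never inside the chain).
#'
#' @param pop a \code{\link{population_params}} object.
#' @param dose_mg_kg_per_24h daily dose in mg/kg.
#' @param uncertainty_factor divisor applied to the EPC.
#' @return object of class \code{"regulatory_limits"}: EPC, IPC, IUC
#'   (ng/mL), the inputs used, and candidate SLs (\code{candidate_plasma_SL},
#'   \code{candidate_urine_SL}).
#' @export
regulatory_limits <- function(pop, dose_mg_kg_per_24h = 1.1,
                              uncertainty_factor = 500) {
  dose <- dose_mg_kg_per_24h * 1e6
  epc <- compute_epc(pop, dose)
  ipc <- compute_ipc(epc, uncertainty_factor)
  iuc <- compute_iuc(ipc, pop$theta[["Rss"]])
  structure(list(EPC = epc, IPC = ipc, IUC = iuc,
                 uncertainty_factor = uncertainty_factor,
                 dose_per_24h = dose,
                 clearance_per_24h = pop$theta[["Cl"]] * 24,
                 tvRss = pop$theta[["Rss"]],
                 candidate_plasma_SL = round(ipc),
                 candidate_urine_SL = round(iuc)),
            class = "regulatory_limits")
}

#' @export
print.regulatory_limits <- function(x, ...) {
  cat(sprintf("EPC %.1f ng/mL (dose %.3g ng/kg/24h, Cl %.4g mL/kg/24h)\n",
              x$EPC, x$dose_per_24h, x$clearance_per_24h))
  cat(sprintf("IPC %.2f ng/mL (uncertainty factor %g)\n",
              x$IPC, x$uncertainty_factor))
  cat(sprintf("IUC %.1f ng/mL (tvRss %.4g)\n", x$IUC, x$tvRss))
  cat(sprintf("candidate SLs: plasma %g, urine %g ng/mL\n",
              x$candidate_plasma_SL, x$candidate_urine_SL))
  invisible(x)
}
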