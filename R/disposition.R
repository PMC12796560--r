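#' Structural disposition parameters for one horse
#'
#' Builds the parameter set of the mammillary three-compartment
#' intravenous-bolus model used throughout the package: a central
#' compartment (volume \code{V1}) exchanging with a superficial
#' (\code{V2}, clearance \code{Cl2}) and a deep (\code{V3}, \code{Cl3})
#' peripheral compartment, elimination by plasma clearance \code{Cl}, and
#' a urine channel proportional to plasma through the pseudo-equilibrium
#' urine-to-plasma ratio \code{Rss}.
#'
#' @param V1,V2,V3 compartment volumes (mL/kg); \code{V1} central,
#'   \code{V2} superficial peripheral, \code{V3} deep peripheral.
#' @param Cl plasma clearance (mL/kg/h), strictly positive.
#' @param Cl2,Cl3 intercompartmental clearances (mL/kg/h), non-negative;
#'   a zero value collapses the corresponding peripheral compartment
#'   analytically.
#' @param Rss pseudo-equilibrium urine-to-plasma concentration ratio
#'   (dimensionless), strictly positive.
#' @return An object of class \code{"disposition_params"}.
#' @examples
#' p <- disposition_params(V1 = 121, V2 = 8.9, V3 = 31.68,
#'                         Cl = 47.36, Cl2 = 0.22, Cl3 = 7.54, Rss = 35.93)
#' secondary_parameters(p)
#' @export
disposition_params <- function(V1, V2, V3, Cl, Cl2, Cl3, Rss) {
  x <- c(V1 = V1, V2 = V2, V3 = V3, Cl = Cl, Cl2 = Cl2, Cl3 = Cl3, Rss = Rss)
  if (any(!is.finite(x)))
    stop("disposition parameters must be finite", call. = FALSE)
  if (V1 <= 0 || Cl <= 0 || Rss <= 0)
    stop("V1, Cl and Rss must be strictly positive", call. = FALSE)
  if (Cl2 < 0 || Cl3 < 0)
    stop("Cl2 and Cl3 must be non-negative", call. = FALSE)
  if ((Cl2 > 0 && V2 <= 0) || (Cl3 > 0 && V3 <= 0))
    stop("a peripheral volume must be positive when its clearance is", call. = FALSE)
  structure(as.list(x), class = "disposition_params")
}

#' @export
print.disposition_params <- function(x, ...) {
  cat("Three-compartment disposition parameters (per kg):\n")
  v <- unlist(x)
  cat(sprintf("  %-4s %10.4g  %s\n", names(v), v,
              c("mL/kg", "mL/kg", "mL/kg", "mL/kg/h", "mL/kg/h", "mL/kg/h", "")))
  invisible(x)
}

#' Intravenous bolus dosing regimen
#'
#' Doses are stored internally in ng/kg.  Fixed total doses (mg per
#' horse) are converted through the horse's body weight.
#'
#' @param dose_mg_kg dose in mg/kg, or \code{NULL} when \code{dose_mg} is
#'   given.
#' @param dose_mg fixed dose in mg per horse (requires \code{bw_kg}).
#' @param bw_kg body weight (kg), used only with \code{dose_mg}.
#' @param n_doses number of IV bolus administrations (>= 1).
#' @param interval dosing interval tau in hours (q24h by default).
#' @return An object of class \code{"dosing_regimen"} with elements
#'   \code{dose} (ng/kg per administration) and \code{times} (h, first
#'   dose at 0).
#' @export
dosing_regimen <- function(dose_mg_kg = NULL, dose_mg = NULL, bw_kg = NULL,
                           n_doses = 1L, interval = 24) {
  if (is.null(dose_mg_kg) && is.null(dose_mg))
    stop("give either dose_mg_kg or dose_mg", call. = FALSE)
  if (!is.null(dose_mg)) {
    if (is.null(bw_kg) || bw_kg <= 0)
      stop("dose_mg requires a positive bw_kg", call. = FALSE)
    dose_mg_kg <- dose_mg / bw_kg
  }
  if (dose_mg_kg <= 0) stop("dose must be positive", call. = FALSE)
  n_doses <- as.integer(n_doses)
  if (n_doses < 1L) stop("n_doses must be >= 1", call. = FALSE)
  if (n_doses > 1L && interval <= 0)
    stop("interval must be positive for multiple dosing", call. = FALSE)
  structure(list(dose = dose_mg_kg * 1e6,
                 times = (seq_len(n_doses) - 1) * interval,
                 interval = interval),
            class = "dosing_regimen")
}

#' @export
print.dosing_regimen <- function(x, ...) {
  cat(sprintf("IV bolus regimen: %.4g ng/kg x %d dose(s)", x$dose,
              length(x$times)))
  if (length(x$times) > 1L) cat(sprintf(" q%gh", x$interval))
  cat("\n")
  invisible(x)
}

# micro-constants of the mammillary model
.micro_k <- function(p) {
  list(k10 = p$Cl / p$V1,
       k12 = p$Cl2 / p$V1,
       k21 = if (p$Cl2 > 0) p$Cl2 / p$V2 else 0,
       k13 = p$Cl3 / p$V1,
       k31 = if (p$Cl3 > 0) p$Cl3 / p$V3 else 0)
}

#' Macro-constants of the tri-exponential bolus solution
#'
#' Converts the clearance/volume parameterization into the exponential
#' rate constants (roots of the characteristic cubic) and bolus
#' coefficients of \eqn{C(t) = A e^{-\alpha t} + B e^{-\beta t} + C
#' e^{-\gamma t}}.  When \code{Cl2} and/or \code{Cl3} is zero the model
#' collapses analytically to the bi-/mono-exponential solution (the
#' corresponding terms are dropped rather than perturbed).
#'
#' @param params a \code{\link{disposition_params}} object.
#' @param dose bolus dose (ng/kg); coefficients scale linearly with it.
#' @return A list of class \code{"macro_disposition"} with \code{lambda}
#'   (rates, 1/h, sorted decreasing: alpha, beta, gamma) and \code{coef}
#'   (ng/mL, same order), satisfying \code{sum(coef) == dose/V1}.
#' @export
micro_to_macro <- function(params, dose = 1e6) {
  stopifnot(inherits(params, "disposition_params"))
  if (dose <= 0) stop("dose must be positive", call. = FALSE)
  k <- .micro_k(params)
  C0 <- dose / params$V1
  two <- params$Cl2 > 0
  three <- params$Cl3 > 0
  if (two && three) {
    E1 <- k$k10 + k$k12 + k$k13; E2 <- k$k21; E3 <- k$k31
    b2 <- E1 + E2 + E3
    b1 <- E1 * E2 + E1 * E3 + E2 * E3 - k$k12 * k$k21 - k$k13 * k$k31
    b0 <- E1 * E2 * E3 - k$k12 * k$k21 * E3 - k$k13 * k$k31 * E2
    rt <- polyroot(c(-b0, b1, -b2, 1))
    if (max(abs(Im(rt))) > 1e-8 * max(abs(Re(rt))))
      stop("characteristic cubic has complex roots for this parameter set",
           call. = FALSE)
    lam <- sort(Re(rt), decreasing = TRUE)
    if (any(lam <= 0))
      stop("non-positive disposition rate constant; parameter set: ",
           paste(sprintf("%s=%g", names(params), unlist(params)), collapse = ", "),
           call. = FALSE)
    co <- vapply(1:3, function(i)
      C0 * (E2 - lam[i]) * (E3 - lam[i]) / prod(lam[-i] - lam[i]), 0)
  } else if (two || three) {
    # one peripheral compartment active -> two-compartment solution
    kp <- if (two) k$k12 else k$k13
    km <- if (two) k$k21 else k$k31
    s <- k$k10 + kp + km
    d <- sqrt(s^2 - 4 * k$k10 * km)
    lam <- c((s + d) / 2, (s - d) / 2)
    co <- c(C0 * (lam[1] - km) / (lam[1] - lam[2]),
            C0 * (km - lam[2]) / (lam[1] - lam[2]))
  } else {
    lam <- k$k10
    co <- C0
  }
  structure(list(lambda = lam, coef = co, dose = dose), class = "macro_disposition")
}

# vectorized single-bolus curve (t may be any numeric vector; 0 before dose)
.bolus_conc <- function(macro, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  if (any(pos)) {
    tt <- t[pos]
    out[pos] <- colSums(macro$coef * exp(-outer(macro$lambda, tt)))
  }
  out
}

#' Plasma concentration under an IV bolus regimen
#'
#' Closed-form tri-exponential disposition with superposition over all
#' administrations at or before \code{t}.
#'
#' @param params a \code{\link{disposition_params}} object.
#' @param regimen a \code{\link{dosing_regimen}} object.
#' @param t time(s) since the first dose (h), vectorized.
#' @return plasma concentration(s), ng/mL; 0 before the first dose.
#' @export
plasma_concentration <- function(params, regimen, t) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  macro <- micro_to_macro(params, regimen$dose)
  out <- numeric(length(t))
  for (td in regimen$times) out <- out + .bolus_conc(macro, t - td)
  out
}

#' Urine concentration under the pseudo-equilibrium model
#'
#' Urine concentration is modelled as proportional to plasma through the
#' individual's \code{Rss}.  The proportionality only holds once
#' pseudo-distribution equilibrium is reached; values earlier than 24 h
#' after the first dose carry \code{valid = FALSE} and are ignored by the
#' fitting and detection-time machinery.
#'
#' @inheritParams plasma_concentration
#' @return numeric vector of urine concentrations (ng/mL) with attribute
#'   \code{valid} (logical, FALSE for t < 24 h after the first dose).
#' @export
urine_concentration <- function(params, regimen, t) {
  conc <- params$Rss * plasma_concentration(params, regimen, t)
  attr(conc, "valid") <- t >= regimen$times[1] + 24
  conc
}

#' Secondary disposition parameters
#'
#' Half-lives of the three disposition phases, steady-state volume of
#' distribution and mean residence time.
#'
#' @param params a \code{\link{disposition_params}} object.
#' @return list with \code{t_half} (named alpha/beta/gamma, h; absent
#'   phases dropped for collapsed models), \code{Vss} (mL/kg) and
#'   \code{MRT} (h).
#' @export
secondary_parameters <- function(params) {
  macro <- micro_to_macro(params, 1e6)
  th <- log(2) / macro$lambda
  names(th) <- c("alpha", "beta", "gamma")[seq_along(th)]
  Vss <- params$V1 +
    (if (params$Cl2 > 0) params$V2 else 0) +
    (if (params$Cl3 > 0) params$V3 else 0)
  list(t_half = th, Vss = Vss, MRT = Vss / params$Cl)
}
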