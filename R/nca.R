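#' Noncompartmental analysis for initial estimates
#'
#' Per-horse linear-trapezoidal AUC/AUMC on the plasma observations,
#' terminal slope by log-linear regression on the last \code{n_terminal}
#' (or more) points, and the derived clearance, steady-state volume and
#' mean residence time.  Multiple-dose horses are analyzed on the decline
#' after the last administration (one dosing interval's dose).
#'
#' @param data a \code{"pk_dataset"}.
#' @param n_terminal number of terminal points for the slope (>= 3).
#' @return data.frame of class \code{"nca_result"}: per horse
#'   \code{AUC_last}, \code{AUC_inf} (ng h/mL), \code{lambda_z} (1/h,
#'   \code{NA} with \code{lambda_z_flag} when fewer than 3 usable
#'   terminal points), \code{Cl_obs} (mL/kg/h), \code{Vss_obs} (mL/kg),
#'   \code{MRT_obs} (h).
#' @export
nca_initial_estimates <- function(data, n_terminal = 3L) {
  horses <- .prep_horses(data)
  rows <- lapply(horses, function(h) {
    tl <- h$regimen$times[length(h$regimen$times)]
    sel <- h$matrix == "plasma" & h$time >= tl
    tt <- h$time[sel] - tl; cc <- h$dv[sel]
    o <- order(tt); tt <- tt[o]; cc <- cc[o]
    out <- data.frame(ID = h$id, AUC_last = NA_real_, AUC_inf = NA_real_,
                      lambda_z = NA_real_, lambda_z_flag = "",
                      Cl_obs = NA_real_, Vss_obs = NA_real_, MRT_obs = NA_real_)
    if (length(tt) < 2L) { out$lambda_z_flag <- "insufficient data"; return(out) }
    n_obs_pos <- sum(cc > 0)
    # IV bolus: back-extrapolate log-linearly to t = 0 from the first two
    # positive observations so the AUC includes the initial segment
    if (tt[1L] > 0 && all(cc[1:2] > 0) && cc[1L] > cc[2L]) {
      c0 <- exp(log(cc[1L]) + (log(cc[2L]) - log(cc[1L])) /
                  (tt[2L] - tt[1L]) * (0 - tt[1L]))
      tt <- c(0, tt); cc <- c(c0, cc)
    }
    dt <- diff(tt)
    auc <- sum(dt * (cc[-1] + cc[-length(cc)]) / 2)
    aumc <- sum(dt * (tt[-1] * cc[-1] + tt[-length(tt)] * cc[-length(cc)]) / 2)
    pos <- cc > 0
    # the terminal slope uses observed points only, never the extrapolation
    if (n_obs_pos < 3L) {
      out$AUC_last <- auc
      out$lambda_z_flag <- "fewer than 3 positive terminal points"
      return(out)
    }
    idx <- utils::tail(which(pos), min(max(n_terminal, 3L), n_obs_pos))
    fitl <- stats::lm(log(cc[idx]) ~ tt[idx])
    lz <- -stats::coef(fitl)[[2L]]
    if (!is.finite(lz) || lz <= 0) {
      out$AUC_last <- auc
      out$lambda_z_flag <- "non-positive terminal slope"
      return(out)
    }
    clast <- cc[length(cc)]; tlast_obs <- tt[length(tt)]
    auc_inf <- auc + clast / lz
    aumc_inf <- aumc + clast * tlast_obs / lz + clast / lz^2
    dose <- h$regimen$dose
    cl <- dose / auc_inf
    mrt <- aumc_inf / auc_inf
    out$AUC_last <- auc; out$AUC_inf <- auc_inf; out$lambda_z <- lz
    out$Cl_obs <- cl; out$MRT_obs <- mrt; out$Vss_obs <- cl * mrt
    out
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("nca_result", "data.frame")
  out
}

#' Build starting population values from an NCA pass
#'
#' Typical clearance and steady-state volume come from the NCA medians;
#' the volume is split over the compartments and the intercompartmental
#' clearances and Rss start at field-plausible fractions.  Residual
#' sigmas start at 20\% proportional + the median LOQ additive.
#'
#' @param nca result of \code{\link{nca_initial_estimates}}.
#' @param data the dataset (used for urine/plasma ratio and LOQs).
#' @return a \code{\link{population_params}} object usable as
#'   \code{init} for \code{\link{fit_population}}.
#' @export
init_from_nca <- function(nca, data) {
  cl <- stats::median(nca$Cl_obs, na.rm = TRUE)
  vss <- stats::median(nca$Vss_obs, na.rm = TRUE)
  if (!is.finite(cl) || !is.finite(vss))
    stop("NCA produced no usable clearance/volume estimates", call. = FALSE)
  obs <- data[data$EVID == 0 & !is.na(data$DV), ]
  # crude Rss start: ratio of urine to plasma geometric means beyond 24 h
  late <- obs$TIME >= 24 & obs$DV > 0
  gm <- function(x) exp(mean(log(x)))
  rss <- if (any(late & obs$MATRIX == "urine") && any(late & obs$MATRIX == "plasma"))
    gm(obs$DV[late & obs$MATRIX == "urine"]) / gm(obs$DV[late & obs$MATRIX == "plasma"])
  else 30
  theta <- c(V1 = 0.75 * vss, V2 = 0.05 * vss, V3 = 0.20 * vss,
             Cl = cl, Cl2 = 0.005 * cl, Cl3 = 0.15 * cl,
             Rss = max(rss, 1))
  loq <- stats::median(obs$LOQ, na.rm = TRUE)
  population_params(theta, diag(0.1, 7),
                    c(plasma_prop = 0.2, plasma_add = max(loq, 0.05),
                      urine_prop = 0.3, urine_add = max(loq, 0.05)))
}
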