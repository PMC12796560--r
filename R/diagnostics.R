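#' Goodness-of-fit diagnostics for a population fit
#'
#' Computes per-observation population predictions (PRED, eta = 0),
#' individual predictions (IPRED, posterior-mode eta), conditional
#' weighted residuals (first-order conditional linearization of the
#' model around the EBE, standardized by the marginal variance
#' \eqn{F \Omega F' + \Sigma}), per-parameter shrinkage
#' (\eqn{1 - SD(\hat\eta)/\omega}) and CV\%, and a visual-predictive-check
#' table of simulated 10/50/90 percentile bands against the observed
#' percentiles, binned by matrix and time after last dose.
#'
#' @param fit a \code{\link{fit_population}} fit (or a fit-shaped list
#'   built at known parameters for simulation studies).
#' @param data the dataset the fit used.
#' @param n_vpc number of simulated replicates for the VPC (0 skips it).
#' @return list of class \code{"fit_diagnostics"}: \code{table}
#'   (per-observation), \code{shrinkage}, \code{cv_percent}, \code{vpc}.
#' @export
diagnostics <- function(fit, data, n_vpc = 500L) {
  horses <- fit$horses
  if (is.null(horses)) horses <- .prep_horses(data)
  model <- fit$model
  pn <- names(fit$theta)
  omega <- fit$omega
  rows <- list()
  for (i in seq_along(horses)) {
    h <- horses[[i]]
    if (!length(h$dv)) next
    eta_i <- fit$ebe[i, ]
    pred <- .pred_horse(h, fit$theta, 0 * eta_i, model)
    ipred <- .pred_horse(h, fit$theta, eta_i, model)
    # FOCE linearization: F = d f / d eta at the EBE
    d <- length(eta_i); Fm <- matrix(0, length(ipred), d)
    hstep <- 1e-4
    for (j in seq_len(d)) {
      ej <- replace(numeric(d), j, hstep)
      Fm[, j] <- (.pred_horse(h, fit$theta, eta_i + ej, model) -
                    .pred_horse(h, fit$theta, eta_i - ej, model)) / (2 * hstep)
    }
    v <- .residual_var(ipred, h$matrix, fit$sigma)
    cov <- Fm %*% omega %*% t(Fm) + diag(v, length(v))
    cpred <- ipred - drop(Fm %*% eta_i)
    cwres <- (h$dv - cpred) / sqrt(diag(cov))
    tl <- h$regimen$times[length(h$regimen$times)]
    rows[[length(rows) + 1L]] <-
      data.frame(ID = h$id, TIME = h$time, TAD = h$time - tl,
                 MATRIX = h$matrix, DV = h$dv,
                 PRED = pred, IPRED = ipred, CWRES = cwres)
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  shr <- 1 - apply(fit$ebe, 2, stats::sd) / sqrt(pmax(diag(omega), 1e-12))
  vpc <- if (n_vpc > 0L) .vpc_table(fit, horses, n_vpc) else NULL
  structure(list(table = tab, shrinkage = shr,
                 cv_percent = cv_percent(diag(omega)), vpc = vpc),
            class = "fit_diagnostics")
}

# simulate replicate datasets at the observation design and summarize
# 10/50/90 percentile bands per matrix x time-after-dose bin
.vpc_table <- function(fit, horses, n_rep) {
  pn <- names(fit$theta)
  design <- do.call(rbind, lapply(horses, function(h) {
    if (!length(h$dv)) return(NULL)
    tl <- h$regimen$times[length(h$regimen$times)]
    data.frame(id = h$id, tad = round(h$time - tl, 3), matrix = h$matrix,
               dv = h$dv)
  }))
  sims <- matrix(NA_real_, nrow(design), n_rep)
  row0 <- 0L
  per_h <- vapply(horses, function(h) length(h$dv), 0L)
  for (r in seq_len(n_rep)) {
    row0 <- 0L
    eta_r <- draw_eta(fit$omega, length(horses))
    for (i in seq_along(horses)) {
      h <- horses[[i]]
      if (!length(h$dv)) next
      f <- .pred_horse(h, fit$theta, eta_r[i, ], fit$model)
      v <- .residual_var(f, h$matrix, fit$sigma)
      sims[row0 + seq_along(f), r] <- pmax(f * (1 + stats::rnorm(length(f), 0,
        ifelse(h$matrix == "plasma", fit$sigma[["plasma_prop"]],
               fit$sigma[["urine_prop"]]))) +
        stats::rnorm(length(f), 0,
        ifelse(h$matrix == "plasma", fit$sigma[["plasma_add"]],
               fit$sigma[["urine_add"]])), 0)
      row0 <- row0 + length(f)
    }
  }
  key <- interaction(design$matrix, design$tad, drop = TRUE)
  out <- lapply(levels(key), function(kk) {
    sel <- key == kk
    qs <- stats::quantile(sims[sel, ], c(0.1, 0.5, 0.9), na.rm = TRUE)
    qo <- stats::quantile(design$dv[sel], c(0.1, 0.5, 0.9))
    data.frame(matrix = design$matrix[sel][1L], tad = design$tad[sel][1L],
               n = sum(sel),
               sim_p10 = qs[[1L]], sim_p50 = qs[[2L]], sim_p90 = qs[[3L]],
               obs_p10 = qo[[1L]], obs_p50 = qo[[2L]], obs_p90 = qo[[3L]])
  })
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  out[order(out$matrix, out$tad), ]
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("Diagnostics on %d observations\n", nrow(x$table)))
  cat(sprintf("  CWRES mean %.3f sd %.3f\n", mean(x$table$CWRES),
              stats::sd(x$table$CWRES)))
  cat("  shrinkage:\n"); print(round(x$shrinkage, 3))
  cat("  BSV CV%:\n"); print(round(x$cv_percent, 1))
  if (!is.null(x$vpc)) {
    inside <- with(merge(x$table, x$vpc,
                         by.x = c("MATRIX", "TAD"), by.y = c("matrix", "tad")),
                   mean(DV >= sim_p10 & DV <= sim_p90))
    cat(sprintf("  VPC: %.1f%% of observations inside the simulated 10-90 band\n",
                100 * inside))
  }
  invisible(x)
}
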