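.PARAM_NAMES <- c("V1", "V2", "V3", "Cl", "Cl2", "Cl3", "Rss")

#' Population parameter set (prior)
#'
#' Typical values, between-subject covariance and residual-error
#' magnitudes of the joint plasma-urine population model.  Random effects
#' are log-scale: individual parameter \eqn{i} is
#' \eqn{\theta_i \exp(\eta_i)} with \eqn{\eta \sim N(0, \Omega)}.
#' Residual error is combined proportional + additive per matrix:
#' observed = pred(1 + e1) + e2.
#'
#' @param theta named numeric vector of typical values for
#'   V1, V2, V3, Cl, Cl2, Cl3, Rss (units as
#'   \code{\link{disposition_params}}).
#' @param omega 7x7 symmetric covariance matrix of the log-scale random
#'   effects (same parameter order).  Projected to the nearest positive
#'   semidefinite matrix (eigenvalue clipping) with a warning if needed.
#' @param sigma named numeric vector with elements
#'   \code{plasma_prop}, \code{plasma_add}, \code{urine_prop},
#'   \code{urine_add} (proportional terms dimensionless, additive ng/mL).
#' @return An object of class \code{"population_params"}.
#' @seealso \code{\link{flunixin_prior}} for the packaged flunixin values.
#' @export
population_params <- function(theta, omega, sigma) {
  theta <- theta[.PARAM_NAMES]
  if (any(is.na(theta)) || any(theta <= 0))
    stop("theta must contain positive values named ",
         paste(.PARAM_NAMES, collapse = ", "), call. = FALSE)
  omega <- as.matrix(omega)
  if (!isTRUE(all.equal(dim(omega), c(7L, 7L))))
    stop("omega must be 7x7", call. = FALSE)
  if (!is.null(rownames(omega))) omega <- omega[.PARAM_NAMES, .PARAM_NAMES]
  if (max(abs(omega - t(omega))) > 1e-8)
    stop("omega must be symmetric", call. = FALSE)
  omega <- (omega + t(omega)) / 2
  omega <- .nearest_psd(omega)
  dimnames(omega) <- list(.PARAM_NAMES, .PARAM_NAMES)
  sg <- c("plasma_prop", "plasma_add", "urine_prop", "urine_add")
  sigma <- sigma[sg]
  if (any(is.na(sigma)) || any(sigma < 0))
    stop("sigma must contain non-negative values named ",
         paste(sg, collapse = ", "), call. = FALSE)
  structure(list(theta = theta, omega = omega, sigma = sigma),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population parameters (log-normal BSV):\n  theta:\n")
  print(round(x$theta, 4))
  cat(sprintf("  BSV CV%%: %s\n",
              paste(sprintf("%s=%.1f", .PARAM_NAMES,
                            cv_percent(diag(x$omega))), collapse = " ")))
  cat("  residual sigma:\n")
  print(round(x$sigma, 4))
  invisible(x)
}

# eigenvalue clipping to the nearest PSD matrix
.nearest_psd <- function(m, warn = TRUE) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < -1e-10) {
    if (warn) warning("covariance matrix not positive semidefinite; ",
                      "clipping negative eigenvalues at 0", call. = FALSE)
    v <- pmax(e$values, 0)
    m <- e$vectors %*% (v * t(e$vectors))
    m <- (m + t(m)) / 2
  }
  m
}

#' Packaged population prior for flunixin in horses
#'
#' Published bootstrap typical values, full between-subject covariance
#' matrix and residual error magnitudes from an international
#' meta-analysis of flunixin disposition in 65 horses (plasma and urine
#' analyzed jointly with a three-compartment model).  Shipped as a
#' versioned JSON file under \code{inst/extdata}.
#'
#' @return A \code{\link{population_params}} object.
#' @examples
#' pop <- flunixin_prior()
#' round(cv_percent(diag(pop$omega)["Cl"]), 1)  # 29.8% BSV on clearance
#' @export
flunixin_prior <- function() {
  read_prior(system.file("extdata", "flunixin_prior.json", package = "popkdt",
                         mustWork = TRUE))
}

#' Convert log-scale variances to coefficients of variation
#'
#' For a log-normal random effect with variance \eqn{\omega^2},
#' CV\% \eqn{= 100\sqrt{\exp(\omega^2) - 1}}.
#'
#' @param omega2 numeric vector of variances (log scale).
#' @return CV in percent.
#' @examples
#' cv_percent(0.085)  # 29.8
#' @export
cv_percent <- function(omega2) 100 * sqrt(exp(omega2) - 1)

#' Draw individual disposition parameters from the population
#'
#' Samples \eqn{\eta \sim N(0, \Omega)} via the Cholesky (or eigen, for
#' semidefinite \eqn{\Omega}) factor and applies
#' \eqn{\theta_i = \theta_{tv} e^{\eta_i}}.
#'
#' @param pop a \code{\link{population_params}} object.
#' @param n number of horses to draw.
#' @param seed optional integer; when given, sets the RNG seed so the
#'   draw is reproducible.
#' @return For \code{n = 1} a \code{\link{disposition_params}} object;
#'   otherwise a list of them.  The eta matrix is attached as attribute
#'   \code{"eta"} (n x 7).
#' @export
sample_individual <- function(pop, n = 1L, seed = NULL) {
  stopifnot(inherits(pop, "population_params"))
  if (!is.null(seed)) set.seed(seed)
  eta <- draw_eta(pop$omega, n)
  pars <- lapply(seq_len(n), function(i) {
    v <- pop$theta * exp(eta[i, ])
    do.call(disposition_params, as.list(v))
  })
  out <- if (n == 1L) pars[[1L]] else pars
  attr(out, "eta") <- eta
  out
}

# n x 7 matrix of MVN(0, omega) draws; tolerates semidefinite omega
draw_eta <- function(omega, n) {
  d <- nrow(omega)
  L <- tryCatch(t(chol(omega)), error = function(e) {
    e <- eigen(omega, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), d)
  })
  eta <- t(L %*% matrix(stats::rnorm(d * n), d))
  colnames(eta) <- colnames(omega)
  eta
}

#' Apply the combined residual-error model
#'
#' observed = pred (1 + e1) + e2 with e1 ~ N(0, sigma_prop^2) and
#' e2 ~ N(0, sigma_add^2), using the matrix-specific sigmas.  Negative
#' results are clamped at 0 (a message reports how many).
#'
#' @param pred noise-free model prediction(s), ng/mL.
#' @param matrix \code{"plasma"} or \code{"urine"}.
#' @param pop a \code{\link{population_params}} object.
#' @param seed optional RNG seed.
#' @return observed concentration(s), ng/mL.
#' @export
apply_residual_error <- function(pred, matrix = c("plasma", "urine"), pop,
                                 seed = NULL) {
  matrix <- match.arg(matrix)
  if (any(pred < 0)) stop("pred must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sp <- pop$sigma[[paste0(matrix, "_prop")]]
  sa <- pop$sigma[[paste0(matrix, "_add")]]
  n <- length(pred)
  obs <- pred * (1 + stats::rnorm(n, 0, sp)) + stats::rnorm(n, 0, sa)
  neg <- obs < 0
  if (any(neg)) {
    message(sum(neg), " negative simulated concentration(s) clamped to 0")
    obs[neg] <- 0
  }
  obs
}

# per-observation residual variance under the combined error model,
# evaluated at the (individual) prediction
.residual_var <- function(pred, matrix, sigma) {
  sp <- ifelse(matrix == "plasma", sigma[["plasma_prop"]], sigma[["urine_prop"]])
  sa <- ifelse(matrix == "plasma", sigma[["plasma_add"]], sigma[["urine_add"]])
  pmax((sp * pred)^2 + sa^2, 1e-12)   # floor keeps noise-free data finite
}
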