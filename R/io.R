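.DATASET_COLS <- c("ID", "TIME", "EVID", "AMT", "DV", "MATRIX", "LOQ")
.COVARIATE_COLS <- c("AGE", "BW", "SEX", "BREED", "COUNTRY")

#' Read a longitudinal concentration dataset
#'
#' The canonical dataset is a NONMEM-style CSV with one row per event:
#' dose rows (\code{EVID = 1}) carry \code{AMT} in ng/kg; observation
#' rows (\code{EVID = 0}) carry \code{DV} (ng/mL), \code{MATRIX}
#' (\code{plasma}/\code{urine}) and \code{LOQ} (ng/mL).  Covariate
#' columns \code{AGE, BW, SEX, BREED, COUNTRY} and the bookkeeping
#' columns \code{ARM} and \code{BLOQ} are carried through when present.
#'
#' @param path path to a CSV file.
#' @return a data.frame of class \code{"pk_dataset"}.
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  missing <- setdiff(.DATASET_COLS, names(d))
  if (length(missing))
    stop("dataset is missing mandatory column(s): ",
         paste(missing, collapse = ", "),
         "; expected at least ", paste(.DATASET_COLS, collapse = ", "),
         call. = FALSE)
  validate_dataset(d)
}

#' @rdname read_dataset
#' @param data a dataset (as from \code{\link{generate_cohort}}).
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

# shared validation; also used on synthetic datasets
validate_dataset <- function(d) {
  bad <- which(!is.na(d$TIME) & d$TIME < 0)
  if (length(bad))
    stop("negative TIME in row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  obs <- d$EVID == 0
  bad <- which(obs & !is.na(d$DV) & d$DV < 0)
  if (length(bad))
    stop("negative DV in row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  dosedv <- which(d$EVID == 1 & !is.na(d$DV) & d$DV != 0)
  if (length(dosedv)) {
    warning("DV present on dose row(s) ",
            paste(utils::head(dosedv, 5), collapse = ", "),
            "; ignored", call. = FALSE)
    d$DV[dosedv] <- NA_real_
  }
  if (any(obs & (is.na(d$MATRIX) | !d$MATRIX %in% c("plasma", "urine"))))
    stop("every observation row needs MATRIX 'plasma' or 'urine'", call. = FALSE)
  if (any(obs & is.na(d$LOQ)))
    stop("every observation row needs an LOQ", call. = FALSE)
  for (id in unique(d$ID))
    if (!any(d$EVID == 1 & d$ID == id))
      stop("horse ", id, " has no dose row", call. = FALSE)
  if (is.null(d$BLOQ)) d$BLOQ <- ifelse(obs, d$DV < d$LOQ, NA)
  class(d) <- c("pk_dataset", "data.frame")
  d
}

#' Read / write a population prior (JSON)
#'
#' The JSON stores theta as a named object, omega as a matrix in any
#' stated parameter order (\code{omega_order}) and the residual sigmas.
#'
#' @param path path to a JSON file.
#' @return a \code{\link{population_params}} object.
#' @export
read_prior <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- unlist(j$theta)
  omega <- as.matrix(j$omega)
  ord <- j$omega_order
  if (!is.null(ord)) dimnames(omega) <- list(ord, ord)
  population_params(theta, omega, unlist(j$sigma))
}

#' @rdname read_prior
#' @param pop a \code{\link{population_params}} object.
#' @param version version string recorded in the file.
#' @export
write_prior <- function(pop, path, version = "1.0") {
  j <- list(version = version,
            theta = as.list(pop$theta),
            omega_order = .PARAM_NAMES,
            omega = unname(pop$omega),
            sigma = as.list(pop$sigma))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Screening-limit scenario set
#'
#' Reads a JSON list of plasma/urine screening-limit pairs.  The default
#' is the packaged set: IFHA ISL (1/100 ng/mL), the candidate pairs
#' derived from the irrelevant concentrations (2/70 and 3/100), HISA
#' (4/100) and RMTC (5/100).
#'
#' @param path optional path to a JSON scenario file.
#' @return data.frame with columns \code{label}, \code{plasma_SL},
#'   \code{urine_SL} and \code{operational_Rss} (urine SL / plasma SL).
#' @export
screening_limits <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "screening_limits.json", package = "popkdt",
                        mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- as.data.frame(j$pairs)
  if (any(p$plasma_SL <= 0) || any(p$urine_SL <= 0))
    stop("screening limits must be positive", call. = FALSE)
  p$operational_Rss <- p$urine_SL / p$plasma_SL
  p
}
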