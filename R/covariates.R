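#' Stepwise covariate screening on the empirical Bayes estimates
#'
#' Screens demographic covariates against the per-horse random-effect
#' estimates of a base fit: each candidate parameter-covariate pair is a
#' linear model of the EBE eta (continuous covariates enter as
#' \code{log(cov/median)}, i.e. a power relation on the original scale;
#' categorical covariates as factor shifts).  Forward steps add the best
#' pair when it improves the BIC by more than \code{add_threshold}
#' (6.635, the chi-square critical value for p = 0.01 at 1 df); backward
#' steps delete any pair whose removal worsens the BIC by less than
#' \code{delete_threshold} (10.823, p = 0.001).  The final set is only
#' retained when the joint improvement over the covariate-free model
#' reaches \code{retain_threshold} (10.0).  Covariates whose levels nest
#' within the country of origin are reported as confounded.
#'
#' @param data the fitted dataset (for the covariate values).
#' @param base_fit a \code{\link{fit_population}} fit.
#' @param covariates covariate column names to screen.
#' @param add_threshold,delete_threshold,retain_threshold BIC decision
#'   thresholds.
#' @return list with \code{selected} (data.frame parameter/covariate),
#'   \code{trace} (every tested step with its BIC delta),
#'   \code{confounded} (character), \code{delta_BIC_vs_null}, and
#'   \code{retained} (logical).
#' @export
covariate_search <- function(data, base_fit,
                             covariates = intersect(.COVARIATE_COLS, names(data)),
                             add_threshold = 6.635, delete_threshold = 10.823,
                             retain_threshold = 10.0) {
  ids <- rownames(base_fit$ebe)
  cov_tab <- do.call(rbind, lapply(ids, function(id) {
    data[match(id, as.character(data$ID)), covariates, drop = FALSE]
  }))
  rownames(cov_tab) <- ids
  # design column for one covariate
  col_for <- function(cv) {
    x <- cov_tab[[cv]]
    if (is.numeric(x)) log(x / stats::median(x)) else factor(x)
  }
  usable <- covariates[vapply(covariates, function(cv) {
    x <- cov_tab[[cv]]
    if (is.numeric(x)) stats::sd(x) > 0 else length(unique(x)) > 1L
  }, TRUE)]
  confounded <- character(0)
  if ("COUNTRY" %in% names(cov_tab)) {
    for (cv in setdiff(usable, "COUNTRY")) {
      x <- cov_tab[[cv]]
      if (!is.numeric(x) &&
          all(rowSums(table(x, cov_tab$COUNTRY) > 0) == 1L))
        confounded <- c(confounded, cv)
    }
  }
  pn <- colnames(base_fit$ebe)
  pairs <- expand.grid(parameter = pn, covariate = usable,
                       stringsAsFactors = FALSE)
  bic_of <- function(param, with_covs) {
    y <- base_fit$ebe[, param]
    if (!length(with_covs)) return(stats::BIC(stats::lm(y ~ 1)))
    X <- data.frame(lapply(with_covs, col_for))
    names(X) <- with_covs
    stats::BIC(stats::lm(y ~ ., data = X))
  }
  selected <- list()   # parameter -> character vector of covariates
  trace <- list()
  note <- function(step, param, cv, delta, action)
    trace[[length(trace) + 1L]] <<-
      data.frame(step = step, parameter = param, covariate = cv,
                 delta_BIC = delta, action = action)
  step <- 0L
  repeat {
    step <- step + 1L
    # forward
    best <- NULL
    for (r in seq_len(nrow(pairs))) {
      param <- pairs$parameter[r]; cv <- pairs$covariate[r]
      cur <- selected[[param]]
      if (cv %in% cur) next
      delta <- bic_of(param, cur) - bic_of(param, c(cur, cv))
      note(step, param, cv, delta, "tested-add")
      if (delta > add_threshold && (is.null(best) || delta > best$delta))
        best <- list(param = param, cv = cv, delta = delta)
    }
    if (is.null(best)) break
    selected[[best$param]] <- c(selected[[best$param]], best$cv)
    note(step, best$param, best$cv, best$delta, "added")
  }
  # backward
  repeat {
    dropped <- FALSE
    for (param in names(selected)) for (cv in selected[[param]]) {
      cur <- selected[[param]]
      delta <- bic_of(param, setdiff(cur, cv)) - bic_of(param, cur)
      if (delta < delete_threshold) {
        selected[[param]] <- setdiff(cur, cv)
        note(step, param, cv, delta, "deleted")
        dropped <- TRUE
      }
    }
    if (!dropped) break
  }
  selected <- selected[lengths(selected) > 0L]
  dnull <- sum(vapply(names(selected), function(p)
    bic_of(p, character(0)) - bic_of(p, selected[[p]]), 0))
  retained <- length(selected) > 0L && dnull >= retain_threshold
  sel_df <- if (length(selected))
    do.call(rbind, lapply(names(selected), function(p)
      data.frame(parameter = p, covariate = selected[[p]])))
  else data.frame(parameter = character(0), covariate = character(0))
  list(selected = if (retained) sel_df else sel_df[0, ],
       candidates = sel_df, retained = retained,
       delta_BIC_vs_null = dnull,
       confounded = confounded,
       trace = do.call(rbind, c(trace, make.row.names = FALSE)))
}
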