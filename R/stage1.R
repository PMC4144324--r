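#' Remove time-varying covariate effects from the phenotype
#'
#' Fits one pooled least-squares regression of the phenotype on the named
#' covariates (with intercept) across all visit rows, and subtracts the
#' estimated covariate contributions, leaving intercept + residual (so a
#' value generated as 120 + 5*med is adjusted back to 120 for every row).
#' This mirrors pre-adjusting blood pressure for current smoking and
#' antihypertensive medication before fitting the age trajectories.
#'
#' @param pheno Long-format phenotype data frame with columns \code{id},
#'   \code{age}, a value column and the covariates.
#' @param covariates Character vector of covariate column names.
#' @param value_col Name of the phenotype column (default \code{"sbp"}).
#' @return The data frame with the value column adjusted; the fitted
#'   coefficients are attached as attribute \code{"adjustment"}.  Constant or
#'   collinear covariates are dropped with a warning.
#' @export
adjust_covariates <- function(pheno, covariates, value_col = "sbp") {
  missing_cols <- setdiff(c(value_col, covariates), names(pheno))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!length(covariates)) return(pheno)
  y <- pheno[[value_col]]
  X <- as.matrix(pheno[covariates])
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  co <- fit$coefficients
  aliased <- names(co)[is.na(co)]
  if (length(aliased))
    warning("dropping constant/collinear covariate(s): ",
            paste(aliased, collapse = ", "))
  keep <- setdiff(names(co)[!is.na(co)], "(Intercept)")
  pheno[[value_col]] <- y - drop(X[, keep, drop = FALSE] %*% co[keep])
  attr(pheno, "adjustment") <- co
  pheno
}

#' Fit per-individual linear age trajectories (level-1 model)
#'
#' For each individual, ordinary least squares of the (adjusted) phenotype on
#' age centered at \code{reference_age}: the fitted value at the reference
#' age is the individual's level (e.g. SBP(42)) and the slope its rate of
#' change.  Individuals with a single visit get their one value carried to
#' the reference age along the population mean slope and a missing slope;
#' individuals with two visits get an exact line and residual variance 0.
#'
#' @param pheno Long-format phenotype data frame.
#' @param reference_age Centering age in years (default 42).
#' @param value_col Name of the phenotype column.
#' @return A \code{trajectory_summary} data frame: \code{id},
#'   \code{intercept_at_ref} (mmHg), \code{slope} (mmHg/yr, \code{NA} for
#'   singletons), \code{n_obs}, \code{resid_var} and \code{outlier_flag}
#'   (initialized to \code{"none"}).
#' @export
fit_individual_trajectories <- function(pheno, reference_age = 42,
                                        value_col = "sbp") {
  stopifnot(all(c("id", "age", value_col) %in% names(pheno)))
  by_id <- split(seq_len(nrow(pheno)), as.character(pheno$id))
  ids <- names(by_id)
  n_obs <- lengths(by_id)
  intercept <- slope <- resid_var <- rep(NA_real_, length(ids))
  for (k in seq_along(by_id)) {
    rows <- by_id[[k]]
    x <- pheno$age[rows] - reference_age
    y <- pheno[[value_col]][rows]
    if (anyDuplicated(x))
      stop(sprintf("duplicated exam age for individual '%s'", ids[k]))
    if (length(x) >= 2) {
      b1 <- stats::cov(x, y) / stats::var(x)
      b0 <- mean(y) - b1 * mean(x)
      slope[k] <- b1
      intercept[k] <- b0                    # fitted value at centered age 0
      rss <- sum((y - b0 - b1 * x)^2)
      resid_var[k] <- if (length(x) > 2) rss / (length(x) - 2) else 0
    }
  }
  mean_slope <- mean(slope, na.rm = TRUE)
  if (is.nan(mean_slope)) mean_slope <- 0
  singles <- which(n_obs == 1)
  for (k in singles) {
    rows <- by_id[[k]]
    x <- pheno$age[rows] - reference_age
    intercept[k] <- pheno[[value_col]][rows] - mean_slope * x
    resid_var[k] <- 0
  }
  out <- data.frame(id = ids, intercept_at_ref = intercept, slope = slope,
                    n_obs = as.integer(n_obs), resid_var = resid_var,
                    outlier_flag = "none", stringsAsFactors = FALSE)
  class(out) <- c("trajectory_summary", "data.frame")
  out
}

#' Flag trajectory outliers
#'
#' Applies the two screening rules used before the level-2 fits: values of
#' the level or the slope beyond \code{sd_mult} standard deviations from
#' their mean (each metric screened separately, mean/SD computed once on the
#' full sample), and a physiological floor flagging any level below
#' \code{min_intercept} mmHg.  Flagged individuals are excluded from both
#' level-2 analyses downstream.
#'
#' @param summaries A \code{trajectory_summary} data frame.
#' @param sd_mult Standard-deviation multiplier (default 3).
#' @param min_intercept Minimum plausible level in mmHg (default 60).
#' @return The summaries with \code{outlier_flag} set to \code{"none"},
#'   \code{"intercept_3sd"}, \code{"slope_3sd"} or \code{"low_intercept"}
#'   (the floor rule takes precedence).
#' @export
flag_outliers <- function(summaries, sd_mult = 3, min_intercept = 60) {
  flag <- rep("none", nrow(summaries))
  band_out <- function(x) {
    ok <- !is.na(x)
    s <- stats::sd(x[ok])
    if (!is.finite(s) || s == 0) return(logical(length(x)))
    ok & abs(x - mean(x[ok])) > sd_mult * s
  }
  flag[band_out(summaries$slope)] <- "slope_3sd"
  flag[band_out(summaries$intercept_at_ref)] <- "intercept_3sd"
  low <- !is.na(summaries$intercept_at_ref) &
    summaries$intercept_at_ref < min_intercept
  flag[low] <- "low_intercept"
  summaries$outlier_flag <- flag
  summaries
}
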