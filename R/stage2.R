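#' Kinship linear mixed model by eigen-rotated REML
#'
#' Fits \eqn{y = X\gamma + u + \epsilon} with \eqn{Var(u) = \sigma^2_g A} and
#' \eqn{Var(\epsilon) = \sigma^2_e I} by restricted maximum likelihood.
#' A is eigendecomposed once, y and X are rotated into its eigenbasis where
#' the covariance is diagonal, and the restricted likelihood is profiled over
#' the variance ratio \eqn{\delta = \sigma^2_e/\sigma^2_g} by a 100-point
#' log-spaced grid on \code{delta_range} refined by Brent optimization;
#' generalized least squares then gives the fixed effects.  Both boundaries
#' (\eqn{\sigma^2_g = 0}, and \eqn{\sigma^2_e = 0} when A is strictly
#' positive definite) are evaluated explicitly and reported when optimal.
#'
#' The restricted log-likelihood includes the \eqn{+\frac12\log|X'X|} term,
#' so it is invariant to the rotation and comparable across parameterizations.
#'
#' @param y Response vector (e.g. per-individual levels or slopes).
#' @param X Fixed-effect design matrix, full column rank.
#' @param A Covariance structure: a relationship matrix (see
#'   [kinship_matrix()]) or any symmetric PSD matrix aligned with \code{y}.
#' @param eigen_A Optional precomputed \code{eigen(A, symmetric = TRUE)}; the
#'   decomposition depends only on A, so one decomposition serves every SNP.
#' @param method \code{"reml"} (default) or \code{"ml"}.
#' @param delta Fix the variance ratio instead of estimating it
#'   (\code{Inf} forces \eqn{\sigma^2_g = 0}, i.e. ordinary least squares).
#' @param delta_range Search range for \eqn{\delta}.
#' @param tol Convergence tolerance of the Brent refinement (in
#'   \eqn{\log_{10}\delta}).
#' @return An object of class \code{lmm_fit}: list with
#'   \code{coefficients}, \code{se}, \code{vcov}, \code{sigma2_g},
#'   \code{sigma2_e}, \code{delta}, \code{loglik} (restricted), \code{n},
#'   \code{boundary} and \code{method}.
#' @export
reml_fit <- function(y, X, A = NULL, eigen_A = NULL,
                     method = c("reml", "ml"), delta = NULL,
                     delta_range = c(1e-5, 1e5), tol = 1e-9) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)",
                     if (ncol(X) > 1) paste0("x", seq_len(ncol(X) - 1)))
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n)
  qx <- qr(X)
  if (qx$rank < p)
    stop("rank-deficient design: column '",
         colnames(X)[qx$pivot[qx$rank + 1L]], "' is aliased")
  if (is.null(eigen_A)) {
    stopifnot(!is.null(A), nrow(A) == n)
    check_psd(A)
    eigen_A <- eigen(A, symmetric = TRUE)
  }
  d <- pmax(eigen_A$values, 0)
  U <- eigen_A$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  fit <- reml_fit_rotated(yt, Xt, d, method = method, delta = delta,
                          delta_range = delta_range, tol = tol)
  names(fit$coefficients) <- names(fit$se) <- colnames(X)
  dimnames(fit$vcov) <- list(colnames(X), colnames(X))
  fit
}

# Profile (restricted) log-likelihood at a fixed variance ratio delta, in the
# eigenbasis of A where Var(y) = sigma2_g * diag(d + delta).
rotated_ll <- function(delta, yt, Xt, d, ldXX, reml = TRUE) {
  n <- length(yt); p <- ncol(Xt)
  if (is.infinite(delta)) {             # sigma2_g -> 0 limit: plain OLS
    co <- qr.coef(qr(Xt), yt)
    rss <- sum((yt - Xt %*% co)^2)
    df <- if (reml) n - p else n
    ll <- 0.5 * (df * (log(df / (2 * pi)) - 1 - log(rss)))
    return(list(ll = ll, coef = drop(co),
                XtWX = crossprod(Xt) * (df / rss), rss = rss,
                sigma2_g = 0, sigma2_e = rss / df))
  }
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xt, w * Xt)
  co <- solve(XtWX, crossprod(Xt, w * yt))
  r <- yt - Xt %*% co
  rss <- sum(w * r * r)
  if (reml) {
    df <- n - p
    ll <- 0.5 * (df * (log(df / (2 * pi)) - 1 - log(rss)) -
                   sum(log(d + delta)) -
                   determinant(XtWX)$modulus + ldXX)
  } else {
    df <- n
    ll <- 0.5 * (df * (log(df / (2 * pi)) - 1 - log(rss)) -
                   sum(log(d + delta)))
  }
  s2g <- rss / df
  list(ll = as.numeric(ll), coef = drop(co), XtWX = XtWX, rss = rss,
       sigma2_g = s2g, sigma2_e = delta * s2g)
}

reml_fit_rotated <- function(yt, Xt, d, method = "reml", delta = NULL,
                             delta_range = c(1e-5, 1e5), tol = 1e-9) {
  reml <- method == "reml"
  ldXX <- as.numeric(determinant(crossprod(Xt))$modulus)
  obj <- function(ld) rotated_ll(10^ld, yt, Xt, d, ldXX, reml)$ll
  if (is.null(delta)) {
    grid <- seq(log10(delta_range[1]), log10(delta_range[2]), length.out = 100)
    vals <- vapply(grid, obj, numeric(1))
    i <- which.max(vals)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = tol)
    delta_hat <- 10^opt$maximum
    ll_hat <- opt$objective
    # explicit boundaries: sigma2_g = 0 (delta -> Inf) and, when A is
    # strictly positive definite, sigma2_e = 0 (delta = 0)
    bnd <- rotated_ll(Inf, yt, Xt, d, ldXX, reml)
    boundary <- bnd$ll >= ll_hat - 1e-8
    if (boundary && bnd$ll >= ll_hat) { delta_hat <- Inf; ll_hat <- bnd$ll }
    if (min(d) > 1e-8 * max(d)) {
      b0 <- rotated_ll(0, yt, Xt, d, ldXX, reml)
      if (b0$ll >= ll_hat) {
        delta_hat <- 0; ll_hat <- b0$ll; boundary <- TRUE
      } else if (b0$ll >= ll_hat - 1e-8) boundary <- TRUE
    }
  } else {
    delta_hat <- delta
    ll_hat <- obj(log10(delta_hat))
    boundary <- is.infinite(delta_hat)
  }
  at <- rotated_ll(delta_hat, yt, Xt, d, ldXX, reml)
  vcov <- if (is.infinite(delta_hat)) at$sigma2_e * solve(crossprod(Xt)) else
    at$sigma2_g * solve(at$XtWX)
  structure(list(coefficients = at$coef, se = sqrt(diag(vcov)), vcov = vcov,
                 sigma2_g = at$sigma2_g * !is.infinite(delta_hat),
                 sigma2_e = at$sigma2_e, delta = delta_hat,
                 loglik = if (is.null(delta)) max(ll_hat, at$ll) else at$ll,
                 n = length(yt), boundary = boundary, method = method),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("kinship LMM (%s): n = %d, sigma2_g = %.4g, sigma2_e = %.4g, logLik = %.4f%s\n",
              toupper(x$method), x$n, x$sigma2_g, x$sigma2_e, x$loglik,
              if (x$boundary) " [boundary]" else ""))
  print(data.frame(estimate = x$coefficients, se = x$se))
  invisible(x)
}

#' Mixed model with a pedigree-membership random effect
#'
#' The comparison model: the kinship structure is replaced by a block
#' indicator matrix (1 within a pedigree, 0 between), i.e. a shared random
#' intercept per pedigree (compound symmetry within pedigrees).
#'
#' @param y,X As in [reml_fit()].
#' @param pedigree_ids Pedigree membership, one label per element of
#'   \code{y}.
#' @param ... Passed to [reml_fit()].
#' @return An \code{lmm_fit}.
#' @export
reml_fit_pedigree_random <- function(y, X, pedigree_ids, ...) {
  stopifnot(length(pedigree_ids) == length(y))
  B <- pedigree_block_matrix(pedigree_ids)
  reml_fit(y, X, B, ...)
}

pedigree_block_matrix <- function(pedigree_ids) {
  pid <- as.character(pedigree_ids)
  B <- 1 * outer(pid, pid, "==")
  dimnames(B) <- list(names(pedigree_ids), names(pedigree_ids))
  B
}

#' Per-SNP association tests for trajectory level and slope
#'
#' For every SNP, fits the level-2 mixed model of the chosen trajectory
#' coefficient on \code{[1, dosage, covariates]} with the selected random
#' structure and reports the Wald test of the per-allele effect
#' (\eqn{\chi^2_1 = (\hat\beta / se)^2}).
#'
#' Individuals flagged as outliers are excluded; for the slope phenotype
#' individuals without an estimated slope (single visit) are excluded;
#' individuals with a missing dosage are dropped for that SNP
#' (complete-case; \code{impute_missing = TRUE} substitutes the mean dosage
#' instead).  SNPs monomorphic in the analyzed subset get a missing effect
#' and p = 1, flagged \code{"monomorphic"}.
#'
#' @param summaries A flagged \code{trajectory_summary} (see
#'   [flag_outliers()]).
#' @param G A \code{genotypes} object.
#' @param A Relationship matrix over (at least) the analyzed individuals;
#'   required for \code{mode = "kinship"}.
#' @param phenotype \code{"level"} (intercept at the reference age) or
#'   \code{"slope"} (rate of change).
#' @param covariates Optional data frame of individual-level fixed covariates
#'   with an \code{id} column (e.g. sex).
#' @param mode Random-effect structure: \code{"kinship"} (default),
#'   \code{"pedigree"} (block random effect, needs \code{pedigree_ids}) or
#'   \code{"none"} (ordinary least squares).
#' @param pedigree_ids Named vector mapping individual id to pedigree id.
#' @param impute_missing Mean-impute missing dosages instead of dropping.
#' @return An \code{assoc_result} data frame: \code{snp_id}, \code{pos},
#'   \code{phenotype}, \code{maf}, \code{n_used}, \code{beta}, \code{se},
#'   \code{chi2}, \code{p}, \code{note}.
#' @export
snp_association <- function(summaries, G, A = NULL,
                            phenotype = c("level", "slope"),
                            covariates = NULL,
                            mode = c("kinship", "pedigree", "none"),
                            pedigree_ids = NULL, impute_missing = FALSE) {
  phenotype <- match.arg(phenotype)
  mode <- match.arg(mode)
  keep <- summaries$outlier_flag == "none"
  if (phenotype == "slope") keep <- keep & !is.na(summaries$slope)
  ids <- summaries$id[keep]
  ids <- ids[ids %in% rownames(G$dosage)]
  if (mode == "kinship") {
    stopifnot(!is.null(A))
    if (identical(attr(A, "scale"), "kinship")) A <- relationship_matrix(A)
    ids <- ids[ids %in% rownames(A)]
  }
  if (mode == "pedigree") {
    stopifnot(!is.null(pedigree_ids))
    ids <- ids[ids %in% names(pedigree_ids)]
  }
  if (!length(ids)) stop("no analyzable individuals")
  y <- summaries[[if (phenotype == "level") "intercept_at_ref" else
    "slope"]][match(ids, summaries$id)]
  Xbase <- matrix(1, length(ids), 1, dimnames = list(ids, "(Intercept)"))
  if (!is.null(covariates)) {
    stopifnot("id" %in% names(covariates))
    cv <- covariates[match(ids, covariates$id),
                     setdiff(names(covariates), "id"), drop = FALSE]
    Xbase <- cbind(Xbase, as.matrix(cv))
  }
  Amat <- switch(mode,
                 kinship = A[ids, ids],
                 pedigree = pedigree_block_matrix(
                   stats::setNames(pedigree_ids[ids], ids)),
                 none = NULL)
  eig_full <- if (!is.null(Amat)) eigen(Amat, symmetric = TRUE)
  snp_ids <- colnames(G$dosage)
  res <- vector("list", length(snp_ids))
  for (s in seq_along(snp_ids)) {
    g <- G$dosage[ids, s]
    if (impute_missing && anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    use <- !is.na(g)
    gs <- g[use]; ys <- y[use]; Xs <- cbind(Xbase[use, , drop = FALSE])
    fbar <- mean(gs) / 2
    maf <- min(fbar, 1 - fbar)
    row <- data.frame(snp_id = snp_ids[s], pos = G$map$pos[s],
                      phenotype = phenotype, maf = maf,
                      n_used = length(gs), beta = NA_real_, se = NA_real_,
                      chi2 = NA_real_, p = 1, note = "monomorphic",
                      stringsAsFactors = FALSE)
    if (length(unique(gs)) > 1) {
      X <- cbind(Xs[, 1, drop = FALSE], dosage = gs,
                 Xs[, -1, drop = FALSE])
      if (mode == "none") {
        fit <- stats::lm.fit(X, ys)
        s2 <- sum(fit$residuals^2) / (length(ys) - fit$rank)
        XtXi <- chol2inv(chol(crossprod(X)))
        beta <- fit$coefficients["dosage"]
        se <- sqrt(s2 * diag(XtXi))[which(colnames(X) == "dosage")]
      } else {
        eg <- if (all(use)) eig_full else {
          sub <- Amat[use, use]
          eigen(sub, symmetric = TRUE)
        }
        fit <- reml_fit(ys, X, eigen_A = eg)
        beta <- fit$coefficients["dosage"]
        se <- fit$se["dosage"]
      }
      chi2 <- (beta / se)^2
      row$beta <- unname(beta); row$se <- unname(se)
      row$chi2 <- unname(chi2)
      row$p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
      row$note <- ""
    }
    res[[s]] <- row
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  class(out) <- c("assoc_result", "data.frame")
  out
}
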