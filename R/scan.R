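#' Genomic-control inflation factor
#'
#' \eqn{\lambda} = median of the \eqn{\chi^2_1} quantiles implied by the
#' p-values, divided by the null \eqn{\chi^2_1} median (0.4549364).  Values
#' near 1 indicate correct calibration; \eqn{\lambda > 1} indicates residual
#' stratification or unmodeled relatedness.
#'
#' @param p_values Vector of association p-values (non-monomorphic tests).
#' @return The inflation factor.
#' @export
genomic_lambda <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no valid p values")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Nominal family-wise error rate.
#' @param n_snps Number of tests.
#' @return \code{alpha / n_snps}.
#' @export
bonferroni_alpha <- function(alpha, n_snps) {
  stopifnot(n_snps >= 1)
  alpha / n_snps
}

#' Q-Q plot coordinates for association p-values
#'
#' @param p_values Vector of p-values.
#' @return Data frame of \code{expected} and \code{observed}
#'   \eqn{-\log_{10}} p pairs, matched by rank against uniform quantiles
#'   i/(n+1); ties keep their multiplicity.
#' @export
qq_export <- function(p_values) {
  p <- sort(p_values[!is.na(p_values)])
  n <- length(p)
  stopifnot(n >= 1)
  data.frame(expected = -log10(seq_len(n) / (n + 1)), observed = -log10(p))
}

#' Run the full two-stage association scan
#'
#' Pipeline: pre-adjust the phenotype for time-varying covariates, fit
#' per-individual age trajectories, flag outliers, build the kinship
#' structure, then test every SNP against both the level (value at the
#' reference age) and the slope (rate of change) with the chosen
#' random-effect mode, and summarize calibration.
#'
#' @param peds List of \code{pedigree} objects.
#' @param geno A \code{genotypes} object.
#' @param pheno Long-format phenotype data frame.
#' @param adjust Names of time-varying covariates to regress out in stage 1.
#' @param level2_covariates Names of individual-level fixed covariates for
#'   stage 2 (taken from each individual's first phenotype row).
#' @param reference_age Centering age (years).
#' @param random Random-effect mode: \code{"kinship"}, \code{"pedigree"} or
#'   \code{"none"}.
#' @param maf_min SNPs below this minor allele frequency (in the analyzed
#'   subset) are excluded from the inflation factor and the Bonferroni count.
#' @param sd_mult,min_intercept Outlier rules, see [flag_outliers()].
#' @param value_col Phenotype column name.
#' @param alpha Nominal level for the Bonferroni threshold.
#' @param A Optional precomputed relationship matrix (skips recomputation).
#' @param phenotypes Which trajectory coefficients to scan (default both).
#' @return List of class \code{scan_result} with elements \code{level} and
#'   \code{slope}, each a \code{scan_summary}: \code{phenotype},
#'   \code{n_snps_tested}, \code{lambda_gc}, \code{bonferroni_alpha},
#'   \code{qq_points}, \code{top_hits} and the full \code{results} table;
#'   plus the flagged stage-1 \code{summaries}.
#' @export
run_scan <- function(peds, geno, pheno, adjust = c("smoke", "med"),
                     level2_covariates = "sex", reference_age = 42,
                     random = c("kinship", "pedigree", "none"),
                     maf_min = 0.01, sd_mult = 3, min_intercept = 60,
                     value_col = "sbp", alpha = 0.05, A = NULL,
                     phenotypes = c("level", "slope")) {
  random <- match.arg(random)
  phenotypes <- match.arg(phenotypes, several.ok = TRUE)
  adjust <- intersect(adjust, names(pheno))
  adj <- adjust_covariates(pheno, adjust, value_col = value_col)
  summaries <- fit_individual_trajectories(adj, reference_age, value_col)
  summaries <- flag_outliers(summaries, sd_mult, min_intercept)
  if (is.null(A) && random == "kinship")
    A <- kinship_matrix(peds, scale = "relationship")
  ped_ids <- unlist(unname(lapply(peds, function(p)
    stats::setNames(rep(attr(p, "ped_id"), nrow(p)), p$id))))
  covs <- NULL
  if (length(level2_covariates)) {
    first <- pheno[!duplicated(pheno$id), , drop = FALSE]
    covs <- first[c("id", intersect(level2_covariates, names(first)))]
    if (ncol(covs) == 1) covs <- NULL
  }
  one <- function(phenotype) {
    res <- snp_association(summaries, geno, A = A, phenotype = phenotype,
                           covariates = covs, mode = random,
                           pedigree_ids = ped_ids)
    ok <- res$note == "" & res$maf >= maf_min
    tested <- res[ok, , drop = FALSE]
    s <- list(phenotype = phenotype,
              n_snps_tested = nrow(tested),
              lambda_gc = if (nrow(tested)) genomic_lambda(tested$p) else NA,
              bonferroni_alpha = if (nrow(tested))
                bonferroni_alpha(alpha, nrow(tested)) else NA,
              qq_points = if (nrow(tested)) qq_export(tested$p) else NULL,
              top_hits = utils::head(tested[order(tested$p), ], 10),
              results = res)
    class(s) <- "scan_summary"
    s
  }
  out <- stats::setNames(lapply(phenotypes, one), phenotypes)
  out$summaries <- summaries
  out$random <- random
  class(out) <- "scan_result"
  out
}

#' @export
print.scan_summary <- function(x, ...) {
  cat(sprintf("%s: %d SNPs tested, lambda = %.3f, Bonferroni alpha = %.3g\n",
              x$phenotype, x$n_snps_tested, x$lambda_gc, x$bonferroni_alpha))
  invisible(x)
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("two-stage scan (random = %s)\n", x$random))
  for (ph in intersect(c("level", "slope"), names(x))) print(x[[ph]])
  invisible(x)
}
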