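#' Replicate-based power estimation
#'
#' Mirrors the replicate design of simulated-phenotype studies: pedigrees and
#' genotypes are held fixed (by default) while phenotypes are redrawn from
#' the generative model in each replicate, the full two-stage pipeline is
#' rerun, and per-SNP significance is counted at each nominal level.
#' Significance is two-sided regardless of the sign of the estimate.
#'
#' @param cfg A [sim_config()]; should usually contain causal SNPs.
#' @param n_replicates Number of phenotype replicates.
#' @param alphas Nominal significance levels (e.g. \code{c(0.05, 0.0008)}).
#' @param snps SNP indices (or ids) to tally; default all SNPs.
#' @param redraw_genotypes Redraw genotypes (and pedigrees stay fixed) each
#'   replicate instead of reusing them.
#' @param random Random-effect mode passed to [run_scan()].
#' @param maf_min MAF filter passed to [run_scan()].
#' @return A \code{power_result} data frame: \code{snp_id},
#'   \code{phenotype}, \code{alpha}, \code{n_replicates},
#'   \code{n_significant}, \code{power} and \code{beta_mean} (average effect
#'   estimate across replicates).
#' @export
estimate_power <- function(cfg, n_replicates, alphas = c(0.05, 0.0008),
                           snps = NULL, redraw_genotypes = FALSE,
                           random = "kinship", maf_min = 0) {
  stopifnot(inherits(cfg, "sim_config"), n_replicates >= 1)
  peds <- simulate_pedigrees(cfg)
  A <- kinship_matrix(peds, scale = "relationship")
  geno <- NULL
  base <- simulate_cohort(cfg, peds = peds)
  if (!redraw_genotypes) geno <- base$genotypes
  snp_ids <- colnames(base$genotypes$dosage)
  if (!is.null(snps))
    snp_ids <- if (is.numeric(snps)) snp_ids[snps] else snps
  recs <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    coh <- simulate_cohort(cfg, peds = peds, geno = geno)
    sub <- coh$genotypes
    keep <- match(snp_ids, colnames(sub$dosage))
    sub$dosage <- sub$dosage[, keep, drop = FALSE]
    sub$map <- sub$map[keep, , drop = FALSE]
    sub$maf <- sub$maf[keep]
    scan <- run_scan(peds, sub, coh$phenotypes, random = random,
                     maf_min = maf_min, reference_age = cfg$reference_age,
                     A = A)
    recs[[r]] <- rbind(scan$level$results, scan$slope$results)
  }
  all <- do.call(rbind, recs)
  agg <- expand.grid(snp_id = snp_ids, phenotype = c("level", "slope"),
                     alpha = alphas, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(agg)), function(k) {
    sel <- all$snp_id == agg$snp_id[k] & all$phenotype == agg$phenotype[k]
    n_sig <- sum(all$p[sel] < agg$alpha[k], na.rm = TRUE)
    data.frame(snp_id = agg$snp_id[k], phenotype = agg$phenotype[k],
               alpha = agg$alpha[k], n_replicates = n_replicates,
               n_significant = n_sig, power = n_sig / n_replicates,
               beta_mean = mean(all$beta[sel], na.rm = TRUE))
  }))
  class(out) <- c("power_result", "data.frame")
  out
}
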