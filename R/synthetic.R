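#' Configuration for the synthetic longitudinal pedigree cohort
#'
#' Bundles every parameter of the generative model: pedigree structure,
#' marker allele frequencies, fixed effects on the phenotype level at the
#' reference age and on its rate of change, kinship-structured variance
#' components, visit schedule and time-varying covariates.
#'
#' The phenotype for visit j of individual i is generated from the combined
#' two-level model
#' \deqn{Y_{ij} = \gamma_{00} + \gamma_{10} t_{ij} + \sum_c (\gamma_{01,c}
#'   G_{ic} + \gamma_{11,c} G_{ic} t_{ij}) + U_{0i} + U_{1i} t_{ij} +
#'   \beta' z_{ij} + r_{ij}}
#' where \eqn{t_{ij}} is age centered at \code{reference_age}, the sum runs
#' over causal SNPs, \eqn{U_{0i} = u_{0i} + \epsilon_{0i}} and
#' \eqn{U_{1i} = u_{1i} + \epsilon_{1i}} split each random coefficient into a
#' heritable part with covariance \eqn{\sigma^2_g A} (A the relationship
#' matrix) and an independent part, \eqn{z_{ij}} are covariates and
#' \eqn{r_{ij} \sim N(0, \sigma^2)} is measurement error.
#'
#' Defaults emulate a cohort of 20 extended pedigrees of 27--107 members with
#' 1--4 exams per person and entry ages 16--94: grand intercept 118 mmHg at
#' age 42, mean slope 0.303 mmHg/yr, intercept variance split 40 (heritable)
#' + 40 (individual) mmHg^2 with residual 50 mmHg^2, and exam gaps of
#' 3.9, 3.0 and 3.0 years.
#'
#' @param n_pedigrees Number of pedigrees.
#' @param pedigree_size_range Integer \code{c(min, max)} members per pedigree.
#' @param n_snps Number of independent SNPs to gene-drop.
#' @param maf Per-SNP minor allele frequencies in (0, 0.5]; recycled, or
#'   \code{NULL} to draw them uniformly on \code{maf_range}.
#' @param maf_range Range for drawn MAFs when \code{maf} is \code{NULL}.
#' @param causal Data frame with columns \code{snp} (index), \code{maf},
#'   \code{gamma01} (mmHg per allele on the level) and \code{gamma11}
#'   (mmHg/yr per allele on the slope); \code{NULL} for a null cohort.
#' @param gamma00 Grand intercept at the reference age (mmHg).
#' @param gamma10 Mean slope (mmHg/yr).
#' @param sigma2_g0,sigma2_e0 Heritable / nonheritable variance of the random
#'   intercept (mmHg^2).
#' @param sigma2_g1,sigma2_e1 Heritable / nonheritable variance of the random
#'   slope ((mmHg/yr)^2).
#' @param sigma2_resid Visit-level measurement error variance (mmHg^2).
#' @param visit_probs Probabilities of 1, 2, 3 or 4 exams per individual.
#' @param entry_age_range Range of age at first exam (years).  Entry ages
#'   are drawn as \code{min + (max - min) * Beta(1.5, 3.46)}, a
#'   right-skewed distribution with mean ~39.6 years over the default
#'   range — adult family-study cohorts enroll mostly younger adults with
#'   a long elderly tail, and the reference age sits near the mean exam
#'   age.
#' @param visit_gaps Years between consecutive exams (length 3).
#' @param covariate_effects Named vector: additive mmHg effects of current
#'   smoking, antihypertensive medication and male sex.
#' @param smoke_prev,med_prev Marginal probability of each time-varying state.
#' @param persistence Probability that a state carries over to the next exam
#'   unchanged (otherwise redrawn at its prevalence).
#' @param reference_age Centering age shared with the level-1 analysis.
#' @param missing_rate Proportion of dosages set missing at random.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_pedigrees = 20L,
                       pedigree_size_range = c(27L, 107L),
                       n_snps = 10L,
                       maf = NULL,
                       maf_range = c(0.05, 0.5),
                       causal = NULL,
                       gamma00 = 118,
                       gamma10 = 0.303,
                       sigma2_g0 = 40, sigma2_e0 = 40,
                       sigma2_g1 = 0.02, sigma2_e1 = 0.02,
                       sigma2_resid = 50,
                       visit_probs = c(246, 183, 309, 194) / 932,
                       entry_age_range = c(16, 94),
                       visit_gaps = c(3.9, 3.0, 3.0),
                       covariate_effects = c(smoke = 4, med = -10, sex = 3),
                       smoke_prev = 0.2, med_prev = 0.25,
                       persistence = 0.85,
                       reference_age = 42,
                       missing_rate = 0) {
  cfg <- list(n_pedigrees = as.integer(n_pedigrees),
              pedigree_size_range = as.integer(pedigree_size_range),
              n_snps = as.integer(n_snps), maf = maf, maf_range = maf_range,
              causal = causal, gamma00 = gamma00, gamma10 = gamma10,
              sigma2_g0 = sigma2_g0, sigma2_e0 = sigma2_e0,
              sigma2_g1 = sigma2_g1, sigma2_e1 = sigma2_e1,
              sigma2_resid = sigma2_resid,
              visit_probs = visit_probs / sum(visit_probs),
              entry_age_range = entry_age_range, visit_gaps = visit_gaps,
              covariate_effects = covariate_effects,
              smoke_prev = smoke_prev, med_prev = med_prev,
              persistence = persistence, reference_age = reference_age,
              missing_rate = missing_rate)
  vars <- c("sigma2_g0", "sigma2_e0", "sigma2_g1", "sigma2_e1", "sigma2_resid")
  bad <- vars[vapply(cfg[vars], function(v) v < 0, logical(1))]
  if (length(bad)) stop("negative variance component(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(maf) && any(maf <= 0 | maf > 0.5))
    stop("MAFs must lie in (0, 0.5]")
  if (!is.null(causal)) {
    stopifnot(is.data.frame(causal),
              all(c("snp", "maf", "gamma01", "gamma11") %in% names(causal)))
    if (any(causal$maf <= 0 | causal$maf > 0.5))
      stop("causal MAFs must lie in (0, 0.5]")
    if (any(causal$snp < 1 | causal$snp > cfg$n_snps))
      stop("causal snp index out of range")
  }
  if (cfg$pedigree_size_range[1] < 3 ||
      cfg$pedigree_size_range[1] > cfg$pedigree_size_range[2])
    stop("unreachable pedigree size range")
  if (abs(sum(cfg$visit_probs) - 1) > 1e-12)
    stop("visit_probs must sum to 1")
  class(cfg) <- "sim_config"
  cfg
}

# Grow one pedigree generation-wise to an exact target size: start from a
# founder couple, draw offspring counts, marry in founder spouses, and stop
# adding members the moment the target is reached.
build_pedigree <- function(ped_id, target) {
  fa <- mo <- character(0)
  sex <- integer(0)
  ids <- character(0)
  add <- function(f, m, s) {
    ids[length(ids) + 1L] <<- sprintf("%s_I%03d", ped_id, length(ids) + 1L)
    fa[length(fa) + 1L] <<- f
    mo[length(mo) + 1L] <<- m
    sex[length(sex) + 1L] <<- s
    ids[length(ids)]
  }
  f1 <- add(NA, NA, 1L); m1 <- add(NA, NA, 2L)
  couples <- list(c(f1, m1))
  gen <- 1L
  while (length(ids) < target) {
    if (!length(couples)) {        # growth stalled: add a fresh founder couple
      a <- add(NA, NA, 1L)
      if (length(ids) >= target) break
      b <- add(NA, NA, 2L)
      couples <- list(c(a, b))
      next
    }
    nxt <- list()
    for (cp in couples) {
      if (length(ids) >= target) break
      n_off <- 1L + stats::rpois(1L, 1.6)
      for (k in seq_len(n_off)) {
        if (length(ids) >= target) break
        s <- sample(1:2, 1L)
        child <- add(cp[1], cp[2], s)
        if (gen < 3L && length(ids) < target && stats::runif(1) < 0.75) {
          sp <- add(NA, NA, 3L - s)
          nxt[[length(nxt) + 1L]] <-
            if (s == 1L) c(child, sp) else c(sp, child)
        }
      }
    }
    couples <- nxt
    gen <- gen + 1L
  }
  new_pedigree(ped_id, ids, fa, mo, sex)
}

#' Simulate extended multi-generation pedigrees
#'
#' Builds pedigrees generation-wise: a founder couple has offspring, each
#' offspring may marry in an unrelated founder spouse, for 3--4 generations,
#' until a target size drawn uniformly from \code{pedigree_size_range} is
#' reached exactly.
#'
#' @param cfg A [sim_config()].
#' @return A list of \code{pedigree} objects named \code{PED01}, ...
#' @export
simulate_pedigrees <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rng <- cfg$pedigree_size_range
  peds <- vector("list", cfg$n_pedigrees)
  for (p in seq_len(cfg$n_pedigrees)) {
    target <- sample(rng[1]:rng[2], 1L)
    peds[[p]] <- build_pedigree(sprintf("PED%02d", p), target)
  }
  names(peds) <- vapply(peds, attr, "", "ped_id")
  peds
}

#' Gene-drop genotypes through pedigrees
#'
#' Founder alleles are drawn Bernoulli(maf) per chromosome; each offspring
#' inherits one uniformly chosen allele from each parent (an unknown parent
#' contributes a population allele).  Dosage is the allele count, so
#' Mendelian consistency holds by construction and SNPs are independent given
#' the transmissions.
#'
#' @param peds List of \code{pedigree} objects.
#' @param maf Numeric vector of allele frequencies, one per SNP.
#' @param missing_rate Proportion of dosages masked to \code{NA} at random.
#' @return A \code{genotypes} object: list with \code{dosage} (individuals x
#'   SNPs matrix), \code{map} (snp_id, chrom, pos) and \code{maf} (sample
#'   minor allele frequency per SNP).
#' @export
drop_genotypes <- function(peds, maf, missing_rate = 0) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  m <- length(maf)
  stopifnot(m >= 1, all(maf >= 0 & maf <= 1))
  blocks <- lapply(peds, function(ped) {
    n <- nrow(ped)
    fi <- match(ped$father, ped$id)
    mi <- match(ped$mother, ped$id)
    a1 <- a2 <- matrix(0L, n, m)
    pop_allele <- function() stats::rbinom(m, 1L, maf)
    for (i in seq_len(n)) {
      a1[i, ] <- if (is.na(fi[i])) pop_allele() else
        ifelse(stats::runif(m) < 0.5, a1[fi[i], ], a2[fi[i], ])
      a2[i, ] <- if (is.na(mi[i])) pop_allele() else
        ifelse(stats::runif(m) < 0.5, a1[mi[i], ], a2[mi[i], ])
    }
    d <- a1 + a2
    rownames(d) <- ped$id
    d
  })
  dosage <- do.call(rbind, blocks)
  colnames(dosage) <- sprintf("snp%04d", seq_len(m))
  if (missing_rate > 0) {
    mask <- stats::runif(length(dosage)) < missing_rate
    dosage[mask] <- NA_integer_
  }
  map <- data.frame(snp_id = colnames(dosage), chrom = 3L,
                    pos = 47000000L + 1000L * seq_len(m))
  new_genotypes(dosage, map)
}

new_genotypes <- function(dosage, map) {
  f <- colMeans(dosage, na.rm = TRUE) / 2
  g <- list(dosage = dosage, map = map, maf = pmin(f, 1 - f))
  class(g) <- "genotypes"
  g
}

#' Draw kinship-structured random effects
#'
#' Samples the heritable component \eqn{u \sim N(0, \sigma^2_g K)} through an
#' eigenfactorization of K (robust to semidefinite K) and the independent
#' component \eqn{\epsilon \sim N(0, \sigma^2_e I)}.
#'
#' @param K Covariance structure matrix (typically the relationship matrix).
#' @param sigma2_g,sigma2_e Heritable and independent variances (>= 0).
#' @return List with vectors \code{u} and \code{eps}, named by the rownames
#'   of \code{K}.
#' @export
simulate_random_effects <- function(K, sigma2_g, sigma2_e) {
  if (sigma2_g < 0 || sigma2_e < 0) stop("variances must be non-negative")
  n <- nrow(K)
  u <- if (sigma2_g == 0) numeric(n) else {
    E <- eigen(K, symmetric = TRUE)
    drop(E$vectors %*% (sqrt(pmax(E$values, 0) * sigma2_g) *
                          stats::rnorm(n)))
  }
  names(u) <- rownames(K)
  eps <- stats::rnorm(n, 0, sqrt(sigma2_e))
  names(eps) <- rownames(K)
  list(u = u, eps = eps)
}

# Markov chain over exams for a binary time-varying state.
sim_tv_state <- function(n_visits, prev, persistence) {
  s <- integer(n_visits)
  s[1] <- stats::rbinom(1L, 1L, prev)
  for (j in seq_len(n_visits - 1L)) {
    s[j + 1L] <- if (stats::runif(1) < persistence) s[j] else
      stats::rbinom(1L, 1L, prev)
  }
  s
}

#' Simulate longitudinal phenotypes from the combined two-level model
#'
#' Given pedigrees, genotypes and per-individual random coefficients, draws a
#' visit schedule and generates phenotype values; see [sim_config()] for the
#' model.
#'
#' @param peds List of \code{pedigree} objects.
#' @param geno A \code{genotypes} object aligned with the pedigree members.
#' @param cfg A [sim_config()].
#' @param ranef Optional list with per-individual \code{u0, eps0, u1, eps1}
#'   (named vectors); drawn from the pedigree kinship structure when
#'   \code{NULL}.
#' @return List: \code{phenotypes} (long data frame \code{id}, \code{age},
#'   \code{sbp}, \code{smoke}, \code{med}, \code{sex}) and \code{truth}
#'   (per-individual \code{beta0}, \code{beta1}, \code{u0}, \code{u1}).
#' @export
simulate_longitudinal <- function(peds, geno, cfg, ranef = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- unlist(lapply(peds, `[[`, "id"), use.names = FALSE)
  sexes <- unlist(lapply(peds, `[[`, "sex"), use.names = FALSE)
  n <- length(ids)
  if (is.null(ranef)) {
    u0 <- eps0 <- u1 <- eps1 <- numeric(0)
    for (ped in peds) {
      A <- relationship_matrix(kinship_from_pedigree(ped))
      r0 <- simulate_random_effects(A, cfg$sigma2_g0, cfg$sigma2_e0)
      r1 <- simulate_random_effects(A, cfg$sigma2_g1, cfg$sigma2_e1)
      u0 <- c(u0, r0$u); eps0 <- c(eps0, r0$eps)
      u1 <- c(u1, r1$u); eps1 <- c(eps1, r1$eps)
    }
    ranef <- list(u0 = u0, eps0 = eps0, u1 = u1, eps1 = eps1)
  }
  # genetic values of the causal SNPs
  g_level <- g_slope <- numeric(n)
  if (!is.null(cfg$causal)) {
    for (r in seq_len(nrow(cfg$causal))) {
      dose <- geno$dosage[ids, cfg$causal$snp[r]]
      dose[is.na(dose)] <- 0
      g_level <- g_level + cfg$causal$gamma01[r] * dose
      g_slope <- g_slope + cfg$causal$gamma11[r] * dose
    }
  }
  beta0 <- cfg$gamma00 + g_level + ranef$u0[ids] + ranef$eps0[ids]
  beta1 <- cfg$gamma10 + g_slope + ranef$u1[ids] + ranef$eps1[ids]
  ce <- cfg$covariate_effects
  male <- as.integer(!is.na(sexes) & sexes == 1L)
  n_visits <- sample(1:4, n, replace = TRUE, prob = cfg$visit_probs)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nv <- n_visits[i]
    entry <- cfg$entry_age_range[1] +
      diff(cfg$entry_age_range) * stats::rbeta(1, 1.5, 3.46)
    ages <- entry + c(0, cumsum(cfg$visit_gaps))[seq_len(nv)]
    t <- ages - cfg$reference_age
    smoke <- sim_tv_state(nv, cfg$smoke_prev, cfg$persistence)
    med <- sim_tv_state(nv, cfg$med_prev, cfg$persistence)
    y <- beta0[i] + beta1[i] * t +
      ce[["smoke"]] * smoke + ce[["med"]] * med + ce[["sex"]] * male[i] +
      stats::rnorm(nv, 0, sqrt(cfg$sigma2_resid))
    rows[[i]] <- data.frame(id = ids[i], age = ages, sbp = y,
                            smoke = smoke, med = med, sex = male[i])
  }
  truth <- data.frame(id = ids, beta0 = unname(beta0), beta1 = unname(beta1),
                      u0 = unname(ranef$u0[ids]), u1 = unname(ranef$u1[ids]),
                      sex = male)
  list(phenotypes = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = truth)
}

#' Generate a complete synthetic cohort with known ground truth
#'
#' Runs [simulate_pedigrees()], [drop_genotypes()] and
#' [simulate_longitudinal()] under one configuration and packages the result
#' with the relationship matrix and all generative parameters.
#'
#' @param cfg A [sim_config()].
#' @param peds,geno Optionally reuse an existing pedigree set / genotypes
#'   (for replicate designs that redraw phenotypes only).
#' @return A \code{synthetic_cohort}: list with \code{pedigrees},
#'   \code{genotypes}, \code{phenotypes}, \code{truth} (per-individual
#'   coefficients and the causal table) and \code{config}.
#' @export
simulate_cohort <- function(cfg = sim_config(), peds = NULL, geno = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(peds)) peds <- simulate_pedigrees(cfg)
  if (is.null(geno)) {
    maf <- cfg$maf
    if (is.null(maf))
      maf <- stats::runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
    maf <- rep_len(maf, cfg$n_snps)
    if (!is.null(cfg$causal)) maf[cfg$causal$snp] <- cfg$causal$maf
    geno <- drop_genotypes(peds, maf, cfg$missing_rate)
  }
  sim <- simulate_longitudinal(peds, geno, cfg)
  out <- list(pedigrees = peds, genotypes = geno,
              phenotypes = sim$phenotypes,
              truth = list(individual = sim$truth, causal = cfg$causal),
              config = cfg)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d pedigrees, %d individuals, %d SNPs, %d phenotype rows\n",
              length(x$pedigrees), nrow(x$genotypes$dosage),
              ncol(x$genotypes$dosage), nrow(x$phenotypes)))
  invisible(x)
}
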