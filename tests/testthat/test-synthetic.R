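test_that("simulated pedigrees respect size bounds and are reproducible", {
  cfg <- sim_config(n_pedigrees = 2, pedigree_size_range = c(5, 8))
  set.seed(3)
  peds <- simulate_pedigrees(cfg)
  expect_length(peds, 2)
  sizes <- vapply(peds, nrow, 0L)
  expect_true(all(sizes >= 5 & sizes <= 8))
  set.seed(3)
  peds2 <- simulate_pedigrees(cfg)
  expect_identical(peds, peds2)

  set.seed(4)
  big <- simulate_pedigrees(sim_config(n_pedigrees = 20,
                                       pedigree_size_range = c(27, 107)))
  total <- sum(vapply(big, nrow, 0L))
  expect_gte(total, 540)
  expect_lte(total, 2140)
  expect_error(sim_config(pedigree_size_range = c(10, 5)), "unreachable")
})

test_that("gene dropping is Mendelian-consistent and tracks allele frequency", {
  set.seed(21)
  peds <- simulate_pedigrees(sim_config(n_pedigrees = 3,
                                        pedigree_size_range = c(10, 20)))
  geno <- drop_genotypes(peds, maf = rep(0.3, 5))
  # a child's dosage is compatible with its parents' dosages in every trio
  for (ped in peds) {
    d <- geno$dosage[ped$id, , drop = FALSE]
    for (i in which(!is.na(ped$father))) {
      cf <- d[ped$father[i], ]; cm <- d[ped$mother[i], ]; cc <- d[i, ]
      expect_true(all(cc >= floor(cf / 2) + floor(cm / 2)))
      expect_true(all(cc <= ceiling(cf / 2) + ceiling(cm / 2)))
    }
  }
  # degenerate frequency
  g0 <- drop_genotypes(peds, maf = 0)
  expect_true(all(g0$dosage == 0))
  # founder-only pedigrees: sample frequency approaches the target
  set.seed(22)
  founders <- lapply(1:40, function(k)
    new_pedigree(paste0("U", k), paste0("u", k, "_", 1:10),
                 rep(NA, 10), rep(NA, 10)))
  gf <- drop_genotypes(founders, maf = 0.3)
  n_alleles <- 2 * nrow(gf$dosage)
  se <- sqrt(0.3 * 0.7 / n_alleles)
  expect_lt(abs(mean(gf$dosage) / 2 - 0.3), 3 * se)
})

test_that("kinship-structured random effects have the prescribed covariance", {
  expect_error(simulate_random_effects(diag(2), -1, 1), "non-negative")
  expect_equal(simulate_random_effects(diag(3), 0, 1)$u, rep(0, 3),
               ignore_attr = TRUE)
  # unrelated individuals: empirical variance -> sigma2_g, covariance -> 0
  set.seed(31)
  reps <- 6000
  U <- replicate(reps, simulate_random_effects(diag(4), 10, 0)$u)
  emp <- tcrossprod(U) / reps
  se_v <- 10 * sqrt(2 / reps)            # var of a chi-square mean
  expect_true(all(abs(diag(emp) - 10) < 3 * se_v))
  expect_true(all(abs(emp[upper.tri(emp)]) < 3 * 10 / sqrt(reps)))
  # sib pairs at relationship 0.5: cov -> sigma2_g / 2
  blk <- matrix(c(1, .5, .5, 1), 2)
  S <- replicate(reps, simulate_random_effects(blk, 10, 0)$u)
  cv <- mean(S[1, ] * S[2, ])
  expect_lt(abs(cv - 5), 3 * sd(S[1, ] * S[2, ]) / sqrt(reps))
})

test_that("noiseless cohorts follow the generative line exactly", {
  cfg <- sim_config(n_pedigrees = 2, pedigree_size_range = c(6, 10),
                    n_snps = 2, sigma2_g0 = 0, sigma2_e0 = 0,
                    sigma2_g1 = 0, sigma2_e1 = 0, sigma2_resid = 0,
                    covariate_effects = c(smoke = 0, med = 0, sex = 0))
  set.seed(41)
  coh <- simulate_cohort(cfg)
  t <- coh$phenotypes$age - cfg$reference_age
  expect_equal(coh$phenotypes$sbp, cfg$gamma00 + cfg$gamma10 * t)

  # one causal SNP, level effect -10 per allele, still noiseless
  cfg2 <- sim_config(n_pedigrees = 2, pedigree_size_range = c(20, 30),
                     n_snps = 2,
                     causal = data.frame(snp = 1, maf = 0.5,
                                         gamma01 = -10, gamma11 = 0),
                     sigma2_g0 = 0, sigma2_e0 = 0, sigma2_g1 = 0,
                     sigma2_e1 = 0, sigma2_resid = 0,
                     covariate_effects = c(smoke = 0, med = 0, sex = 0))
  set.seed(42)
  coh2 <- simulate_cohort(cfg2)
  ph <- coh2$phenotypes
  dose <- unname(coh2$genotypes$dosage[ph$id, 1])
  t2 <- ph$age - cfg2$reference_age
  expect_equal(ph$sbp, cfg2$gamma00 + cfg2$gamma10 * t2 - 10 * dose)
  # dosage 2 vs 0 differ by -20 at the reference age by construction
  expect_equal(diff(range(tapply(ph$sbp - cfg2$gamma10 * t2, dose, mean))),
               20)
})

test_that("individual slope variance matches its analytic decomposition", {
  cfg <- sim_config(n_pedigrees = 12, pedigree_size_range = c(27, 60),
                    n_snps = 1, sigma2_g1 = 0.5, sigma2_e1 = 0.5,
                    visit_probs = c(0, 0, 0, 1))
  set.seed(51)
  coh <- simulate_cohort(cfg)
  b1 <- coh$truth$individual$beta1
  v <- var(b1)
  target <- cfg$sigma2_g1 + cfg$sigma2_e1
  # generous band: pedigree correlation inflates the variance of var()
  expect_lt(abs(v - target), 4 * target * sqrt(2 / length(b1)) + 0.05)
})

test_that("a fixed seed reproduces the cohort bit for bit", {
  cfg <- sim_config(n_pedigrees = 2, pedigree_size_range = c(8, 12),
                    n_snps = 4)
  set.seed(61); c1 <- simulate_cohort(cfg)
  set.seed(61); c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
})

test_that("cohort writers and readers round-trip", {
  cfg <- sim_config(n_pedigrees = 2, pedigree_size_range = c(6, 9),
                    n_snps = 3, missing_rate = 0.1)
  set.seed(71)
  coh <- simulate_cohort(cfg)
  fam <- tempfile(); dos <- tempfile(); map <- tempfile(); phe <- tempfile()
  write_fam(coh$pedigrees, fam)
  write_dosage(coh$genotypes, dos)
  write_map(coh$genotypes, map)
  write_phenotypes(coh$phenotypes, phe)
  peds <- read_pedigree(fam)
  expect_setequal(names(peds), names(coh$pedigrees))
  for (k in names(peds)) {
    got <- peds[[k]][order(peds[[k]]$id), ]
    want <- coh$pedigrees[[k]][order(coh$pedigrees[[k]]$id), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, ignore_attr = TRUE)
  }
  ids <- unlist(lapply(peds, `[[`, "id"), use.names = FALSE)
  geno <- read_genotypes(dos, map, ids = rownames(coh$genotypes$dosage))
  expect_equal(geno$dosage, coh$genotypes$dosage, ignore_attr = TRUE)
  expect_equal(geno$maf, coh$genotypes$maf, tolerance = 1e-12)
  ph <- read_phenotypes(phe)
  expect_equal(ph$sbp, coh$phenotypes$sbp, tolerance = 1e-6)
  expect_equal(ph$id, coh$phenotypes$id)
})
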