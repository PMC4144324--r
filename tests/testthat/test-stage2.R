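test_that("identity relatedness reduces the mixed model to OLS", {
  set.seed(101)
  n <- 40
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(2, 0.5)) + rnorm(n)
  fit <- reml_fit(y, X, diag(n))
  ols <- lm.fit(X, y)
  expect_equal(unname(fit$coefficients), unname(ols$coefficients),
               tolerance = 1e-8)
  # only the total variance is identifiable; it matches the OLS residual MS
  s2 <- sum(ols$residuals^2) / (n - 2)
  expect_equal(fit$sigma2_g + fit$sigma2_e, s2, tolerance = 1e-4)
})

test_that("fixing sigma2_g to zero reproduces closed-form OLS exactly", {
  set.seed(102)
  n <- 24
  A <- sib_quad_relationship(n)
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- draw_mixed(X, c(1, 2, -1), A, 3, 2)
  fit <- reml_fit(y, X, A, delta = Inf)
  XtXi <- solve(crossprod(X))
  beta <- drop(XtXi %*% crossprod(X, y))
  rss <- sum((y - X %*% beta)^2)
  se <- sqrt(rss / (n - 3) * diag(XtXi))
  expect_lt(max(abs(fit$coefficients - beta)), 1e-10)
  expect_lt(max(abs(fit$se - se)), 1e-10)
})

test_that("rotated profile likelihood equals dense direct-inversion REML", {
  set.seed(103)
  for (n in c(16, 36)) {
    A <- sib_quad_relationship(n)
    X <- cbind(1, rnorm(n))
    y <- draw_mixed(X, c(0, 1), A, 4, 1)
    fit <- reml_fit(y, X, A)
    for (pars in list(c(1, 1), c(4, 0.5), c(0.2, 3))) {
      E <- eigen(A, symmetric = TRUE)
      delta <- pars[2] / pars[1]
      # profile value at this delta, rescaled to the (g, e) likelihood:
      # evaluate the dense definition and the rotated profile at its
      # own sigma2_g-hat for the same delta
      yt <- drop(crossprod(E$vectors, y))
      Xt <- crossprod(E$vectors, X)
      r <- hlmkin:::rotated_ll(delta, yt, Xt, pmax(E$values, 0),
                               as.numeric(determinant(crossprod(X))$modulus))
      expect_equal(r$ll, dense_reml_ll(r$sigma2_g, r$sigma2_e, y, X, A),
                   tolerance = 1e-8)
    }
  }
})

test_that("two-sib-quad toy problem matches the brute-force oracle", {
  # fixed 8-individual fixture: two sibships of four
  A <- sib_quad_relationship(8)
  y <- c(10.81, 12.47, 9.35, 11.06, 7.62, 8.93, 9.71, 8.04)
  X <- cbind(1, c(0, 1, 1, 2, 0, 0, 1, 0))
  fit <- reml_fit(y, X, A)
  oracle <- dense_reml_fit(y, X, A)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  expect_lt(abs(fit$sigma2_g - oracle$sigma2_g), 1e-3)
  expect_lt(abs(fit$sigma2_e - oracle$sigma2_e), 1e-3)
})

test_that("estimates are equivariant to scaling and to reordering", {
  set.seed(104)
  n <- 28
  A <- sib_quad_relationship(n)
  X <- cbind(1, rbinom(n, 2, 0.3))
  y <- draw_mixed(X, c(5, 1), A, 4, 2)
  fit <- reml_fit(y, X, A)
  fit2 <- reml_fit(2 * y, X, A)
  expect_equal(fit2$coefficients, 2 * fit$coefficients, tolerance = 1e-5)
  expect_equal(fit2$sigma2_g, 4 * fit$sigma2_g, tolerance = 1e-3)
  expect_equal(fit2$sigma2_e, 4 * fit$sigma2_e, tolerance = 1e-3)
  perm <- sample(n)
  fit3 <- reml_fit(y[perm], X[perm, ], A[perm, perm])
  expect_equal(fit3$coefficients, fit$coefficients, tolerance = 1e-6)
  expect_equal(fit3$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("variance components are recovered on simulated cohorts", {
  set.seed(105)
  devs <- replicate(12, {
    peds <- simulate_pedigrees(sim_config(n_pedigrees = 6,
                                          pedigree_size_range = c(27, 40)))
    A <- kinship_matrix(peds, scale = "relationship")
    n <- nrow(A)
    X <- matrix(1, n, 1)
    y <- draw_mixed(X, 0, A, 40, 60)
    fit <- reml_fit(y, X, A)
    c(fit$sigma2_g, fit$sigma2_e)
  })
  expect_lt(abs(mean(devs[1, ]) - 40), 3 * sd(devs[1, ]) / sqrt(12))
  expect_lt(abs(mean(devs[2, ]) - 60), 3 * sd(devs[2, ]) / sqrt(12))
})

test_that("rank-deficient designs are rejected with the offending column", {
  n <- 12
  X <- cbind(a = rep(1, n), b = rep(2, n))
  expect_error(reml_fit(rnorm(n), X, diag(n)), "aliased")
})

test_that("pedigree-block random effect has the block eigenstructure", {
  pid <- rep(c("p1", "p2", "p3"), times = c(5, 3, 4))
  B <- hlmkin:::pedigree_block_matrix(pid)
  ev <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  expect_equal(ev[1:3], c(5, 4, 3))
  expect_equal(ev[-(1:3)], rep(0, 9))
  # single pedigree: compound symmetry fit runs and returns a valid object
  set.seed(106)
  y <- rnorm(12, 5)
  # eigen() on the exact block-of-ones matrix yields a ~ -1e-15 eigenvalue,
  # which the PSD guard clips with a warning
  fit <- suppressWarnings(
    reml_fit_pedigree_random(y, matrix(1, 12, 1), rep("p1", 12)))
  expect_s3_class(fit, "lmm_fit")
  expect_gte(fit$sigma2_g, 0)
})

test_that("snp_association flags monomorphic SNPs and recovers causal effects", {
  set.seed(107)
  cfg <- sim_config(n_pedigrees = 6, pedigree_size_range = c(27, 45),
                    n_snps = 3,
                    causal = data.frame(snp = 2, maf = 0.3,
                                        gamma01 = -8, gamma11 = 0))
  coh <- simulate_cohort(cfg)
  coh$genotypes$dosage[, 1] <- 0           # force monomorphic
  A <- kinship_matrix(coh$pedigrees, scale = "relationship")
  adj <- adjust_covariates(coh$phenotypes, c("smoke", "med"))
  tr <- flag_outliers(fit_individual_trajectories(adj, 42))
  res <- snp_association(tr, coh$genotypes, A, phenotype = "level")
  expect_equal(res$note[1], "monomorphic")
  expect_true(is.na(res$beta[1]))
  expect_equal(res$p[1], 1)
  causal <- res[2, ]
  expect_equal(causal$chi2, (causal$beta / causal$se)^2)
  expect_lt(abs(causal$beta - (-8)), 3 * causal$se)
  expect_true(all(res$p > 0 & res$p <= 1))
})

test_that("missing dosages drop individuals for that SNP only", {
  set.seed(108)
  cfg <- sim_config(n_pedigrees = 3, pedigree_size_range = c(10, 15),
                    n_snps = 2)
  coh <- simulate_cohort(cfg)
  n <- nrow(coh$genotypes$dosage)
  coh$genotypes$dosage[1:3, 2] <- NA
  A <- kinship_matrix(coh$pedigrees, scale = "relationship")
  tr <- flag_outliers(fit_individual_trajectories(coh$phenotypes, 42))
  res <- snp_association(tr, coh$genotypes, A, phenotype = "level")
  expect_equal(res$n_used[2], res$n_used[1] - 3)
})
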