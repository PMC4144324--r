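# Independent oracles used by the unit and acceptance tests.  Both are
# deliberately written against the definitions, not against the package's
# computational path.

# Monte-Carlo gene dropping: founders get uniquely labelled allele pairs,
# each offspring inherits one uniformly chosen allele per parent, and the
# kinship coefficient of (i, j) is estimated as the probability that one
# allele drawn from i and one from j carry the same founder label.
# Returns the estimate matrix and its per-pair Monte-Carlo standard error.
gene_drop_kinship <- function(ped, n_drops) {
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  A1 <- A2 <- matrix(0L, n_drops, n)
  for (i in seq_len(n)) {
    A1[, i] <- if (is.na(fi[i])) rep.int(4L * i - 3L, n_drops) else
      ifelse(stats::runif(n_drops) < 0.5, A1[, fi[i]], A2[, fi[i]])
    A2[, i] <- if (is.na(mi[i])) rep.int(4L * i - 2L, n_drops) else
      ifelse(stats::runif(n_drops) < 0.5, A1[, mi[i]], A2[, mi[i]])
  }
  phi <- se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    v <- ((A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
            (A2[, i] == A1[, j]) + (A2[, i] == A2[, j])) / 4
    phi[i, j] <- phi[j, i] <- mean(v)
    se[i, j] <- se[j, i] <- stats::sd(v) / sqrt(n_drops)
  }
  list(phi = phi, se = se)
}

# Restricted log-likelihood by direct dense covariance inversion (the
# definition the eigen-rotated profile must reproduce).  Includes the
# +log|X'X|/2 term so it is comparable across parameterizations.
dense_reml_ll <- function(sigma2_g, sigma2_e, y, X, A) {
  n <- length(y); p <- ncol(X)
  V <- sigma2_g * A + sigma2_e * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) -
            as.numeric(determinant(crossprod(X))$modulus) +
            drop(t(r) %*% Vi %*% r))
}

# Brute-force REML: log-grid over (sigma2_g, sigma2_e) with repeated
# zoom-in refinement of the dense-inversion likelihood, then a final
# Nelder-Mead polish from the refined grid optimum.
dense_reml_fit <- function(y, X, A) {
  vy <- stats::var(y)
  ctr <- log(c(vy / 2, vy / 2))
  span <- log(10^4)
  best <- ctr; best_ll <- -Inf
  for (round in 1:6) {
    gs <- best[1] + seq(-span, span, length.out = 21)
    es <- best[2] + seq(-span, span, length.out = 21)
    for (lg in gs) for (le in es) {
      ll <- dense_reml_ll(exp(lg), exp(le), y, X, A)
      if (ll > best_ll) { best_ll <- ll; best <- c(lg, le) }
    }
    span <- span / 8
  }
  opt <- stats::optim(best, function(lp)
    -dense_reml_ll(exp(lp[1]), exp(lp[2]), y, X, A),
    method = "Nelder-Mead",
    control = list(reltol = 1e-15, maxit = 20000))
  list(sigma2_g = exp(opt$par[1]), sigma2_e = exp(opt$par[2]),
       loglik = -opt$value)
}

# Small labelled pedigrees reused across tests -------------------------------

trio_pedigree <- function() {
  new_pedigree("F1", c("P", "M", "C"), c(NA, NA, "P"), c(NA, NA, "M"),
               c(1L, 2L, 1L))
}

# two founder parents, two full sibs, and a cousin branch:
# G1: A,B and C,D; G2: sibs S1,S2 (AxB) and S3 (CxD) marrying S2;
# G3: K1 (S1 x E), K2 (S2 x S3) -> K1, K2 are first cousins
cousin_pedigree <- function() {
  id <- c("A", "B", "C", "D", "E", "S1", "S2", "S3", "K1", "K2")
  fa <- c(NA, NA, NA, NA, NA, "A", "A", "C", "S1", "S3")
  mo <- c(NA, NA, NA, NA, NA, "B", "B", "D", "E", "S2")
  sx <- c(1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L, 1L, 2L)
  new_pedigree("F1", id, fa, mo, sx)
}

# 12-member, 3-generation pedigree for the gene-dropping comparison
three_gen_pedigree <- function() {
  id <- c("F1", "M1", "F2", "M2", "S1", "S2", "W1", "S3", "C1", "C2", "C3",
          "C4")
  fa <- c(NA, NA, NA, NA, "F1", "F1", NA, "F2", "S1", "S1", "S3", "S3")
  mo <- c(NA, NA, NA, NA, "M1", "M1", NA, "M2", "W1", "W1", "S2", "S2")
  sx <- c(1L, 2L, 1L, 2L, 1L, 2L, 2L, 1L, 1L, 2L, 1L, 2L)
  new_pedigree("PED3G", id, fa, mo, sx)
}

# n individuals split into sib-quads (used for small LMM problems): block
# diagonal relationship matrix, diag 1, 0.5 within each quad.
sib_quad_relationship <- function(n) {
  stopifnot(n %% 4 == 0)
  blk <- matrix(0.5, 4, 4); diag(blk) <- 1
  A <- matrix(0, n, n)
  for (b in seq_len(n / 4)) {
    idx <- (b - 1) * 4 + 1:4
    A[idx, idx] <- blk
  }
  structure(A, scale = "relationship")
}

# draw y from the mixed model given a relationship matrix
draw_mixed <- function(X, gamma, A, sigma2_g, sigma2_e) {
  n <- nrow(A)
  E <- eigen(A, symmetric = TRUE)
  u <- drop(E$vectors %*% (sqrt(pmax(E$values, 0) * sigma2_g) * rnorm(n)))
  drop(X %*% gamma) + u + rnorm(n, 0, sqrt(sigma2_e))
}
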