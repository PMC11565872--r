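# Per-variant logistic regression for genotype matrices.
#
# Without covariates the likelihood of the model logit P(y=1) = b0 + b1*g
# depends on the data only through the six counts of genotype {0,1,2} by
# case status, so Newton-Raphson runs vectorized across all variants on
# those counts: each iteration costs O(variants), not O(individuals x
# variants), and the result equals a glm() fit to machine precision. With
# covariates the per-variant design no longer collapses to counts and each
# variant is fitted with stats::glm.fit().

# Sufficient statistics per variant: counts n0,n1,n2 of genotypes and case
# counts y0,y1,y2 within each genotype class. Chunked over columns to keep
# the logical indicator matrices small.
genotype_case_counts <- function(G, y, chunk = 2000L) {
  m <- ncol(G)
  n1 <- n2 <- y1 <- y2 <- numeric(m)
  for (start in seq(1L, m, by = chunk)) {
    j <- start:min(start + chunk - 1L, m)
    Gc <- G[, j, drop = FALSE]
    I1 <- Gc == 1L
    I2 <- Gc == 2L
    n1[j] <- colSums(I1)
    n2[j] <- colSums(I2)
    y1[j] <- as.vector(crossprod(I1, y))
    y2[j] <- as.vector(crossprod(I2, y))
  }
  n <- nrow(G)
  sy <- sum(y)
  list(n0 = n - n1 - n2, n1 = n1, n2 = n2,
       y0 = sy - y1 - y2, y1 = y1, y2 = y2, n = n, sy = sy)
}

# Vectorized Newton-Raphson on the genotype-count sufficient statistics.
# Returns beta, se and a convergence flag per variant; monomorphic or
# separated variants come back NA.
logistic_newton_counts <- function(G, y, maxit = 50L, tol = 1e-10) {
  cc <- genotype_case_counts(G, y)
  m <- ncol(G)
  b0 <- rep(stats::qlogis(cc$sy / cc$n), m)
  b1 <- numeric(m)
  sy1 <- cc$y1 + 2 * cc$y2

  # monomorphic: genotype has a single observed value
  mono <- (cc$n1 + cc$n2 == 0) | (cc$n0 + cc$n2 == 0) | (cc$n0 + cc$n1 == 0)
  # complete separation on the genotype margin: the minor genotype classes
  # are all cases or all controls
  active <- !mono

  S0 <- S1 <- det <- rep(NA_real_, m)
  for (it in seq_len(maxit)) {
    mu0 <- stats::plogis(b0)
    mu1 <- stats::plogis(b0 + b1)
    mu2 <- stats::plogis(b0 + 2 * b1)
    w0 <- cc$n0 * mu0 * (1 - mu0)
    w1 <- cc$n1 * mu1 * (1 - mu1)
    w2 <- cc$n2 * mu2 * (1 - mu2)
    S0 <- w0 + w1 + w2
    S1 <- w1 + 2 * w2
    S2 <- w1 + 4 * w2
    t0 <- cc$sy - (cc$n0 * mu0 + cc$n1 * mu1 + cc$n2 * mu2)
    t1 <- sy1 - (cc$n1 * mu1 + 2 * cc$n2 * mu2)
    det <- S0 * S2 - S1 * S1
    db0 <- ifelse(active & det > 0, (S2 * t0 - S1 * t1) / det, 0)
    db1 <- ifelse(active & det > 0, (S0 * t1 - S1 * t0) / det, 0)
    b0 <- b0 + db0
    b1 <- b1 + db1
    if (max(abs(c(db0, db1))) < tol) break
  }
  converged <- active & det > 0 & abs(b1) < 15 & is.finite(b1)
  beta <- ifelse(converged, b1, NA_real_)
  se <- ifelse(converged, sqrt(S0 / det), NA_real_)
  data.frame(beta = beta, se = se, converged = converged)
}

# Per-variant glm.fit() with a shared covariate design.
logistic_glm_covariates <- function(G, y, covar, maxit = 25L) {
  m <- ncol(G)
  n <- nrow(G)
  X <- cbind(`(Intercept)` = 1, genotype = 0, covar)
  beta <- se <- rep(NA_real_, m)
  converged <- logical(m)
  fam <- stats::binomial()
  for (j in seq_len(m)) {
    g <- G[, j]
    if (length(unique(g)) < 2L) next
    X[, 2L] <- g
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = fam,
                     control = stats::glm.control(maxit = maxit)))
    if (!fit$converged) next
    b <- fit$coefficients[2L]
    if (!is.finite(b) || abs(b) > 15) next
    # Wald SE from the unscaled covariance of the IRLS solve
    R <- fit$qr$qr[seq_len(fit$qr$rank), seq_len(fit$qr$rank), drop = FALSE]
    R[lower.tri(R)] <- 0
    cov <- chol2inv(R)
    pos <- match(2L, fit$qr$pivot)
    beta[j] <- b
    se[j] <- sqrt(cov[pos, pos])
    converged[j] <- TRUE
  }
  data.frame(beta = beta, se = se, converged = converged)
}
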