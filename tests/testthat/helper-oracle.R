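# Independent quadrature oracle: mode-centered Gauss-Hermite integration of
# the exact integrand (logistic likelihood x point-normal slab on active
# SNPs x broad intercept prior). Used to certify the closed-form
# quasi-Laplace configuration marginals. Kept free of any package
# internals beyond exported genotype utilities.

oracle_log1pexp <- function(x) ifelse(x > 33, x, log1p(exp(x)))

# Golub-Welsch Gauss-Hermite nodes/weights
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Newton mode of g(beta) = logL(beta) + log N(beta | 0, diag(pvar))
oracle_mode <- function(phi, XA, pvar) {
  b <- numeric(ncol(XA))
  H <- NULL
  for (it in 1:100) {
    eta <- drop(XA %*% b)
    p <- plogis(eta)
    gr <- drop(crossprod(XA, phi - p)) - b / pvar
    H <- crossprod(XA * sqrt(p * (1 - p))) + diag(1 / pvar, length(b))
    if (max(abs(gr)) < 1e-10) break
    b <- b + solve(H, gr)
  }
  list(m = b, H = H)
}

# log int exp(g(beta)) dbeta by GH product quadrature centered and scaled
# at the mode, evaluated in chunks to bound memory
oracle_gh_log_integral <- function(phi, XA, pvar, nodes = 12) {
  d <- ncol(XA)
  gh <- gauss_hermite(nodes)
  mh <- oracle_mode(phi, XA, pvar)
  A <- t(chol(solve(mh$H)))
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(nodes)), d)))
  tmat <- matrix(gh$x[idx], ncol = d)
  lw <- rowSums(matrix(log(gh$w[idx]) + gh$x[idx]^2, ncol = d))
  B <- mh$m + sqrt(2) * A %*% t(tmat)
  npts <- ncol(B)
  gv <- numeric(npts)
  chunk <- 20000
  for (s in seq(1, npts, chunk)) {
    e <- min(s + chunk - 1, npts)
    Eta <- XA %*% B[, s:e, drop = FALSE]
    gv[s:e] <- colSums(phi * Eta - oracle_log1pexp(Eta)) +
      colSums(dnorm(B[, s:e, drop = FALSE], 0, sqrt(pvar), log = TRUE))
  }
  v <- lw + gv
  m <- max(v)
  (d / 2) * log(2) + sum(log(diag(A))) + m + log(sum(exp(v - m)))
}

# oracle value of log p(c | pi, sigma) + log of the exact Eq-style integral
oracle_config_value <- function(phi, X, cfg, hp, nodes = 12) {
  I <- ncol(X) - 1
  act <- c(1L, cfg + 1L)
  pvar <- c(100, rep(hp$sigma^2, length(cfg)))
  k <- length(cfg)
  k * log(hp$pi) + (I - k) * log(1 - hp$pi) +
    oracle_gh_log_integral(phi, X[, act, drop = FALSE], pvar, nodes)
}

# max per-config |implementation - oracle| after null-config matching
oracle_instance_error <- function(n, n_snps, seed, sigma_tilde, h2,
                                  hp = hyperparameters(0.1, 0.1),
                                  nodes = 12, ld_rho = 0.5) {
  g <- generate_genotypes(n, 1, n_snps, ld_rho = ld_rho, seed = seed)
  cs <- list(sample_causal_snps(1, n_snps, 1e-9, TRUE, seed)[[1]])
  sim <- simulate_phenotype(g, cs, h2 = h2, seed = seed)
  X <- cbind(1, g$normalized)
  fit <- fit_regularized_mode(sim$phenotype, X, sigma_tilde)
  bl <- locus_blocks(combine_studies(list(fit)))[[1]]
  cfgs <- enumerate_configs(n_snps, n_snps)
  impl <- vapply(cfgs, function(cf) config_log_joint(bl, cf, hp), numeric(1))
  orc <- vapply(cfgs, function(cf)
    oracle_config_value(sim$phenotype, X, cf, hp, nodes), numeric(1))
  max(abs((impl - impl[1]) - (orc - orc[1]))[-1])
}
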