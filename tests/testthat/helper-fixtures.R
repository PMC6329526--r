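# Small in-code fixtures shared across test files.

# one simulated case-control dataset with locus structure
make_dataset <- function(n = 600, n_loci = 2, snps_per_locus = 6,
                         h2 = 0.2, ld_rho = 0.5, seed = 1,
                         pi_sim = 0.05) {
  geno <- generate_genotypes(n, n_loci, snps_per_locus, ld_rho = ld_rho,
                             seed = seed)
  cs <- sample_causal_snps(n_loci, snps_per_locus, pi_sim, TRUE, seed)
  sim <- simulate_phenotype(geno, cs, h2 = h2, seed = seed)
  list(geno = geno, phi = sim$phenotype, truth = sim$truth,
       X = cbind(1, geno$normalized),
       blocks = unname(split(seq_len(geno$n_snps), geno$locus)))
}

# locus evidence blocks straight from one fit
fit_blocks <- function(d, sigma_tilde = 0.05, method = "logistic") {
  fit <- fit_regularized_mode(d$phi, d$X, sigma_tilde, blocks = d$blocks,
                              method = method)
  locus_blocks(combine_studies(list(fit)))
}

# pure-R reference for the closed-form configuration log joint, written
# with dense base-R linear algebra, independent of the C++ kernel
r_config_log_joint <- function(block, cfg, hp) {
  I <- block$n_snps
  k <- length(cfg)
  act <- c(1L, cfg + 1L)
  pvar <- c(100, rep(hp$sigma^2, k))
  Q <- block$M[act, act, drop = FALSE] + diag(1 / pvar, k + 1)
  ba <- block$b[act]
  val <- k * log(hp$pi) + (I - k) * log(1 - hp$pi) -
    0.5 * k * log(hp$sigma^2) -
    0.5 * as.numeric(determinant(Q)$modulus) +
    0.5 * sum(ba * solve(Q, ba))
  pi0 <- 1 / max(I, 2)
  q0 <- block$M[1, 1] + 1 / 100
  ref <- I * log(1 - pi0) - 0.5 * log(q0) + 0.5 * block$b[1]^2 / q0
  val - ref
}

# pure-R posterior by explicit enumeration and normalization
r_brute_posterior <- function(block, hp, cmax) {
  cfgs <- enumerate_configs(block$n_snps, cmax)
  lj <- vapply(cfgs, function(cf) r_config_log_joint(block, cf, hp),
               numeric(1))
  w <- exp(lj - max(lj)); w <- w / sum(w)
  pip <- numeric(block$n_snps)
  for (i in seq_along(cfgs)) pip[cfgs[[i]]] <- pip[cfgs[[i]]] + w[i]
  list(weights = w, pip = pip, pr_causal = 1 - w[1])
}
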