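# configuration enumeration, closed-form marginals, study pooling

test_that("enumerate_configs counts and orders configurations correctly", {
  cfg <- enumerate_configs(3, 3)
  expect_length(cfg, 8)
  expect_equal(cfg[[1]], integer(0))
  expect_length(enumerate_configs(4, 0), 1)
  expect_error(enumerate_configs(3, -1), "cmax")
  # size non-decreasing, lexicographic within size
  for (n in c(4, 6)) {
    cc <- enumerate_configs(n, 3)
    sizes <- lengths(cc)
    expect_true(all(diff(sizes) >= 0))
    expect_length(cc, sum(choose(n, 0:3)))
    for (k in 1:3) {
      keys <- vapply(cc[sizes == k], function(x)
        paste(sprintf("%02d", x), collapse = ","), character(1))
      expect_equal(keys, sort(keys))                            # lexicographic
    }
  }
})

test_that("config_log_joint obeys the closed-form prior identities", {
  d <- make_dataset(seed = 20)
  bl <- fit_blocks(d)[[1]]
  I <- bl$n_snps
  sig <- 0.1
  # null config at two pi values differs by I log((1-pi1)/(1-pi2))
  v1 <- config_log_joint(bl, integer(0), hyperparameters(0.02, sig))
  v2 <- config_log_joint(bl, integer(0), hyperparameters(0.2, sig))
  expect_equal(v1 - v2, I * log((1 - 0.02) / (1 - 0.2)), tolerance = 1e-10)
  # monotone prior effect for any config, in closed form
  cfg <- c(2L, 5L)
  for (pis in list(c(0.01, 0.05), c(0.05, 0.3))) {
    dv <- config_log_joint(bl, cfg, hyperparameters(pis[2], sig)) -
      config_log_joint(bl, cfg, hyperparameters(pis[1], sig))
    expected <- 2 * (log(pis[2] / (1 - pis[2])) - log(pis[1] / (1 - pis[1]))) +
      I * (log(1 - pis[2]) - log(1 - pis[1]))
    expect_equal(dv, expected, tolerance = 1e-10)
  }
  # binary-vector and index representations agree
  cvec <- integer(I); cvec[c(2, 5)] <- 1L
  expect_equal(config_log_joint(bl, cvec, hyperparameters(0.1, sig)),
               config_log_joint(bl, cfg, hyperparameters(0.1, sig)))
})

test_that("a vanishing slab collapses every config onto the null plus its prior offset", {
  d <- make_dataset(seed = 21)
  bl <- fit_blocks(d)[[1]]
  pi <- 0.1
  null_v <- config_log_joint(bl, integer(0), hyperparameters(pi, 1e-6))
  for (cfg in list(1L, c(1L, 4L), c(2L, 3L, 6L))) {
    v <- config_log_joint(bl, cfg, hyperparameters(pi, 1e-6))
    expect_equal(v, null_v + length(cfg) * log(pi / (1 - pi)),
                 tolerance = 1e-3)
  }
})

test_that("config values are invariant under consistent SNP relabeling", {
  d <- make_dataset(seed = 22)
  bl <- fit_blocks(d)[[1]]
  hp <- hyperparameters(0.05, 0.15)
  set.seed(1)
  perm <- sample(bl$n_snps)
  blp <- bl
  pidx <- c(1L, perm + 1L)
  blp$M <- bl$M[pidx, pidx]
  blp$b <- bl$b[pidx]
  for (cfg in list(2L, c(1L, 5L), c(2L, 4L, 6L))) {
    expect_equal(config_log_joint(bl, cfg, hp),
                 config_log_joint(blp, sort(match(cfg, perm)), hp),
                 tolerance = 1e-10)
  }
})

test_that("combine_studies implements exact precision-weighted pooling", {
  d <- make_dataset(n = 400, seed = 23)
  n1 <- 1:200; n2 <- 201:400
  f1 <- fit_regularized_mode(d$phi[n1], d$X[n1, ], 0.1, blocks = d$blocks)
  f2 <- fit_regularized_mode(d$phi[n2], d$X[n2, ], 0.2, blocks = d$blocks)
  # single study: identity
  c1 <- combine_studies(list(f1))
  expect_equal(c1$lambda_blocks, f1$lambda_blocks)
  for (b in seq_along(d$blocks)) {
    idx <- c(1L, d$blocks[[b]] + 1L)
    expect_equal(c1$beta_blocks[[b]], f1$beta[idx], tolerance = 1e-10)
  }
  # two identical studies: precision doubles, mode unchanged
  c2 <- combine_studies(list(f1, f1))
  expect_equal(c2$lambda_blocks[[1]], 2 * f1$lambda_blocks[[1]])
  expect_equal(c2$beta_blocks[[2]], f1$beta[c(1L, d$blocks[[2]] + 1L)],
               tolerance = 1e-10)
  # dense linear-algebra oracle on a random 2-study pooling
  cc <- combine_studies(list(f1, f2))
  for (b in seq_along(d$blocks)) {
    idx <- c(1L, d$blocks[[b]] + 1L)
    L1 <- f1$lambda_blocks[[b]]; L2 <- f2$lambda_blocks[[b]]
    expect_equal(cc$beta_blocks[[b]],
                 drop(solve(L1 + L2, L1 %*% f1$beta[idx] + L2 %*% f2$beta[idx])),
                 tolerance = 1e-10)
  }
  expect_equal(cc$dsnp_total, 1 / 0.1^2 + 1 / 0.2^2)
})

test_that("combine_studies validates SNP sets and alleles", {
  d <- make_dataset(seed = 24)
  f1 <- fit_regularized_mode(d$phi, d$X, 0.1, blocks = d$blocks)
  f1$snps <- d$geno$snps
  f2 <- f1
  f2$snps$id[3] <- "other_snp"
  expect_error(combine_studies(list(f1, f2)), "SNP sets differ")
  f3 <- f1
  f3$snps$a0[2] <- "B"; f3$snps$a1[2] <- "A"
  expect_error(combine_studies(list(f1, f3)), "flip")
  f4 <- f1
  f4$blocks <- list(f1$blocks[[1]])
  f4$lambda_blocks <- list(f1$lambda_blocks[[1]])
  expect_error(combine_studies(list(f1, f4)), "block structure")
})

test_that("locus_log_marginal is a stable logsumexp over enumerated configs", {
  d <- make_dataset(seed = 25)
  bl <- fit_blocks(d)[[1]]
  hp <- hyperparameters(0.05, 0.1)
  cfgs <- enumerate_configs(bl$n_snps, 2)
  vals <- vapply(cfgs, function(cf) config_log_joint(bl, cf, hp), numeric(1))
  lm <- locus_log_marginal(bl, hp, cmax = 2)
  expect_gte(lm, max(vals))
  m <- max(vals)
  expect_equal(lm, m + log(sum(exp(vals - m))), tolerance = 1e-10)
  # conservative pruning changes the marginal negligibly
  lmp <- locus_log_marginal(bl, hp, cmax = 2, prune_log_width = 30)
  expect_equal(lmp, lm, tolerance = 1e-6)
  expect_lte(lmp, lm + 1e-12)
})

test_that("the marginal factorizes over loci with decoupled intercepts", {
  # construct two artificial locus blocks and their concatenation with an
  # intercept uncoupled from the SNPs, so factorization is exact
  set.seed(26)
  mk <- function(k) {
    A <- crossprod(matrix(rnorm(k * k), k)) + diag(k) * 2
    b <- rnorm(k)
    list(A = A, b = b)
  }
  a <- mk(2); b2 <- mk(2)
  q0 <- 5; b0 <- 0.7
  blA <- list(M = rbind(c(q0, 0, 0), cbind(0, a$A)), b = c(b0, a$b),
              n_snps = 2L, method = "logistic")
  blB <- list(M = rbind(c(q0, 0, 0), cbind(0, b2$A)), b = c(b0, b2$b),
              n_snps = 2L, method = "logistic")
  MJ <- matrix(0, 5, 5)
  MJ[1, 1] <- q0
  MJ[2:3, 2:3] <- a$A
  MJ[4:5, 4:5] <- b2$A
  blJ <- list(M = MJ, b = c(b0, a$b, b2$b), n_snps = 4L, method = "logistic")
  hp <- hyperparameters(0.1, 0.3)
  rel <- function(bl, cmax) {
    locus_log_marginal(bl, hp, cmax) -
      config_log_joint(bl, integer(0), hp)
  }
  # full enumeration on both sides so the config sets correspond exactly
  expect_equal(rel(blJ, 4), rel(blA, 2) + rel(blB, 2), tolerance = 1e-10)
})

test_that("linear comparator shares the constant convention and flags misuse", {
  d <- make_dataset(seed = 27)
  bl_log <- fit_blocks(d, method = "logistic")[[1]]
  bl_lin <- fit_blocks(d, method = "linear")[[1]]
  hp <- hyperparameters(0.07, 0.12)
  expect_error(config_log_joint_linear(bl_log, 1L, hp), "linear")
  # null config value depends only on the prior: identical across methods
  expect_equal(config_log_joint_linear(bl_lin, integer(0), hp),
               config_log_joint(bl_log, integer(0), hp), tolerance = 1e-10)
})

test_that("linear and quasi-Laplace scores agree near balance and diverge under imbalance", {
  rho_for <- function(imbalanced, seed) {
    g <- generate_genotypes(4000, 1, 10, ld_rho = 0.6, seed = seed)
    cs <- sample_causal_snps(1, 10, 0.1, TRUE, seed)
    sim <- simulate_phenotype(g, cs, h2 = 0.05, seed = seed)
    keep <- if (imbalanced) {
      ascertain(sim$phenotype, 0.25, "fix_cases", n_cases = 350, seed = seed)
    } else {
      seq_len(4000)
    }
    raw <- g$raw[keep, , drop = FALSE]
    X <- cbind(1, normalize_genotypes(raw, colMeans(raw) / 2))
    ph <- sim$phenotype[keep]
    hp <- hyperparameters(0.1, 0.15)
    cfgs <- enumerate_configs(10, 2)[-1]
    sc <- function(meth) {
      f <- fit_regularized_mode(ph, X, 0.2, method = meth)
      bl <- locus_blocks(combine_studies(list(f)))[[1]]
      vapply(cfgs, function(cf) config_log_joint(bl, cf, hp), numeric(1))
    }
    cor(sc("logistic"), sc("linear"), method = "spearman")
  }
  rb <- vapply(1:3, function(s) rho_for(FALSE, 30 + s), numeric(1))
  ri <- vapply(1:3, function(s) rho_for(TRUE, 30 + s), numeric(1))
  expect_true(all(rb > 0.95))        # near-balance: linear regime
  expect_lt(mean(ri), mean(rb))      # imbalance degrades rank agreement
})
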