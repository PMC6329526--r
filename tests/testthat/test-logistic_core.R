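# logistic likelihood, derivatives, regularized mode, regularizer choice

test_that("predict_risk matches the closed form and is overflow-safe", {
  X <- cbind(1, matrix(rnorm(20), 10, 2))
  expect_equal(predict_risk(X, c(0, 0, 0)), rep(0.5, 10))
  expect_equal(predict_risk(matrix(1), log(3)), 0.75)
  set.seed(1)
  beta <- rnorm(3)
  expect_equal(predict_risk(X, beta) + predict_risk(X, -beta), rep(1, 10))
  # |eta| up to 1e3 stays finite and in (0,1)
  p <- predict_risk(matrix(c(1, 1)), 1e3)
  expect_true(all(is.finite(p) & p > 0 & p <= 1))
  expect_equal(predict_risk(matrix(1), -1e3), 0)
})

test_that("log_likelihood agrees with the explicit product form", {
  X <- cbind(1, matrix(rnorm(30), 15, 2))
  phi <- rbinom(15, 1, 0.5)
  expect_equal(log_likelihood(phi, X, c(0, 0, 0)), 15 * log(0.5))
  expect_equal(log_likelihood(1, matrix(1), log(3)), log(0.75))
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    Xr <- cbind(1, matrix(rnorm(2 * n), n, 2))
    phir <- rbinom(n, 1, 0.5)
    br <- rnorm(3, 0, 0.5)
    p <- predict_risk(Xr, br)
    expect_equal(log_likelihood(phir, Xr, br),
                 log(prod(p^phir * (1 - p)^(1 - phir))), tolerance = 1e-10)
  }
})

test_that("log_likelihood_grad matches finite differences and saturates", {
  set.seed(3)
  n <- 40
  # duplicated design with complementary phenotypes: each centered column
  # sums to zero within cases and within controls, so at beta = 0 the
  # residual phi - 1/2 annihilates every SNP column exactly
  Z <- scale(matrix(rnorm(3 * n / 2), n / 2, 3), scale = FALSE)
  X <- cbind(1, rbind(Z, Z))
  phi <- rep(c(1L, 0L), each = n / 2)
  g0 <- log_likelihood_grad(phi, X, rep(0, 4))
  expect_lt(max(abs(g0[-1])), 1e-10)
  for (rep in 1:3) {
    beta <- rnorm(4, 0, 0.3)
    g <- log_likelihood_grad(phi, X, beta)
    h <- 1e-5
    fd <- vapply(1:4, function(j) {
      e <- numeric(4); e[j] <- h
      (log_likelihood(phi, X, beta + e) - log_likelihood(phi, X, beta - e)) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-6)
  }
  # at a data-separating beta scaled up, residuals phi - p saturate to 0
  Xsep <- cbind(1, c(-2, -1, 1, 2))
  phisep <- c(0L, 0L, 1L, 1L)
  bsep <- c(0, 1)
  expect_lt(sqrt(sum(log_likelihood_grad(phisep, Xsep, bsep * 10)^2)),
            sqrt(sum(log_likelihood_grad(phisep, Xsep, bsep)^2)))
})

test_that("fit_regularized_mode finds the regularized mode with exact curvature", {
  # balanced intercept-only fit is exactly 0
  phi <- rep_len(c(0L, 1L), 50)
  f0 <- fit_regularized_mode(phi, matrix(1, 50, 1), 0.1)
  expect_equal(f0$beta, 0, tolerance = 1e-8)

  d <- make_dataset(n = 300, n_loci = 1, snps_per_locus = 4, h2 = 0.2, seed = 6)
  fit <- fit_regularized_mode(d$phi, d$X, 0.2)
  dprec <- c(1 / 100, rep(1 / 0.2^2, 4))
  obj <- function(b) log_likelihood(d$phi, d$X, b) - 0.5 * sum(dprec * b^2)
  # gradient at the mode is tiny
  gmode <- log_likelihood_grad(d$phi, d$X, fit$beta) - dprec * fit$beta
  expect_lt(max(abs(gmode)), 1e-6)
  # lambda_tilde equals the negated finite-difference Hessian at the mode
  h <- 1e-4
  H <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    ei <- numeric(5); ei[i] <- h
    ej <- numeric(5); ej[j] <- h
    H[i, j] <- (obj(fit$beta + ei + ej) - obj(fit$beta + ei - ej) -
                obj(fit$beta - ei + ej) + obj(fit$beta - ei - ej)) / (4 * h^2)
  }
  expect_equal(fit$lambda_full, -H, tolerance = 1e-4)

  # infinite regularization shrinks SNP effects to 0
  tight <- fit_regularized_mode(d$phi, d$X, 1e-4)
  expect_lt(sqrt(sum(tight$beta[-1]^2)), 1e-4)
  expect_error(fit_regularized_mode(d$phi, d$X, -1), "sigma_tilde")
  expect_error(fit_regularized_mode(d$phi, d$X, 0.2, max_iter = 1),
               "convergence")
})

test_that("fit is invariant to sample order and strictly concave in practice", {
  d <- make_dataset(n = 250, n_loci = 2, snps_per_locus = 4, h2 = 0.3, seed = 7)
  fit <- fit_regularized_mode(d$phi, d$X, 0.15)
  set.seed(8)
  perm <- sample(250)
  fit2 <- fit_regularized_mode(d$phi[perm], d$X[perm, ], 0.15)
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-10)
  expect_true(all(eigen(fit$lambda_full, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  expect_equal(fit$lambda_full, t(fit$lambda_full), tolerance = 1e-8)
})

test_that("block-Newton fit matches the dense fit and stores per-locus curvature", {
  d <- make_dataset(n = 400, n_loci = 3, snps_per_locus = 5, h2 = 0.3, seed = 9)
  dense <- fit_regularized_mode(d$phi, d$X, 0.1)
  blocked <- fit_regularized_mode(d$phi, d$X, 0.1, blocks = d$blocks)
  expect_equal(blocked$beta, dense$beta, tolerance = 1e-6)
  # each stored block is the corresponding sub-matrix of the dense Hessian
  for (b in seq_along(d$blocks)) {
    idx <- c(1L, d$blocks[[b]] + 1L)
    expect_equal(blocked$lambda_blocks[[b]], dense$lambda_full[idx, idx],
                 tolerance = 1e-5)
  }
})

test_that("linear-approximation fit freezes curvature at beta = 0", {
  d <- make_dataset(n = 300, n_loci = 1, snps_per_locus = 4, h2 = 0.2, seed = 10)
  lin <- fit_regularized_mode(d$phi, d$X, 0.2, method = "linear")
  dprec <- c(1 / 100, rep(1 / 0.2^2, 4))
  # lambda - D is exactly X'X/4: the scaled LD matrix of the linear model
  expect_equal(lin$lambda_full - diag(dprec), crossprod(d$X) / 4,
               tolerance = 1e-10)
  expect_equal(drop(lin$lambda_full %*% lin$beta),
               drop(crossprod(d$X, d$phi - 0.5)), tolerance = 1e-8)
})

test_that("optimize_regularizer honors user override and matches a grid search", {
  d <- make_dataset(n = 400, n_loci = 1, snps_per_locus = 5, h2 = 0.25, seed = 12)
  # pass-through contract
  out <- optimize_regularizer(d$phi, d$X, sigma_tilde = 0.123)
  expect_identical(out$sigma_tilde, 0.123)
  # grid-search oracle: optimum within one log-spaced grid step
  opt <- suppressWarnings(optimize_regularizer(d$phi, d$X))
  grid <- exp(seq(log(1e-3), log(1), length.out = 50))
  ev <- vapply(grid, function(s) {
    f <- fit_regularized_mode(d$phi, d$X, s)
    blore:::laplace_evidence(d$phi, d$X, f)
  }, numeric(1))
  step <- diff(log(grid))[1]
  expect_lt(abs(log(opt$sigma_tilde) - log(grid[which.max(ev)])),
            step + 1e-8)
})

test_that("strong genetic signal raises the fitted regularizer above permuted data", {
  wins <- 0L
  for (s in 1:20) {
    d <- make_dataset(n = 300, n_loci = 1, snps_per_locus = 5, h2 = 0.4,
                      seed = 100 + s, pi_sim = 0.4)
    st1 <- suppressWarnings(optimize_regularizer(d$phi, d$X))$sigma_tilde
    set.seed(s)
    st0 <- suppressWarnings(
      optimize_regularizer(sample(d$phi), d$X))$sigma_tilde
    wins <- wins + (st1 > st0)
  }
  expect_gt(wins, 10)
})
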