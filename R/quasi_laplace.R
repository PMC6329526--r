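# Causality configurations and their closed-form quasi-Laplace marginals.
#
# Per locus, the regularized likelihood (pooled over studies) is the
# Gaussian N(beta | beta~, Lambda~^{-1}). Dividing out the ridge
# regularizer(s) and multiplying the point-normal slab restricted to a
# configuration's causal subspace leaves a Gaussian integral with a closed
# form. All values are reported relative to the null configuration at
# reference hyperparameters (pi0 = 1/I, sigma0 = 0.01), which pins the
# arbitrary additive constant identically for every configuration and every
# (pi, sigma).

#' Spike-and-slab hyperparameters
#'
#' `pi` is the shared prior probability for a SNP to be causal; `sigma` is
#' the standard deviation of causal effect sizes (the slab).
#'
#' @param pi probability in (0, 1).
#' @param sigma positive scalar.
#' @return object of class `blore_hyperparameters`.
#' @export
hyperparameters <- function(pi, sigma) {
  if (!is.numeric(pi) || pi <= 0 || pi >= 1) stop("pi must be in (0, 1)")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  structure(list(pi = pi, sigma = sigma), class = "blore_hyperparameters")
}

#' Enumerate causality configurations
#'
#' All binary configurations over `n_snps` SNPs with at most `cmax` causal
#' SNPs, ordered by increasing size then lexicographically. Configurations
#' are represented by their sorted causal index sets (the null configuration
#' is the empty set).
#'
#' @param n_snps number of SNPs in the locus.
#' @param cmax maximum configuration size.
#' @return list of integer vectors; attributes `n_snps` and `cmax`.
#' @export
enumerate_configs <- function(n_snps, cmax) {
  if (cmax < 0) stop("cmax must be >= 0")
  cmax <- min(cmax, n_snps)
  out <- list(integer(0))
  for (k in seq_len(cmax)) {
    cm <- utils::combn(n_snps, k)
    out <- c(out, lapply(seq_len(ncol(cm)), function(j) cm[, j]))
  }
  attr(out, "n_snps") <- as.integer(n_snps)
  attr(out, "cmax") <- as.integer(cmax)
  out
}

#' Combine per-study regularized fits into a pooled summary
#'
#' Gaussian pooling of the per-study quasi-Laplace summaries: per locus
#' block, \eqn{\tilde\Lambda = \sum_s \tilde\Lambda_s} and
#' \eqn{\tilde\beta = \tilde\Lambda^{-1} \sum_s \tilde\Lambda_s
#' \tilde\beta_s}, solved by Cholesky factorization. Studies must carry
#' identical SNP sets in identical order; when SNP metadata is available,
#' ids and alleles are validated and ref/alt swaps are reported.
#'
#' @param fits list of `blore_fit` (or summaries read back from disk).
#' @return object of class `blore_combined` with pooled per-locus
#'   `lambda_blocks` and `beta_blocks` (intercept entry first), the
#'   per-study `sigma_tildes`, and the total deregularization precisions.
#' @export
combine_studies <- function(fits) {
  stopifnot(length(fits) >= 1)
  S <- length(fits)
  ref <- fits[[1]]
  nb <- length(ref$blocks)
  for (s in seq_len(S)) {
    f <- fits[[s]]
    if (length(f$blocks) != nb ||
        !all(lengths(f$blocks) == lengths(ref$blocks))) {
      stop("study ", s, " has a different locus block structure")
    }
  }
  have_snps <- all(vapply(fits, function(f) !is.null(f$snps), logical(1)))
  if (have_snps) {
    ids <- ref$snps$id
    for (s in seq_len(S)[-1]) {
      sn <- fits[[s]]$snps
      if (!identical(sn$id, ids)) {
        off <- utils::head(ids[sn$id != ids], 5)
        stop("SNP sets differ across studies; offending ids: ",
             paste(off, collapse = ", "))
      }
      flip <- sn$a0 == ref$snps$a1 & sn$a1 == ref$snps$a0
      if (any(flip)) {
        stop("allele flip (ref/alt swapped) for SNP(s): ",
             paste(utils::head(ids[flip], 5), collapse = ", "),
             "; harmonize alleles before combining")
      }
      if (!all(sn$a0 == ref$snps$a0 & sn$a1 == ref$snps$a1)) {
        stop("allele mismatch across studies; harmonize before combining")
      }
    }
  }
  lambda_blocks <- vector("list", nb)
  beta_blocks <- vector("list", nb)
  for (b in seq_len(nb)) {
    idx <- c(1L, ref$blocks[[b]] + 1L)
    L <- 0; rhs <- 0
    for (s in seq_len(S)) {
      Ls <- fits[[s]]$lambda_blocks[[b]]
      bs <- if (!is.null(fits[[s]]$beta_blocks)) {
        fits[[s]]$beta_blocks[[b]]
      } else {
        fits[[s]]$beta[idx]
      }
      L <- L + Ls
      rhs <- rhs + drop(Ls %*% bs)
    }
    R <- chol(L)
    beta_blocks[[b]] <- drop(backsolve(R, backsolve(R, rhs, transpose = TRUE)))
    lambda_blocks[[b]] <- L
  }
  sigma_tildes <- vapply(fits, `[[`, numeric(1), "sigma_tilde")
  structure(list(
    blocks = ref$blocks,
    lambda_blocks = lambda_blocks,
    beta_blocks = beta_blocks,
    sigma_tildes = sigma_tildes,
    S = S,
    d0_total = S / INTERCEPT_SD^2,
    dsnp_total = sum(1 / sigma_tildes^2),
    n_samples = sum(vapply(fits, function(f) f$n_samples %||% 0L, numeric(1))),
    snps = if (have_snps) ref$snps else NULL,
    method = ref$method %||% "logistic"
  ), class = "blore_combined")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract per-locus evidence blocks from a summary
#'
#' Builds, for each locus, the deregularized precision block
#' \eqn{M = \tilde\Lambda_{block} - D} (the pooled \eqn{X^T W X}
#' curvature) and the linear term \eqn{b = \tilde\Lambda_{block}
#' \tilde\beta_{block}} used by the closed-form configuration marginals.
#' The intercept row/column is the first entry of every block.
#'
#' @param summary a `blore_combined` (or a single `blore_fit`).
#' @return list of locus blocks, each with `M`, `b`, `n_snps`, `method`.
#' @export
locus_blocks <- function(summary) {
  if (inherits(summary, "blore_fit")) summary <- combine_studies(list(summary))
  stopifnot(inherits(summary, "blore_combined"))
  out <- vector("list", length(summary$blocks))
  for (k in seq_along(summary$blocks)) {
    L <- summary$lambda_blocks[[k]]
    m <- nrow(L)
    M <- L
    M[1, 1] <- M[1, 1] - summary$d0_total
    if (m > 1) {
      di <- seq(2, m)
      M[cbind(di, di)] <- M[cbind(di, di)] - summary$dsnp_total
    }
    out[[k]] <- list(M = M, b = drop(L %*% summary$beta_blocks[[k]]),
                     n_snps = m - 1L, method = summary$method,
                     ids = if (!is.null(summary$snps))
                       summary$snps$id[summary$blocks[[k]]] else NULL)
  }
  out
}

# reference constant: null configuration at (pi0 = 1/I, sigma0 = 0.01)
REF_SIGMA0 <- 0.01

locus_ref_constant <- function(block) {
  I <- block$n_snps
  pi0 <- 1 / max(I, 2)
  q0 <- block$M[1, 1] + 1 / INTERCEPT_SD^2
  I * log(1 - pi0) - 0.5 * log(q0) + 0.5 * block$b[1]^2 / q0
}

# flatten a configuration list once so repeated objective evaluations skip
# the R-side unlist overhead
compile_configs <- function(configs) {
  if (inherits(configs, "blore_compiled_configs")) return(configs)
  sizes <- lengths(configs)
  structure(list(
    flat = as.integer(unlist(configs, use.names = FALSE)),
    offsets = as.integer(c(0L, cumsum(sizes))),
    sizes = as.integer(sizes)
  ), class = "blore_compiled_configs")
}

# vectorized log joint over a list of configurations (index form)
config_log_joint_all <- function(block, configs, hp) {
  stopifnot(inherits(hp, "blore_hyperparameters"))
  cc <- compile_configs(configs)
  gauss <- config_gauss_terms(block$M, block$b, cc$flat, cc$offsets,
                              hp$sigma^2, 1 / INTERCEPT_SD^2)
  I <- block$n_snps
  prior <- cc$sizes * log(hp$pi) + (I - cc$sizes) * log(1 - hp$pi)
  as.numeric(gauss + prior - locus_ref_constant(block))
}

#' Log joint of one causality configuration
#'
#' \eqn{\log p(c | \pi, \sigma) + \log \int N(\beta | \tilde\beta,
#' \tilde\Lambda^{-1}) N(\beta_c | 0, \sigma^2 I) / \prod_s N(\beta | 0,
#' \tilde\sigma_s^2 I) \, d\beta} over the causal subspace (spike components
#' fixed at 0, intercept always active with its broad prior), in closed
#' form, relative to the null configuration at reference hyperparameters.
#'
#' @param block a locus block from [locus_blocks()].
#' @param c binary causality vector over the locus's SNPs, or a sorted
#'   integer vector of causal indices.
#' @param hp a [hyperparameters()] object.
#' @return scalar log joint (shared additive constant removed).
#' @export
config_log_joint <- function(block, c, hp) {
  idx <- as_config_index(c, block$n_snps)
  config_log_joint_all(block, list(idx), hp)
}

#' Linear-approximation comparator for the configuration log joint
#'
#' Identical contract to [config_log_joint()] but requires a block built
#' from a `method = "linear"` fit, i.e. with the likelihood curvature frozen
#' at `beta = 0` (W = 1/4, precision proportional to X'X/4) — the
#' approximation used by linear-model fine-mapping tools. The contrast
#' between the two scores reproduces the logistic-vs-linear benchmark.
#'
#' @inheritParams config_log_joint
#' @export
config_log_joint_linear <- function(block, c, hp) {
  if (!identical(block$method, "linear")) {
    stop("block was not built from a linear-approximation fit; ",
         "use fit_regularized_mode(..., method = \"linear\")")
  }
  config_log_joint(block, c, hp)
}

as_config_index <- function(c, n_snps) {
  if (length(c) == n_snps && all(c %in% c(0, 1)) &&
      (n_snps == 0 || max(c) <= 1)) {
    which(c == 1)
  } else {
    idx <- as.integer(c)
    if (length(idx) && (min(idx) < 1 || max(idx) > n_snps)) {
      stop("configuration indices out of range")
    }
    idx
  }
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Log marginal likelihood of one locus
#'
#' Log-sum-exp of [config_log_joint()] over all configurations with at most
#' `cmax` causal SNPs. With `prune_log_width` set, SNPs whose single-SNP
#' configuration falls more than that many log-units below the current best
#' are excluded from larger configurations (a conservative branch-and-bound
#' style pruning; off by default).
#'
#' @param block a locus block from [locus_blocks()].
#' @param hp a [hyperparameters()] object.
#' @param cmax maximum number of causal SNPs per configuration (default 3).
#' @param prune_log_width optional pruning margin in log-units.
#' @param configs optional pre-enumerated configuration list.
#' @return scalar log marginal (relative to the shared constant).
#' @export
locus_log_marginal <- function(block, hp, cmax = 3, prune_log_width = NULL,
                               configs = NULL) {
  if (is.null(configs)) {
    configs <- locus_configs(block$n_snps, cmax, block, hp, prune_log_width)
  }
  logsumexp(config_log_joint_all(block, configs, hp))
}

# enumeration with optional single-SNP-score pruning of larger configs
locus_configs <- function(n_snps, cmax, block = NULL, hp = NULL,
                          prune_log_width = NULL) {
  if (is.null(prune_log_width) || cmax < 2) {
    return(enumerate_configs(n_snps, cmax))
  }
  singles <- lapply(seq_len(n_snps), function(i) i)
  v1 <- config_log_joint_all(block, singles, hp)
  keep <- which(v1 >= max(v1) - prune_log_width)
  out <- c(list(integer(0)), singles)
  for (k in 2:min(cmax, length(keep))) {
    cm <- utils::combn(keep, k)
    out <- c(out, lapply(seq_len(ncol(cm)), function(j) cm[, j]))
  }
  attr(out, "n_snps") <- as.integer(n_snps)
  attr(out, "cmax") <- as.integer(cmax)
  out
}
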