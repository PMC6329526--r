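# Synthetic-data engine: LD-structured genotypes, causal-SNP sampling,
# liability-threshold phenotypes, logistic model-matched phenotypes, and
# case/control ascertainment. All randomness flows from the `seed`
# argument; identical seeds give bitwise-identical output.

#' Generate LD-structured synthetic genotypes
#'
#' Per locus, haplotypes are drawn from a latent AR(1) Gaussian with lag-1
#' correlation `ld_rho` and thresholded at the allele-frequency quantile;
#' two haplotypes per individual are summed to a 0/1/2 dosage. Loci are
#' mutually independent, giving the block-diagonal LD structure the method
#' exploits. Monomorphic columns are redrawn (new allele frequency) up to
#' 10 times.
#'
#' @param n number of individuals.
#' @param n_loci number of loci.
#' @param snps_per_locus SNPs per locus.
#' @param ld_rho latent lag-1 correlation, in \[0, 1).
#' @param maf_range range of allele frequencies to draw from.
#' @param seed integer seed.
#' @return a [genotype_data()] with loci assigned consecutively.
#' @export
generate_genotypes <- function(n, n_loci, snps_per_locus, ld_rho = 0.9,
                               maf_range = c(0.05, 0.5), seed = 1) {
  stopifnot(ld_rho >= 0, ld_rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  set.seed(seed)  # dedicated stream; other ops offset the seed (see below)
  p <- n_loci * snps_per_locus
  raw <- matrix(0, n, p)
  for (l in seq_len(n_loci)) {
    mafs <- stats::runif(snps_per_locus, maf_range[1], maf_range[2])
    z <- matrix(0, 2 * n, snps_per_locus)
    z[, 1] <- stats::rnorm(2 * n)
    if (snps_per_locus > 1) {
      for (j in 2:snps_per_locus) {
        z[, j] <- ld_rho * z[, j - 1] +
          sqrt(1 - ld_rho^2) * stats::rnorm(2 * n)
      }
    }
    for (j in seq_len(snps_per_locus)) {
      col <- NULL
      for (attempt in seq_len(10)) {
        h <- as.numeric(z[, j] < stats::qnorm(mafs[j]))
        g <- h[seq_len(n)] + h[n + seq_len(n)]
        if (stats::var(g) > 0) { col <- g; break }
        mafs[j] <- stats::runif(1, maf_range[1], maf_range[2])
      }
      if (is.null(col)) {
        stop("monomorphic SNP could not be regenerated (locus ", l,
             ", SNP ", j, ")")
      }
      raw[, (l - 1) * snps_per_locus + j] <- col
    }
  }
  snps <- data.frame(
    id = paste0("loc", rep(seq_len(n_loci), each = snps_per_locus),
                "_snp", rep(seq_len(snps_per_locus), n_loci)),
    chr = rep(seq_len(n_loci), each = snps_per_locus),
    pos = rep(seq_len(snps_per_locus), n_loci) * 1000L,
    a0 = "A", a1 = "B", stringsAsFactors = FALSE)
  genotype_data(raw, snps = snps,
                locus = rep(seq_len(n_loci), each = snps_per_locus))
}

#' Sample causal SNP sets
#'
#' Independent Bernoulli(`pi_sim`) draws per SNP; when `at_least_one` is
#' set (the default) a locus that drew no causal SNP receives one chosen
#' uniformly at random, emulating the benchmark constraint that every
#' simulated locus carries signal.
#'
#' @param n_loci,snps_per_locus locus geometry.
#' @param pi_sim prior causal probability (default 0.005).
#' @param at_least_one force >= 1 causal SNP per locus.
#' @param seed integer seed.
#' @return list of per-locus integer index vectors (indices within locus).
#' @export
sample_causal_snps <- function(n_loci, snps_per_locus, pi_sim = 0.005,
                               at_least_one = TRUE, seed = 1) {
  stopifnot(pi_sim > 0, pi_sim < 1)
  # offset seed: reusing one seed across ops must not alias RNG substreams
  set.seed(seed + 1000003L)
  lapply(seq_len(n_loci), function(l) {
    idx <- which(stats::runif(snps_per_locus) < pi_sim)
    if (length(idx) == 0 && at_least_one) {
      idx <- sample.int(snps_per_locus, 1)
    }
    idx
  })
}

#' Simulate binary phenotypes under the liability threshold model
#'
#' Liability \eqn{y_n = \sum_i \beta_i x_{ni} + \epsilon_n} over the causal
#' SNPs (normalized genotypes), with \eqn{\beta_i \sim N(0, h^2/C)} rescaled
#' so that \eqn{\sum_i \beta_i^2 = h^2} exactly and
#' \eqn{\epsilon_n \sim N(0, 1 - h^2)}. Disease status is
#' \eqn{\phi_n = 1} iff \eqn{y_n >} `threshold` (default 0, i.e. prevalence
#' 0.5 and roughly balanced cases/controls).
#'
#' @param geno a [genotype_data()].
#' @param causal_sets per-locus causal index list from
#'   [sample_causal_snps()] (indices within each locus).
#' @param h2 heritability on the liability scale, in \[0, 1).
#' @param threshold liability threshold.
#' @param seed integer seed.
#' @return list with `phenotype` (0/1 integer vector) and `truth`
#'   (class `blore_truth`: `causal` global indices, `causal_sets`, `beta`,
#'   `h2`, `liability`, `genetic`, `threshold`, `seed`).
#' @export
simulate_phenotype <- function(geno, causal_sets, h2, threshold = 0,
                               seed = 1) {
  stopifnot(inherits(geno, "genotype_data"), h2 >= 0, h2 < 1)
  set.seed(seed + 2000003L)
  spl <- table(factor(geno$locus, levels = unique(geno$locus)))
  offset <- c(0L, cumsum(as.integer(spl)))
  causal <- unlist(lapply(seq_along(causal_sets), function(l) {
    offset[l] + causal_sets[[l]]
  }), use.names = FALSE)
  C <- length(causal)
  if (C == 0 && h2 > 0) stop("h2 > 0 requires at least one causal SNP")
  beta <- numeric(C)
  genetic <- numeric(geno$n_samples)
  if (C > 0 && h2 > 0) {
    beta <- stats::rnorm(C, 0, sqrt(h2 / C))
    beta <- beta * sqrt(h2 / sum(beta^2))   # exact sum(beta^2) = h2
    genetic <- drop(geno$normalized[, causal, drop = FALSE] %*% beta)
  }
  eps <- stats::rnorm(geno$n_samples, 0, sqrt(1 - h2))
  y <- genetic + eps
  phi <- as.integer(y > threshold)
  truth <- structure(list(causal = causal, causal_sets = causal_sets,
                          beta = beta, h2 = h2, liability = y,
                          genetic = genetic, threshold = threshold,
                          seed = seed), class = "blore_truth")
  list(phenotype = phi, truth = truth)
}

#' Simulate phenotypes from the logistic spike-and-slab model itself
#'
#' Model-matched generator for hyperparameter-recovery and calibration
#' experiments: each SNP is causal with probability `pi`, causal effects are
#' N(0, sigma^2), and \eqn{\phi_n \sim} Bernoulli of the logistic risk with
#' intercept `beta0`.
#'
#' @param geno a [genotype_data()].
#' @param pi,sigma generating hyperparameters.
#' @param beta0 intercept (0 gives balanced cases/controls on average).
#' @param seed integer seed.
#' @return list with `phenotype` and `truth` (as in
#'   [simulate_phenotype()], plus `pi`, `sigma`).
#' @export
simulate_phenotype_logistic <- function(geno, pi, sigma, beta0 = 0,
                                        seed = 1) {
  stopifnot(inherits(geno, "genotype_data"))
  set.seed(seed + 3000003L)
  causal <- which(stats::runif(geno$n_snps) < pi)
  beta <- stats::rnorm(length(causal), 0, sigma)
  eta <- beta0 + if (length(causal)) {
    drop(geno$normalized[, causal, drop = FALSE] %*% beta)
  } else 0
  phi <- as.integer(stats::runif(geno$n_samples) < stats::plogis(eta))
  spl <- table(factor(geno$locus, levels = unique(geno$locus)))
  offset <- c(0L, cumsum(as.integer(spl)))
  causal_sets <- lapply(seq_along(spl), function(l) {
    causal[causal > offset[l] & causal <= offset[l + 1]] - offset[l]
  })
  truth <- structure(list(causal = causal, causal_sets = causal_sets,
                          beta = beta, pi = pi, sigma = sigma,
                          genetic = eta - beta0, seed = seed),
                     class = "blore_truth")
  list(phenotype = phi, truth = truth)
}

#' Select a case/control subset
#'
#' Random ascertainment of study samples. `fix_cases` keeps all (or
#' `n_cases`) cases and samples controls to match `case_control_ratio`;
#' `fix_controls` mirrors that; `prevalence_threshold` first re-thresholds
#' the liability at the standard-normal upper-`prevalence` quantile (so the
#' population prevalence is `prevalence`) and then applies `fix_cases`.
#' Excluded individuals are simply not in the returned index set (their
#' status would be recorded as missing/NA downstream).
#'
#' @param phi 0/1 phenotype vector.
#' @param case_control_ratio desired cases/controls ratio.
#' @param mode one of `"fix_cases"`, `"fix_controls"`,
#'   `"prevalence_threshold"`.
#' @param n_cases optional fixed number of cases to keep (default: all).
#' @param prevalence population prevalence for `prevalence_threshold`.
#' @param liability liability vector (required for
#'   `prevalence_threshold`).
#' @param seed integer seed.
#' @return sorted integer vector of selected sample indices; attribute
#'   `phenotype` carries the (possibly re-thresholded) status of the
#'   selected samples.
#' @export
ascertain <- function(phi, case_control_ratio, mode = c("fix_cases",
                      "fix_controls", "prevalence_threshold"),
                      n_cases = NULL, prevalence = NULL, liability = NULL,
                      seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed + 4000003L)
  if (mode == "prevalence_threshold") {
    if (is.null(liability) || is.null(prevalence)) {
      stop("prevalence_threshold mode needs `liability` and `prevalence`")
    }
    phi <- as.integer(liability > stats::qnorm(1 - prevalence))
  }
  cases <- which(phi == 1)
  controls <- which(phi == 0)
  if (mode == "fix_controls") {
    n_ctl <- length(controls)
    n_cas <- round(n_ctl * case_control_ratio)
    if (n_cas > length(cases)) {
      stop(sprintf("infeasible ratio: need %d cases but only %d available",
                   n_cas, length(cases)))
    }
    sel <- c(sample(cases, n_cas), controls)
  } else {
    n_cas <- if (is.null(n_cases)) length(cases) else n_cases
    if (n_cas > length(cases)) {
      stop(sprintf("infeasible: need %d cases but only %d available",
                   n_cas, length(cases)))
    }
    n_ctl <- round(n_cas / case_control_ratio)
    if (n_ctl > length(controls)) {
      stop(sprintf("infeasible ratio: need %d controls but only %d available",
                   n_ctl, length(controls)))
    }
    keep_cases <- if (n_cas == length(cases)) cases else sample(cases, n_cas)
    sel <- c(keep_cases, sample(controls, n_ctl))
  }
  sel <- sort(sel)
  attr(sel, "phenotype") <- phi[sel]
  sel
}
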