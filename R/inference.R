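# Posterior summaries at fixed hyperparameters: normalized configuration
# posteriors, per-SNP posterior inclusion probabilities (PIPs), and the
# per-locus probability of harboring at least one causal SNP.

#' Posterior over causality configurations for one locus
#'
#' Softmax of [config_log_joint()] over all configurations with at most
#' `cmax` causal SNPs.
#'
#' @param block a locus block from [locus_blocks()].
#' @param hp fitted or supplied [hyperparameters()].
#' @param cmax maximum configuration size.
#' @return object of class `blore_posterior`: `configs` (index form),
#'   `weights` (normalized, sum 1), `pip`, `pr_causal`, `expected_causal`,
#'   `ranking` (SNP indices by decreasing PIP, position-ascending ties).
#' @export
config_posterior <- function(block, hp, cmax = 3) {
  configs <- enumerate_configs(block$n_snps, cmax)
  lj <- config_log_joint_all(block, configs, hp)
  w <- exp(lj - logsumexp(lj))
  w <- w / sum(w)
  pip <- numeric(block$n_snps)
  for (k in seq_along(configs)) {
    idx <- configs[[k]]
    if (length(idx)) pip[idx] <- pip[idx] + w[k]
  }
  pip <- pmin(pmax(pip, 0), 1)   # guard accumulated rounding at the ends
  structure(list(
    configs = configs,
    weights = w,
    pip = pip,
    pr_causal = 1 - w[1],            # configs[[1]] is the null
    expected_causal = sum(lengths(configs) * w),
    ranking = order(-pip, seq_along(pip)),
    ids = block$ids
  ), class = "blore_posterior")
}

#' @export
print.blore_posterior <- function(x, ...) {
  cat(sprintf("blore_posterior: %d SNPs, Pr_causal = %.4f, E[#causal] = %.3f, top SNP %d (PIP %.3f)\n",
              length(x$pip), x$pr_causal, x$expected_causal,
              x$ranking[1], x$pip[x$ranking[1]]))
  invisible(x)
}

#' Posterior inclusion probabilities from a configuration posterior
#'
#' PIP of SNP i is the summed posterior weight of all configurations in
#' which it is causal; consequently the PIPs sum to the posterior expected
#' number of causal SNPs.
#'
#' @param posterior a `blore_posterior`.
#' @return numeric vector of PIPs.
#' @export
compute_pips <- function(posterior) {
  stopifnot(inherits(posterior, "blore_posterior"))
  posterior$pip
}

#' Probability that a locus harbors at least one causal SNP
#'
#' One minus the posterior weight of the null configuration.
#'
#' @param posterior a `blore_posterior`.
#' @return scalar probability.
#' @export
locus_causal_prob <- function(posterior) {
  stopifnot(inherits(posterior, "blore_posterior"))
  posterior$pr_causal
}
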