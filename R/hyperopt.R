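# Empirical-Bayes estimation of the spike-and-slab hyperparameters by
# maximizing the total log marginal likelihood, summed over loci (the
# block-diagonal factorization) and pooled over studies. Flat hyperpriors
# p(pi) = const, p(sigma^2) = const, so the objective is the marginal
# likelihood itself.

#' Total log marginal likelihood over loci
#'
#' Sum of [locus_log_marginal()] over all locus blocks under the shared
#' constant convention.
#'
#' @param blocks list of locus blocks from [locus_blocks()].
#' @param hp a [hyperparameters()] object.
#' @param cmax maximum configuration size.
#' @param configs optional list of pre-enumerated configuration lists (one
#'   per locus), reused across objective evaluations.
#' @return scalar.
#' @export
total_log_marginal <- function(blocks, hp, cmax = 3, configs = NULL) {
  stopifnot(length(blocks) >= 1)
  tot <- 0
  for (k in seq_along(blocks)) {
    cfg <- if (is.null(configs)) NULL else configs[[k]]
    tot <- tot + locus_log_marginal(blocks[[k]], hp, cmax, configs = cfg)
  }
  tot
}

# search box in transformed coordinates (logit pi, log sigma)
HYPER_BOX <- list(lpi = c(-12, -1), lsig = c(-7, 0))

#' Estimate (pi, sigma) by conjugate-gradient ascent
#'
#' Maximizes [total_log_marginal()] over transformed coordinates
#' (logit pi, log sigma) with Polak-Ribiere conjugate gradients and central
#' finite-difference gradients. A quadratic penalty keeps the search inside
#' the box logit pi in \[-12, -1\], log sigma in \[-7, 0\]; landing on a
#' boundary is reported with a warning.
#'
#' @param blocks list of locus blocks from [locus_blocks()] (or a
#'   `blore_combined`, converted automatically).
#' @param cmax maximum configuration size.
#' @param init optional [hyperparameters()] starting point; default
#'   pi = 1/(total SNPs), sigma = 0.05.
#' @param max_iter CG iteration cap.
#' @param tol absolute objective-change tolerance.
#' @return object of class `blore_hyperopt`: `hp_hat`, `objective`,
#'   `trace` (best objective after each evaluation), `n_eval`, `converged`,
#'   `boundary`, `n_loci`, `cmax`.
#' @export
optimize_hyperparameters <- function(blocks, cmax = 3, init = NULL,
                                     max_iter = 200, tol = 1e-5) {
  if (inherits(blocks, "blore_combined")) blocks <- locus_blocks(blocks)
  n_snps_total <- sum(vapply(blocks, `[[`, integer(1), "n_snps"))
  if (is.null(init)) {
    init <- hyperparameters(pi = 1 / n_snps_total, sigma = 0.05)
  }
  configs <- lapply(blocks, function(b) {
    compile_configs(enumerate_configs(b$n_snps, cmax))
  })
  box <- HYPER_BOX
  clamp <- function(x, r) pmin(pmax(x, r[1]), r[2])
  trace_env <- new.env()
  trace_env$best <- -Inf
  trace_env$trace <- numeric(0)
  trace_env$n <- 0L
  negobj <- function(par) {
    pen <- 0
    lpi <- par[1]; lsig <- par[2]
    if (lpi < box$lpi[1]) { pen <- pen + 1e3 * (box$lpi[1] - lpi)^2; lpi <- box$lpi[1] }
    if (lpi > box$lpi[2]) { pen <- pen + 1e3 * (lpi - box$lpi[2])^2; lpi <- box$lpi[2] }
    if (lsig < box$lsig[1]) { pen <- pen + 1e3 * (box$lsig[1] - lsig)^2; lsig <- box$lsig[1] }
    if (lsig > box$lsig[2]) { pen <- pen + 1e3 * (lsig - box$lsig[2])^2; lsig <- box$lsig[2] }
    hp <- hyperparameters(stats::plogis(lpi), exp(lsig))
    val <- tryCatch(
      total_log_marginal(blocks, hp, cmax, configs = configs),
      error = function(e) NA_real_)
    if (!is.finite(val)) return(1e10 + pen)
    trace_env$n <- trace_env$n + 1L
    trace_env$best <- max(trace_env$best, val - pen)
    trace_env$trace <- c(trace_env$trace, trace_env$best)
    -(val - pen)
  }
  par0 <- c(clamp(stats::qlogis(init$pi), box$lpi),
            clamp(log(init$sigma), box$lsig))
  opt <- stats::optim(par0, negobj, method = "CG",
                      control = list(type = 2, maxit = max_iter,
                                     reltol = tol / (abs(negobj(par0)) + 1)))
  par <- c(clamp(opt$par[1], box$lpi), clamp(opt$par[2], box$lsig))
  boundary <- any(abs(par - c(box$lpi[1], box$lsig[1])) < 1e-8) ||
    any(abs(par - c(box$lpi[2], box$lsig[2])) < 1e-8)
  if (boundary) {
    warning("optimize_hyperparameters: estimate at search-box boundary")
  }
  hp_hat <- hyperparameters(stats::plogis(par[1]), exp(par[2]))
  structure(list(
    hp_hat = hp_hat,
    objective = total_log_marginal(blocks, hp_hat, cmax, configs = configs),
    trace = trace_env$trace,
    n_eval = trace_env$n,
    converged = opt$convergence == 0,
    boundary = boundary,
    n_loci = length(blocks),
    cmax = cmax
  ), class = "blore_hyperopt")
}

#' @export
print.blore_hyperopt <- function(x, ...) {
  cat(sprintf("blore_hyperopt: pi_hat = %.4g, sigma_hat = %.4g, objective = %.4f (%d loci, cmax = %d, %d evaluations)\n",
              x$hp_hat$pi, x$hp_hat$sigma, x$objective, x$n_loci, x$cmax,
              x$n_eval))
  invisible(x)
}
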