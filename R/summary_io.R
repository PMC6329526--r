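# Plain-text summary-statistics directory format (one directory per study):
#   meta.json               study metadata: N, cases, sigma_tilde, intercept
#                           effect, tolerances, locus sizes
#   locus_<k>_snps.tsv      id, chr, pos, a0, a1, freq, beta
#   locus_<k>_lambda.txt    dense symmetric precision block, whitespace
#                           delimited, header row of column names
#                           ("intercept" then SNP ids)
# Values are printed with 12 significant digits for stable round trips.

#' Write a study's summary statistics to a directory
#'
#' @param fit a `blore_fit` from [fit_regularized_mode()].
#' @param geno the `genotype_data` the fit was computed from (for SNP
#'   metadata and allele frequencies).
#' @param dir output directory (created if missing).
#' @export
write_summary <- function(fit, geno, dir) {
  stopifnot(inherits(fit, "blore_fit"), inherits(geno, "genotype_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) sprintf("%.12g", x)
  meta <- list(
    n_samples = fit$n_samples,
    n_cases = fit$n_cases,
    sigma_tilde = fit$sigma_tilde,
    intercept_beta = fit$beta[1],
    intercept_sd = INTERCEPT_SD,
    method = fit$method,
    grad_tol = 1e-6,
    n_loci = length(fit$blocks),
    locus_sizes = lengths(fit$blocks)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (k in seq_along(fit$blocks)) {
    idx <- fit$blocks[[k]]
    sn <- geno$snps[idx, , drop = FALSE]
    tab <- data.frame(id = sn$id, chr = sn$chr, pos = sn$pos,
                      a0 = sn$a0, a1 = sn$a1,
                      freq = fmt(geno$freqs[idx]),
                      beta = fmt(fit$beta[idx + 1L]),
                      stringsAsFactors = FALSE)
    utils::write.table(tab, file.path(dir, sprintf("locus_%d_snps.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    L <- fit$lambda_blocks[[k]]
    colnames(L) <- c("intercept", sn$id)
    out <- rbind(colnames(L), matrix(fmt(L), nrow(L)))
    writeLines(apply(out, 1, paste, collapse = " "),
               file.path(dir, sprintf("locus_%d_lambda.txt", k)))
  }
  invisible(dir)
}

#' Read a study's summary statistics back from a directory
#'
#' @param dir directory written by [write_summary()].
#' @return a `blore_fit`-compatible object carrying `snps`, `locus`,
#'   `beta_blocks` and `lambda_blocks`.
#' @export
read_summary <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  nb <- meta$n_loci
  blocks <- vector("list", nb)
  lambda_blocks <- vector("list", nb)
  beta_blocks <- vector("list", nb)
  snps <- NULL
  off <- 0L
  locus <- integer(0)
  for (k in seq_len(nb)) {
    tab <- utils::read.table(file.path(dir, sprintf("locus_%d_snps.tsv", k)),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    for (cc in c("id", "chr", "a0", "a1")) tab[[cc]] <- as.character(tab[[cc]])
    lam <- utils::read.table(file.path(dir, sprintf("locus_%d_lambda.txt", k)),
                             header = TRUE, check.names = FALSE)
    lam <- as.matrix(lam)
    dimnames(lam) <- NULL
    m <- nrow(tab)
    blocks[[k]] <- off + seq_len(m)
    lambda_blocks[[k]] <- lam
    beta_blocks[[k]] <- c(meta$intercept_beta, tab$beta)
    tab$freq <- as.numeric(tab$freq)
    tab$beta <- as.numeric(tab$beta)
    snps <- rbind(snps, tab[, c("id", "chr", "pos", "a0", "a1")])
    locus <- c(locus, rep(k, m))
    off <- off + m
  }
  structure(list(
    sigma_tilde = meta$sigma_tilde,
    blocks = blocks,
    lambda_blocks = lambda_blocks,
    beta_blocks = beta_blocks,
    snps = snps,
    locus = locus,
    n_samples = meta$n_samples,
    n_cases = meta$n_cases,
    method = meta$method %||% "logistic"
  ), class = "blore_fit")
}
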