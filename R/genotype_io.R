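#' Construct a genotype container
#'
#' Bundles a dosage matrix with SNP metadata, observed minor-allele
#' frequencies, the centered/normalized genotype matrix used by the logistic
#' model, and the SNP-to-locus assignment.
#'
#' Genotypes are minor-allele dosages \eqn{w_{ni} \in [0, 2]}. Each column is
#' normalized as \eqn{x_{ni} = (w_{ni} - 2 f_i) / \sqrt{2 f_i (1 - f_i)}}
#' where \eqn{f_i} is the column's allele frequency. Missing dosages are
#' mean-imputed to \eqn{2 f_i}, i.e. they become 0 after normalization and
#' contribute nothing to any score.
#'
#' @param raw numeric matrix, samples x SNPs, dosages in \[0, 2\] (NA allowed).
#' @param snps data.frame with columns `id`, `chr`, `pos`, `a0`, `a1`
#'   (one row per SNP); generated automatically if `NULL`.
#' @param locus integer vector assigning each SNP to a locus (default: all 1).
#' @param freqs optional allele frequencies; computed from `raw` if `NULL`.
#' @return An object of class `genotype_data` with fields `raw`, `freqs`,
#'   `normalized`, `snps`, `locus`, `n_samples`, `n_snps`.
#' @export
genotype_data <- function(raw, snps = NULL, locus = NULL, freqs = NULL) {
  raw <- as.matrix(raw)
  n <- nrow(raw); p <- ncol(raw)
  if (is.null(snps)) {
    snps <- data.frame(id = paste0("snp", seq_len(p)), chr = 1L,
                       pos = seq_len(p), a0 = "A", a1 = "B",
                       stringsAsFactors = FALSE)
  }
  stopifnot(nrow(snps) == p)
  if (is.null(locus)) locus <- rep(1L, p)
  locus <- as.integer(locus)
  if (length(locus) != p) stop("locus assignment must cover every SNP")
  if (anyNA(locus)) stop("every SNP must be assigned to exactly one locus")
  if (is.null(freqs)) freqs <- colMeans(raw, na.rm = TRUE) / 2
  bad <- which(freqs <= 0 | freqs >= 1)
  if (length(bad)) {
    stop("allele frequency outside (0,1) for SNP(s): ",
         paste(snps$id[bad], collapse = ", "))
  }
  structure(list(
    raw = raw, freqs = as.numeric(freqs),
    normalized = normalize_genotypes(raw, freqs),
    snps = snps, locus = locus,
    n_samples = n, n_snps = p
  ), class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d samples x %d SNPs in %d loci\n",
              x$n_samples, x$n_snps, length(unique(x$locus))))
  invisible(x)
}

#' Center and scale a dosage matrix
#'
#' @param raw samples x SNPs dosage matrix (NA = missing).
#' @param freqs per-SNP minor-allele frequencies in (0, 1).
#' @return matrix of \eqn{x_{ni} = (w_{ni} - 2 f_i)/\sqrt{2 f_i (1-f_i)}};
#'   missing entries are imputed to the column mean \eqn{2 f_i} first and so
#'   map to exactly 0.
#' @export
normalize_genotypes <- function(raw, freqs) {
  raw <- as.matrix(raw)
  freqs <- as.numeric(freqs)
  stopifnot(length(freqs) == ncol(raw))
  bad <- which(freqs <= 0 | freqs >= 1)
  if (length(bad)) stop("allele frequency outside (0,1) for SNP index ", bad[1])
  x <- sweep(raw, 2, 2 * freqs, `-`)
  x[is.na(x)] <- 0
  sweep(x, 2, sqrt(2 * freqs * (1 - freqs)), `/`)
}

#' Invert the genotype normalization (used for round-trip checks)
#' @param x normalized matrix
#' @param freqs allele frequencies used to normalize
#' @return dosage matrix
#' @export
denormalize_genotypes <- function(x, freqs) {
  sweep(sweep(as.matrix(x), 2, sqrt(2 * freqs * (1 - freqs)), `*`),
        2, 2 * freqs, `+`)
}

#' Hardy-Weinberg chi-square test from hard-call genotype counts
#'
#' 1-df chi-square of observed (AA, Aa, aa) counts against the expectation
#' under the observed allele frequency.
#'
#' @param n0,n1,n2 counts of 0/1/2 minor-allele genotypes.
#' @return list with `stat` and `p`.
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  f <- (n1 + 2 * n2) / (2 * n)
  if (f <= 0 || f >= 1) return(list(stat = 0, p = 1))
  e <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
  stat <- sum((c(n0, n1, n2) - e)^2 / e)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Filter SNPs on minor-allele frequency and Hardy-Weinberg equilibrium
#'
#' Keeps SNPs with MAF strictly greater than `maf_min` and HWE chi-square
#' p-value strictly greater than `hwe_p_min` (defaults follow the usual
#' case-control QC thresholds MAF > 0.05, p > 1e-4). Genotype counts are
#' obtained by rounding dosages to the nearest hard call.
#'
#' @param data a `genotype_data` object.
#' @param maf_min MAF threshold (exclusive).
#' @param hwe_p_min HWE p-value threshold (exclusive).
#' @param verbose log counts to stderr.
#' @return filtered `genotype_data`.
#' @export
filter_snps <- function(data, maf_min = 0.05, hwe_p_min = 1e-4,
                        verbose = FALSE) {
  stopifnot(inherits(data, "genotype_data"))
  hard <- round(data$raw)
  keep <- logical(data$n_snps)
  for (i in seq_len(data$n_snps)) {
    g <- hard[, i]
    g <- g[!is.na(g)]
    n0 <- sum(g == 0); n1 <- sum(g == 1); n2 <- sum(g == 2)
    f <- (n1 + 2 * n2) / (2 * (n0 + n1 + n2))
    maf <- min(f, 1 - f)
    keep[i] <- maf > maf_min && hwe_test(n0, n1, n2)$p > hwe_p_min
  }
  if (!any(keep)) warning("all SNPs removed by filtering")
  if (verbose) {
    message(sprintf("filter_snps: kept %d / %d SNPs (maf > %g, hwe p > %g)",
                    sum(keep), data$n_snps, maf_min, hwe_p_min))
  }
  subset_snps(data, which(keep))
}

# take a column subset, recomputing frequencies/normalization from the kept data
subset_snps <- function(data, idx) {
  if (length(idx) == 0) {
    out <- data
    out$raw <- data$raw[, 0, drop = FALSE]
    out$freqs <- numeric(0)
    out$normalized <- data$normalized[, 0, drop = FALSE]
    out$snps <- data$snps[0, , drop = FALSE]
    out$locus <- integer(0)
    out$n_snps <- 0L
    return(out)
  }
  genotype_data(data$raw[, idx, drop = FALSE],
                snps = data$snps[idx, , drop = FALSE],
                locus = data$locus[idx])
}

#' Read Oxford GEN/SAMPLE genotype files
#'
#' GEN lines carry chromosome, SNP id, position, two alleles, then three
#' genotype probabilities per individual (hom-ref, het, hom-alt). Dosage is
#' `p(het) + 2 p(hom-alt)` after renormalizing the triple when its sum lies
#' in \[0.98, 1.02\]; triples outside that window are treated as missing for
#' that individual/SNP. The SAMPLE file follows the SNPTEST dialect: two
#' header lines, then one row per individual whose last column is the binary
#' phenotype.
#'
#' @param gen_path path to the (uncompressed) GEN file.
#' @param sample_path path to the SAMPLE file.
#' @param locus optional per-SNP locus assignment (integer vector or path to
#'   a two-column `snp_id locus_id` TSV).
#' @param verbose log counts to stderr.
#' @return list with `genotypes` (a `genotype_data`) and `phenotype`
#'   (integer 0/1 vector, NA = missing status).
#' @export
read_oxford_gen <- function(gen_path, sample_path, locus = NULL,
                            verbose = FALSE) {
  lines <- readLines(gen_path)
  lines <- lines[nzchar(lines)]
  n_snp <- length(lines)
  meta <- vector("list", n_snp)
  dos <- NULL
  n_missing <- 0L
  for (k in seq_len(n_snp)) {
    tok <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    if (length(tok) < 8 || (length(tok) - 5) %% 3 != 0) {
      stop(sprintf("malformed GEN line %d: expected 5 columns + 3 probabilities per individual, got %d fields",
                   k, length(tok)))
    }
    probs <- suppressWarnings(as.numeric(tok[-(1:5)]))
    if (anyNA(probs)) stop(sprintf("malformed GEN line %d: non-numeric probability", k))
    n_ind <- length(probs) / 3
    if (is.null(dos)) dos <- matrix(NA_real_, n_ind, n_snp)
    if (n_ind != nrow(dos)) {
      stop(sprintf("GEN line %d has %d individuals, expected %d", k, n_ind, nrow(dos)))
    }
    pm <- matrix(probs, nrow = 3)
    s <- colSums(pm)
    ok <- s >= 0.98 & s <= 1.02
    d <- (pm[2, ] + 2 * pm[3, ]) / s
    d[!ok] <- NA_real_
    n_missing <- n_missing + sum(!ok)
    dos[, k] <- d
    meta[[k]] <- data.frame(chr = tok[1], id = tok[2],
                            pos = as.integer(tok[3]),
                            a0 = tok[4], a1 = tok[5],
                            stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, meta)
  snps <- snps[, c("id", "chr", "pos", "a0", "a1")]

  samp <- utils::read.table(sample_path, header = TRUE,
                            stringsAsFactors = FALSE)
  # drop the SNPTEST type line ("0 0 0 B") if present
  if (nrow(samp) >= 1 && all(samp[1, 1:2] == c("0", "0"))) {
    samp <- samp[-1, , drop = FALSE]
  }
  if (nrow(samp) != nrow(dos)) {
    stop(sprintf("sample file has %d individuals but GEN file has %d",
                 nrow(samp), nrow(dos)))
  }
  phen <- suppressWarnings(as.numeric(samp[[ncol(samp)]]))
  phen[!is.na(phen) & !(phen %in% c(0, 1))] <- NA
  if (is.character(locus) && length(locus) == 1) {
    locus <- read_locus_map(locus, snps$id)
  }
  if (verbose) {
    message(sprintf("read_oxford_gen: %d SNPs x %d individuals, %d missing dosages",
                    n_snp, nrow(dos), n_missing))
  }
  list(genotypes = genotype_data(dos, snps = snps, locus = locus),
       phenotype = as.integer(phen))
}

#' Read a SNP-to-locus map
#'
#' Plain-text two-column file (`snp_id`, `locus_id`), whitespace-delimited,
#' no header. Every SNP in `snp_ids` must be assigned exactly once.
#'
#' @param path file path.
#' @param snp_ids character vector of SNP ids in genotype column order.
#' @return integer locus index per SNP (loci renumbered 1..L in order of
#'   first appearance).
#' @export
read_locus_map <- function(path, snp_ids) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("snp_id", "locus_id"))
  if (anyDuplicated(tab$snp_id)) {
    stop("locus map assigns some SNP more than once: ",
         tab$snp_id[duplicated(tab$snp_id)][1])
  }
  m <- match(snp_ids, tab$snp_id)
  if (anyNA(m)) {
    stop("locus map is missing SNP(s): ",
         paste(utils::head(snp_ids[is.na(m)], 5), collapse = ", "))
  }
  ids <- tab$locus_id[m]
  as.integer(factor(ids, levels = unique(ids)))
}

#' Write Oxford GEN/SAMPLE files
#'
#' Inverse of [read_oxford_gen()] for synthetic data: integer dosages become
#' certain probability triples; fractional dosages `d` are written as the
#' two-point distribution on the neighbouring hard calls, which reproduces
#' `d` exactly under the dosage formula.
#'
#' @param data a `genotype_data`.
#' @param phenotype 0/1 vector (NA allowed).
#' @param gen_path,sample_path output paths.
#' @export
write_oxford_gen <- function(data, phenotype, gen_path, sample_path) {
  stopifnot(inherits(data, "genotype_data"))
  n <- data$n_samples
  con <- file(gen_path, "w")
  on.exit(close(con))
  for (i in seq_len(data$n_snps)) {
    w <- data$raw[, i]
    w[is.na(w)] <- -1            # encoded as an invalid triple (0 0 0)
    lo <- pmax(pmin(floor(w), 1), 0)
    frac <- w - lo
    pm <- matrix(0, 3, n)
    for (j in seq_len(n)) {
      if (w[j] < 0) next
      pm[lo[j] + 1, j] <- 1 - frac[j]
      pm[lo[j] + 2, j] <- frac[j]
    }
    s <- data$snps[i, ]
    writeLines(paste(s$chr, s$id, s$pos, s$a0, s$a1,
                     paste(sprintf("%.6g", pm), collapse = " ")), con)
  }
  sc <- file(sample_path, "w")
  on.exit(close(sc), add = TRUE)
  writeLines(c("ID_1 ID_2 missing pheno", "0 0 0 B"), sc)
  ph <- ifelse(is.na(phenotype), "NA", as.character(phenotype))
  writeLines(paste(paste0("ind", seq_len(n)), paste0("ind", seq_len(n)),
                   "0", ph), sc)
  invisible(NULL)
}

#' Write a SNP-to-locus map file
#' @param data a `genotype_data`
#' @param path output TSV path
#' @export
write_locus_map <- function(data, path) {
  utils::write.table(data.frame(data$snps$id, data$locus),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
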