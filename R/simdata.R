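# Seeded synthetic cohorts: HWE genotypes, odds-model phenotypes, bimodal
# methylation beta values, and genomic positions.

#' Simulate independent HWE genotypes
#'
#' Each SNP is drawn independently under Hardy-Weinberg equilibrium at its
#' minor allele frequency q: genotype ~ Binomial(2, q), so
#' P(0, 1, 2) = ((1-q)^2, 2q(1-q), q^2).  No linkage disequilibrium is
#' simulated.
#'
#' @param n_subjects Number of subjects (rows).
#' @param maf Vector of per-SNP minor allele frequencies in [0, 0.5]; its
#'   length sets the number of SNPs.
#' @param seed Optional integer seed.
#' @return Integer matrix (subjects x SNPs) with columns `snp1`, `snp2`, ...
#' @examples
#' g <- sim_genotypes(100, maf = c(0.1, 0.3, 0.5), seed = 1)
#' colMeans(g) / 2
#' @export
sim_genotypes <- function(n_subjects, maf, seed = NULL) {
  if (any(maf < 0 | maf > 0.5)) abort("`maf` must be in [0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  g <- vapply(maf, function(q) rbinom(n_subjects, 2L, q), integer(n_subjects))
  g <- matrix(as.integer(g), nrow = n_subjects)
  colnames(g) <- paste0("snp", seq_along(maf))
  g
}

#' Simulate a binary phenotype from a penetrance odds model
#'
#' Each subject's case odds start at `prevalence / (1 - prevalence)` and are
#' multiplied by `or` for every effect whose target joint category the
#' subject carries; the phenotype is then Bernoulli with the implied
#' probability.  Effects are parameterized on the odds scale so planted
#' signals translate directly into the log odds-ratio terms of the W
#' statistic.
#'
#' @param g Genotype (or genotype-plus-recoded-methylation) matrix whose
#'   columns the effects reference.
#' @param prevalence Baseline case probability in (0, 1).
#' @param effects List of effects, each a list with `markers` (column names
#'   or indices into `g`), `category` (the target joint genotype tuple, same
#'   length) and `or` (odds multiplier > 0).
#' @param seed Optional integer seed.
#' @return Integer 0/1 vector of length `nrow(g)`.
#' @examples
#' g <- sim_genotypes(500, maf = rep(0.3, 4), seed = 1)
#' y <- sim_phenotype(g, prevalence = 0.4,
#'   effects = list(list(markers = c(1, 2), category = c(2, 2), or = 4)),
#'   seed = 2)
#' table(y)
#' @export
sim_phenotype <- function(g, prevalence = 0.5, effects = list(), seed = NULL) {
  if (is.data.frame(g)) g <- as.matrix(g)
  if (prevalence <= 0 || prevalence >= 1) abort("`prevalence` must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  odds <- rep(prevalence / (1 - prevalence), nrow(g))
  for (e in effects) {
    if (is.null(e$markers) || is.null(e$category) || is.null(e$or)) {
      abort("each effect needs `markers`, `category` and `or`")
    }
    if (e$or <= 0) abort("odds multipliers must be > 0")
    idx <- if (is.character(e$markers)) match(e$markers, colnames(g)) else as.integer(e$markers)
    if (anyNA(idx)) abort("effect references unknown marker(s)")
    sub <- g[, idx, drop = FALSE]
    hit <- rowSums(sub == matrix(e$category, nrow(g), length(idx), byrow = TRUE)) == length(idx)
    hit[is.na(hit)] <- FALSE
    odds[hit] <- odds[hit] * e$or
  }
  pr <- odds / (1 + odds)
  as.integer(rbinom(nrow(g), 1L, pr))
}

# Normal truncated to [0, 1] by inverse-CDF sampling.
rtnorm01 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(pmin(1, pmax(0, mean)), n))
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(runif(n, lo, hi), mean, sd)
}

#' Simulate bimodal methylation beta values
#'
#' Each CpG is a two-component mixture of normals truncated to [0, 1]: a
#' low-methylation component and a high-methylation component, mimicking the
#' bimodal shape of array beta values.
#'
#' @param n_subjects Number of subjects.
#' @param n_cpgs Number of CpG columns.
#' @param mean_low,mean_high Component means (defaults 0.2 and 0.8).
#' @param sd Common component standard deviation (default 0.07).
#' @param prop_high Mixing fraction of the high component (default 0.5);
#'   scalar or per-CpG vector.
#' @param seed Optional integer seed.
#' @return Numeric matrix (subjects x CpGs) in [0, 1], columns `cg1`, ...,
#'   with attribute `component` (the 0/1 mixture labels, same shape).
#' @export
sim_methylation <- function(n_subjects, n_cpgs, mean_low = 0.2, mean_high = 0.8,
                            sd = 0.07, prop_high = 0.5, seed = NULL) {
  if (mean_low >= mean_high) abort("`mean_low` must be below `mean_high`")
  if (any(prop_high < 0 | prop_high > 1)) abort("`prop_high` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  prop_high <- rep_len(prop_high, n_cpgs)
  z <- vapply(prop_high, function(p) rbinom(n_subjects, 1L, p), integer(n_subjects))
  z <- matrix(as.integer(z), nrow = n_subjects)
  beta <- matrix(0, n_subjects, n_cpgs)
  beta[z == 0L] <- rtnorm01(sum(z == 0L), mean_low, sd)
  beta[z == 1L] <- rtnorm01(sum(z == 1L), mean_high, sd)
  colnames(beta) <- paste0("cg", seq_len(n_cpgs))
  colnames(z) <- colnames(beta)
  attr(beta, "component") <- z
  beta
}

#' Simulate genomic positions for SNPs and CpGs
#'
#' Positions are drawn uniformly over the configured chromosome lengths;
#' markers are spread over chromosomes round-robin.  `planted_pairs` places
#' selected (SNP, CpG) pairs on the same chromosome at an exact distance, to
#' build cis candidates at controlled offsets.
#'
#' @param snp_ids,cpg_ids Character vectors of marker ids.
#' @param chr_lengths Named numeric vector: chromosome label -> length in bp.
#' @param planted_pairs Optional list of lists with `snp`, `cpg`, `distance`
#'   (bp), and optionally `chr` and `pos` (SNP position, default mid-
#'   chromosome).
#' @param seed Optional integer seed.
#' @return A list with tibbles `snps` and `cpgs`, each with columns `id`,
#'   `chr`, `pos`.
#' @export
sim_positions <- function(snp_ids, cpg_ids, chr_lengths = c("1" = 1e6),
                          planted_pairs = list(), seed = NULL) {
  if (is.null(names(chr_lengths))) abort("`chr_lengths` must be named by chromosome")
  if (!is.null(seed)) set.seed(seed)
  draw <- function(ids) {
    chr <- rep_len(names(chr_lengths), length(ids))
    pos <- vapply(chr, function(cc) sample.int(chr_lengths[[cc]], 1L), integer(1))
    tibble::tibble(id = ids, chr = chr, pos = as.integer(pos))
  }
  snps <- draw(snp_ids)
  cpgs <- draw(cpg_ids)
  for (pl in planted_pairs) {
    chr <- pl$chr %||% names(chr_lengths)[1]
    base <- as.integer(pl$pos %||% floor(chr_lengths[[chr]] / 2))
    snps$chr[snps$id == pl$snp] <- chr
    snps$pos[snps$id == pl$snp] <- base
    cpgs$chr[cpgs$id == pl$cpg] <- chr
    cpgs$pos[cpgs$id == pl$cpg] <- base + as.integer(pl$distance)
  }
  list(snps = snps, cpgs = cpgs)
}
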