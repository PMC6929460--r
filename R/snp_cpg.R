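# Gene-methylation interaction: beta-value binarization, cis-window pairing,
# and the SNP-CpG W-test scan.

# Two-means (Lloyd) clustering of one beta-value column, deterministic:
# centers initialized at the column min and max, assignments updated until
# stable (max 100 iterations), equidistant points join the low cluster.
recode_column <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (lo == hi) return(NULL)
  assign <- rep(NA_integer_, length(x))
  for (it in seq_len(100L)) {
    new <- as.integer(abs(x - hi) < abs(x - lo)) # ties -> low cluster
    if (identical(new, assign)) break
    assign <- new
    if (all(assign == 0L) || all(assign == 1L)) break
    lo <- mean(x[assign == 0L])
    hi <- mean(x[assign == 1L])
  }
  if (all(assign == 0L) || all(assign == 1L)) return(NULL)
  # the cluster with the larger center is "high" = 1 (hi > lo throughout)
  assign
}

#' Binarize methylation beta values by two-means clustering
#'
#' Each CpG column is clustered independently into a low- and a
#' high-methylation group with Lloyd's two-means algorithm (centers
#' initialized at the column minimum and maximum, so the result is
#' deterministic and seed-free).  The cluster with the larger center is coded
#' 1 (high), the other 0 (low).  CpGs that cannot be split into two groups
#' (constant, or collapsing to one cluster) are dropped with a warning.
#'
#' @param m Methylation matrix or data frame (subjects x CpGs), entries in
#'   [0, 1].
#' @return An integer 0/1 matrix with the recodable CpG columns, column names
#'   preserved; attribute `excluded_cpgs` lists dropped CpG ids.
#' @examples
#' recode_methylation(cbind(cg1 = c(0.1, 0.1, 0.9, 0.9)))
#' @export
recode_methylation <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || !is.numeric(m)) abort("`m` must be a numeric matrix or data frame")
  if (anyNA(m)) abort("methylation beta values must not be missing")
  if (any(m < 0 | m > 1)) {
    idx <- which(m < 0 | m > 1, arr.ind = TRUE)[1, ]
    abort(sprintf("beta values must lie in [0, 1]; offending entry at row %d, column %d",
                  idx[1], idx[2]))
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("cpg", seq_len(ncol(m)))
  if (anyDuplicated(colnames(m))) abort("CpG ids must be unique")

  codes <- lapply(seq_len(ncol(m)), function(j) recode_column(m[, j]))
  ok <- !vapply(codes, is.null, logical(1))
  if (!any(ok)) abort("no recodable CpGs: every column is constant")
  if (any(!ok)) {
    warn(sprintf("excluded %d constant-like CpG(s): %s", sum(!ok),
                 paste(head(colnames(m)[!ok], 5), collapse = ", ")))
  }
  out <- do.call(cbind, codes[ok])
  colnames(out) <- colnames(m)[ok]
  attr(out, "excluded_cpgs") <- colnames(m)[!ok]
  out
}

# Validate a position table: columns id, chr, pos.
as_position_table <- function(pos, arg = "pos") {
  pos <- tibble::as_tibble(pos)
  need <- c("id", "chr", "pos")
  if (!all(need %in% names(pos))) {
    abort(sprintf("`%s` must have columns id, chr, pos", arg))
  }
  if (anyDuplicated(pos$id)) abort(sprintf("duplicate ids in `%s`", arg))
  if (any(is.na(pos$pos)) || any(pos$pos < 1)) {
    abort(sprintf("positions in `%s` must be integers >= 1", arg))
  }
  pos
}

#' Candidate cis SNP-CpG pairs within a genomic window
#'
#' All (SNP, CpG) pairs on the same chromosome whose base-pair distance is at
#' most `window_size` (inclusive).  Chromosome labels are matched as
#' normalized strings ("chr6" and "6" are the same chromosome); pairing is
#' strand-agnostic.
#'
#' @param snp_pos,cpg_pos Position tables: data frames with columns `id`,
#'   `chr`, `pos` (1-based base pairs).
#' @param window_size Maximum distance in base pairs (default 10,000, the
#'   usual cis-regulation window).
#' @param snp_ids,cpg_ids Optional ids present in the genotype / methylation
#'   data; any of them missing from the position tables raises an error
#'   listing the offenders.
#' @return A tibble with columns `snp_id`, `cpg_id`, `chromosome`,
#'   `distance` (bp), sorted by (chromosome, snp_id, cpg_id).
#' @examples
#' snps <- data.frame(id = "rs1", chr = "6", pos = 1000)
#' cpgs <- data.frame(id = "cg1", chr = "chr6", pos = 5500)
#' pair_within_window(snps, cpgs, window_size = 10000)
#' @export
pair_within_window <- function(snp_pos, cpg_pos, window_size = 10000,
                               snp_ids = NULL, cpg_ids = NULL) {
  snp_pos <- as_position_table(snp_pos, "snp_pos")
  cpg_pos <- as_position_table(cpg_pos, "cpg_pos")
  if (window_size < 0) abort("`window_size` must be >= 0")
  missing_ids <- c(setdiff(snp_ids, snp_pos$id), setdiff(cpg_ids, cpg_pos$id))
  if (length(missing_ids) > 0) {
    abort(sprintf("ids present in data but absent from position tables: %s",
                  paste(missing_ids, collapse = ", ")))
  }

  s <- tibble::tibble(snp_id = snp_pos$id, chromosome = normalize_chrom(snp_pos$chr),
                      snp_bp = as.numeric(snp_pos$pos))
  c_ <- tibble::tibble(cpg_id = cpg_pos$id, chromosome = normalize_chrom(cpg_pos$chr),
                       cpg_bp = as.numeric(cpg_pos$pos))
  dplyr::inner_join(s, c_, by = "chromosome", relationship = "many-to-many") |>
    dplyr::mutate(distance = abs(.data$snp_bp - .data$cpg_bp)) |>
    dplyr::filter(.data$distance <= window_size) |>
    dplyr::select("snp_id", "cpg_id", "chromosome", "distance") |>
    dplyr::arrange(.data$chromosome, .data$snp_id, .data$cpg_id)
}

#' SNP-CpG interaction W-test scan
#'
#' Tests each candidate (SNP, CpG) pair: the CpG beta values are binarized
#' with [recode_methylation()], the joint categories of genotype (0/1/2) by
#' methylation level (low/high) form a k-by-2 table with k <= 6, and the
#' W-test is applied with per-k (h, f).  Pairs whose CpG is dropped by the
#' recode are skipped with a warning.
#'
#' @param g Genotype matrix (subjects x SNPs), entries 0/1/2/NA.
#' @param m Methylation beta-value matrix (subjects x CpGs) in [0, 1], or an
#'   already-recoded 0/1 matrix from [recode_methylation()].
#' @param y Binary phenotype vector.
#' @param pairs Candidate pairs from [pair_within_window()] (columns `snp_id`,
#'   `cpg_id`, and optionally `chromosome`, `distance`).
#' @param hf_table Optional calibrated `wscan_hf` from [w_calibrate_snp_cpg()].
#' @param output_pval Optional reporting threshold on p.
#' @param alpha Family-wise rate for the Bonferroni annotation (over the
#'   candidate pairs).
#' @param compat Default-h convention; see [default_hf()].
#' @return A tibble with one row per tested pair — `snp`, `cpg`,
#'   `chromosome`, `distance`, `k`, `h`, `f`, `w`, `p`, `rank` — sorted by p.
#' @export
w_scan_snp_cpg <- function(g, m, y, pairs, hf_table = NULL, output_pval = NULL,
                           alpha = 0.05, compat = "or_equivalent") {
  g <- as_genotype_matrix(g)
  y <- as_phenotype(y, nrow(g))
  already_binary <- is.matrix(m) && is.integer(m) && all(m %in% c(0L, 1L))
  mc <- if (already_binary) m else recode_methylation(m)
  if (nrow(mc) != nrow(g)) abort("genotype and methylation matrices must share subjects")
  if (is.null(pairs$snp_id) || is.null(pairs$cpg_id) || nrow(pairs) == 0L) {
    abort("`pairs` must be a non-empty table with columns snp_id and cpg_id")
  }

  bad_snp <- setdiff(pairs$snp_id, colnames(g))
  if (length(bad_snp) > 0) {
    abort(sprintf("pairs reference unknown SNP(s): %s", paste(bad_snp, collapse = ", ")))
  }
  excluded <- attr(mc, "excluded_cpgs") %||% character(0)
  bad_cpg <- setdiff(pairs$cpg_id, c(colnames(mc), excluded))
  if (length(bad_cpg) > 0) {
    abort(sprintf("pairs reference unknown CpG(s): %s", paste(bad_cpg, collapse = ", ")))
  }
  skip <- pairs$cpg_id %in% excluded
  if (any(skip)) {
    warn(sprintf("skipped %d pair(s) with constant-after-recode CpG(s)", sum(skip)))
    pairs <- pairs[!skip, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) abort("no testable pairs remain")

  comb <- cbind(g, mc)
  sets <- cbind(match(pairs$snp_id, colnames(g)),
                ncol(g) + match(pairs$cpg_id, colnames(mc)))
  ks <- w_set_sums_cpp(comb, y, sets)
  keep <- !is.na(ks$k)
  if (any(!keep)) {
    warn(sprintf("skipped %d degenerate pair(s)", sum(!keep)))
  }
  extra <- tibble::tibble(
    chromosome = if ("chromosome" %in% names(pairs)) pairs$chromosome[keep] else NA_character_,
    distance = if ("distance" %in% names(pairs)) pairs$distance[keep] else NA_real_
  )
  ids <- cbind(pairs$snp_id[keep], pairs$cpg_id[keep])
  res <- score_sets(ids, ks$k[keep], ks$s[keep], hf_table, compat, extra = extra)
  res <- dplyr::rename(res, snp = "marker1", cpg = "marker2")
  if (!is.null(output_pval)) {
    if (output_pval <= 0 || output_pval > 1) abort("`output_pval` must be in (0, 1]")
    res <- dplyr::filter(res, .data$p <= output_pval)
  }
  out <- new_scan_report(res, order = 2L, n_markers = ncol(g),
                         n_performed = sum(keep), output_pval = output_pval,
                         alpha = alpha)
  # the design here is the candidate pair list, not choose(n_snps, 2)
  attr(out, "n_tests_total_design") <- nrow(sets)
  attr(out, "bonferroni_threshold") <- alpha / nrow(sets)
  out
}
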