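#' Cross-tabulate a marker set against a binary phenotype
#'
#' Builds the k-by-2 contingency table underlying the W-test: each row is one
#' observed (non-empty) joint genotype category of the marker set, with the
#' number of cases (`n1`) and controls (`n0`) falling in it.  `k` is the
#' number of such categories.  Subjects with a missing genotype at any marker
#' in the set are excluded from this table only (listwise deletion per set, so
#' each test uses the maximal complete data for its own marker set).
#'
#' @param g Genotype matrix or data frame, subjects in rows, markers in
#'   columns, entries 0/1/2 (minor-allele count) or `NA`.
#' @param y Binary phenotype vector, 0 = control, 1 = case, one per subject.
#' @param markers Marker set: column names or indices (length = interaction
#'   order).
#'
#' @return A tibble with one row per non-empty joint category: one column per
#'   marker in the set (named by marker id) holding the genotype value, plus
#'   `n1` and `n0`.  Rows are ordered lexicographically on the genotype tuple.
#'   Attributes `k`, `N1`, `N0`, `n_excluded` and `marker_ids` record the
#'   category count, class totals, subjects dropped for missingness, and the
#'   set tested.
#'
#' @examples
#' g <- cbind(snp1 = c(0L, 0L, 1L, 1L, 2L, 2L))
#' partition_table(g, c(1, 0, 1, 0, 1, 0), "snp1")
#' @export
partition_table <- function(g, y, markers) {
  g <- as_genotype_matrix(g)
  y <- as_phenotype(y, nrow(g))
  idx <- resolve_markers(g, markers)

  sub <- g[, idx, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  if (!any(complete)) abort("empty table: every subject is missing a genotype in this marker set")
  sub <- sub[complete, , drop = FALSE]
  yy <- y[complete]
  if (all(yy == 1L) || all(yy == 0L)) {
    abort("degenerate phenotype: only one class remains after removing incomplete subjects")
  }

  # joint category code, base 3, lexicographic in the tuple
  code <- as.vector(sub %*% 3L^(rev(seq_along(idx)) - 1L))
  levs <- sort(unique(code))
  ci <- match(code, levs)
  n1 <- tabulate(ci[yy == 1L], nbins = length(levs))
  n0 <- tabulate(ci[yy == 0L], nbins = length(levs))

  # decode category tuples back to per-marker genotype values
  tuples <- matrix(0L, nrow = length(levs), ncol = length(idx))
  rem <- levs
  for (j in rev(seq_along(idx))) {
    tuples[, j] <- rem %% 3L
    rem <- rem %/% 3L
  }
  colnames(tuples) <- colnames(g)[idx]

  out <- tibble::as_tibble(as.data.frame(tuples))
  out$n1 <- n1
  out$n0 <- n0
  attr(out, "k") <- length(levs)
  attr(out, "N1") <- sum(yy == 1L)
  attr(out, "N0") <- sum(yy == 0L)
  attr(out, "n_excluded") <- sum(!complete)
  attr(out, "marker_ids") <- colnames(g)[idx]
  class(out) <- c("wscan_table", class(out))
  out
}
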