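# Main-effect, pairwise and high-order W-test scans with screening and
# multiple-testing thresholds.

#' Number of tests in a full scan design
#'
#' The combinatorial count of marker sets of a given order, `choose(n, order)`
#' — the denominator of the design-wide Bonferroni correction.
#'
#' @param n_markers Number of markers in the design.
#' @param order Interaction order.
#' @return A numeric count (exact up to 2^53).
#' @examples
#' count_tests(46181, 2)
#' @export
count_tests <- function(n_markers, order) {
  choose(as.numeric(n_markers), as.numeric(order))
}

#' Bonferroni-corrected significance threshold for a scan
#'
#' @inheritParams count_tests
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / count_tests(n_markers, order)`.
#' @examples
#' bonferroni_threshold(46181, 1) # main effects
#' bonferroni_threshold(46181, 2) # pairwise interactions
#' @export
bonferroni_threshold <- function(n_markers, order, alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1]")
  alpha / count_tests(n_markers, order)
}

#' Expected-cell-count feasibility of a high-order scan
#'
#' Under Hardy-Weinberg equilibrium and marker independence, the expected
#' count in each of the 3^order joint genotype cells is n times the product of
#' per-marker genotype probabilities ((1-q)^2, 2q(1-q), q^2).  An order is
#' considered feasible for a sample when no more than 25% of cells have
#' expected count below 2.
#'
#' @param n_subjects Sample size.
#' @param order Interaction order.
#' @param maf Minor allele frequency in (0, 0.5]; a scalar (shared by all
#'   markers in the set) or a vector of length `order`.
#' @return A one-row tibble: `n_subjects`, `order`, `n_cells`,
#'   `n_below_2`, `fraction_below`, `feasible`.
#' @examples
#' sample_size_feasibility(1000, 2, maf = 0.3)
#' @export
sample_size_feasibility <- function(n_subjects, order, maf) {
  if (any(maf <= 0) || any(maf > 0.5)) abort("`maf` must be in (0, 0.5]")
  order <- as.integer(order)
  if (length(maf) == 1L) maf <- rep(maf, order)
  if (length(maf) != order) abort("`maf` must have length 1 or `order`")
  cellp <- 1
  for (q in maf) {
    cellp <- as.vector(outer(cellp, c((1 - q)^2, 2 * q * (1 - q), q^2)))
  }
  expected <- n_subjects * cellp
  tibble::tibble(
    n_subjects = n_subjects, order = order,
    n_cells = length(expected),
    n_below_2 = sum(expected < 2),
    fraction_below = mean(expected < 2),
    feasible = mean(expected < 2) <= 0.25
  )
}

# Assemble a scan report tibble with its design metadata.
new_scan_report <- function(results, order, n_markers, n_performed,
                            input_pval = NULL, output_pval = NULL,
                            alpha = 0.05) {
  design <- count_tests(n_markers, order)
  attr(results, "order") <- order
  attr(results, "n_markers") <- n_markers
  attr(results, "n_tests_performed") <- n_performed
  attr(results, "n_tests_total_design") <- design
  attr(results, "bonferroni_threshold") <- alpha / design
  attr(results, "bonferroni_threshold_performed") <-
    if (n_performed > 0) alpha / n_performed else NA_real_
  attr(results, "input_pval") <- input_pval %||% NA_real_
  attr(results, "output_pval") <- output_pval %||% NA_real_
  class(results) <- c("wscan_scan", class(results))
  results
}

#' Main-effect W-test scan
#'
#' Tests every marker against the phenotype with the W-test (one k-by-2 table
#' per marker, k <= 3).  Markers with a single observed category are skipped
#' with a message; they still count towards the scan design size.
#'
#' @param g Genotype matrix or data frame (subjects x markers), entries
#'   0/1/2/NA.
#' @param y Binary phenotype vector (0 = control, 1 = case).
#' @param hf_table Optional calibrated `wscan_hf` table from [w_calibrate()];
#'   defaults per k via [default_hf()] otherwise.
#' @param alpha Family-wise rate used for the Bonferroni annotation.
#' @param compat Default-h convention; see [default_hf()].
#' @return A tibble with one row per tested marker — `marker`, `k`, `h`, `f`,
#'   `w`, `p`, `rank` — sorted by p (ties broken by marker id).  Attributes
#'   carry the design size and Bonferroni thresholds; see [glance()].
#' @examples
#' g <- sim_genotypes(300, maf = rep(0.3, 10), seed = 1)
#' y <- sim_phenotype(g, prevalence = 0.5, seed = 2)
#' w_scan_main(g, y)
#' @export
w_scan_main <- function(g, y, hf_table = NULL, alpha = 0.05,
                        compat = "or_equivalent") {
  g <- as_genotype_matrix(g)
  y <- as_phenotype(y, nrow(g))
  m <- ncol(g)
  sets <- matrix(seq_len(m), ncol = 1L)
  ks <- w_set_sums_cpp(g, y, sets)
  keep <- !is.na(ks$k)
  if (any(!keep)) {
    message(sprintf("skipped %d single-category (constant) marker(s)", sum(!keep)))
  }
  res <- score_sets(colnames(g)[keep], ks$k[keep], ks$s[keep], hf_table, compat)
  res <- dplyr::rename(res, marker = "marker1")
  new_scan_report(res, order = 1L, n_markers = m, n_performed = nrow(res),
                  alpha = alpha)
}

# Scale the raw sums by per-k (h, f), attach p-values, sort and rank.
# `ids` is a character matrix (sets x order) or vector (order 1).
score_sets <- function(ids, k, s, hf_table, compat = "or_equivalent",
                       extra = NULL) {
  ids <- as.matrix(ids)
  order <- ncol(ids)
  hfk <- lapply(
    stats::setNames(unique(k), unique(k)),
    function(kk) lookup_hf(kk, hf_table, compat)
  )
  kk <- as.character(k)
  h <- unname(vapply(kk, function(x) hfk[[x]]$h, numeric(1)))
  f <- unname(vapply(kk, function(x) hfk[[x]]$f, numeric(1)))
  w <- h * s
  p <- pmin(1, pmax(0, pchisq(w, df = f, lower.tail = FALSE)))
  out <- tibble::as_tibble(as.data.frame(ids, stringsAsFactors = FALSE))
  names(out) <- paste0("marker", seq_len(order))
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out <- dplyr::mutate(out, k = as.integer(k), h = unname(h), f = unname(f),
                       w = w, p = p)
  out <- dplyr::arrange(out, .data$p, !!!rlang::syms(paste0("marker", seq_len(order))))
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Screen interaction candidates by main-effect p-value
#'
#' @param main_report A report from [w_scan_main()].
#' @param input_pval Screening threshold in (0, 1]; markers with main-effect
#'   p <= `input_pval` pass.  `NULL` returns all tested markers.
#' @return Character vector of candidate marker ids.
#' @export
screen_candidates <- function(main_report, input_pval = NULL) {
  if (is.null(input_pval)) return(main_report$marker)
  if (input_pval <= 0 || input_pval > 1) abort("`input_pval` must be in (0, 1]")
  main_report$marker[main_report$p <= input_pval]
}

#' Pairwise and high-order interaction W-test scan
#'
#' Enumerates every size-`order` combination of the screened candidate
#' markers and tests it with the W-test on the joint genotype categories
#' (k <= 3^order non-empty cells).  Candidates are screened by main-effect
#' p-value when `input_pval` is set, mirroring the usual two-stage workflow;
#' constant markers are never part of a tested combination.
#'
#' @inheritParams w_scan_main
#' @param order Interaction order (>= 2).
#' @param input_pval Optional main-effect screening threshold in (0, 1].
#' @param output_pval Optional reporting threshold: only sets with p <=
#'   `output_pval` appear in the result.
#' @param max_sets Guard on the number of combinations actually tested;
#'   increase deliberately for large scans.
#' @return A tibble with one row per tested (and reported) set — columns
#'   `marker1..markerO`, `k`, `h`, `f`, `w`, `p`, `rank` — sorted by p.
#'   Attributes carry `n_tests_performed`, the full design count
#'   `n_tests_total_design = choose(n_markers, order)` (screening does not
#'   shrink the design used for the Bonferroni annotation), and both
#'   Bonferroni thresholds; see [glance()].
#' @examples
#' g <- sim_genotypes(300, maf = rep(0.3, 6), seed = 1)
#' y <- sim_phenotype(g, prevalence = 0.5, seed = 2)
#' w_scan_interactions(g, y, order = 2)
#' @export
w_scan_interactions <- function(g, y, order = 2L, input_pval = NULL,
                                output_pval = NULL, hf_table = NULL,
                                alpha = 0.05, max_sets = 2e6,
                                compat = "or_equivalent") {
  g <- as_genotype_matrix(g)
  y <- as_phenotype(y, nrow(g))
  order <- as.integer(order)
  if (order < 2L) abort("`order` must be >= 2; use w_scan_main() for main effects")
  if (!is.null(output_pval) && (output_pval <= 0 || output_pval > 1)) {
    abort("`output_pval` must be in (0, 1]")
  }
  m <- ncol(g)

  main <- w_scan_main(g, y, hf_table = hf_table, compat = compat)
  candidates <- screen_candidates(main, input_pval)
  empty <- function() {
    res <- tibble::as_tibble(stats::setNames(
      c(rep(list(character(0)), order),
        list(integer(0), numeric(0), numeric(0), numeric(0), numeric(0), integer(0))),
      c(paste0("marker", seq_len(order)), "k", "h", "f", "w", "p", "rank")
    ))
    new_scan_report(res, order, m, 0L, input_pval, output_pval, alpha)
  }
  if (length(candidates) < order) {
    warn(sprintf("only %d candidate marker(s) after screening; need at least %d",
                 length(candidates), order))
    return(empty())
  }
  n_comb <- count_tests(length(candidates), order)
  if (n_comb > max_sets) {
    abort(sprintf(
      "%.3g combinations exceed max_sets = %.3g; tighten `input_pval` or raise `max_sets`",
      n_comb, max_sets
    ))
  }

  cand_idx <- match(candidates, colnames(g))
  sets <- t(combn(cand_idx, order))
  ks <- w_set_sums_cpp(g, y, sets)
  keep <- !is.na(ks$k)
  n_performed <- sum(keep)
  if (n_performed == 0L) {
    warn("no testable combinations (all degenerate)")
    return(empty())
  }
  ids <- matrix(colnames(g)[sets[keep, , drop = FALSE]], ncol = order)
  res <- score_sets(ids, ks$k[keep], ks$s[keep], hf_table, compat)
  if (!is.null(output_pval)) {
    res <- dplyr::filter(res, .data$p <= output_pval)
  }
  new_scan_report(res, order, m, n_performed, input_pval, output_pval, alpha)
}

#' @export
glance.wscan_scan <- function(x, ...) {
  tibble::tibble(
    order = attr(x, "order"),
    n_markers = attr(x, "n_markers"),
    n_tests_performed = attr(x, "n_tests_performed"),
    n_tests_total_design = attr(x, "n_tests_total_design"),
    bonferroni_threshold = attr(x, "bonferroni_threshold"),
    bonferroni_threshold_performed = attr(x, "bonferroni_threshold_performed"),
    input_pval = attr(x, "input_pval"),
    output_pval = attr(x, "output_pval")
  )
}

#' @export
tidy.wscan_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "wscan_scan")
  out
}
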