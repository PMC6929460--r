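# Estimation of the W-test's null parameters (h, f) per category count k,
# from bootstrap replicates with permuted phenotypes.

# Draw n_sample distinct marker sets of a given order, uniformly and without
# replacement within one replicate.  Enumerates all combinations when cheap,
# otherwise rejection-samples distinct sorted tuples.
sample_marker_sets <- function(n_markers, order, n_sample, all_sets = NULL) {
  total <- choose(n_markers, order)
  n <- min(n_sample, total)
  if (order == 1L) {
    return(matrix(sample.int(n_markers, n), ncol = 1L))
  }
  if (!is.null(all_sets)) {
    return(all_sets[sample.int(nrow(all_sets), n), , drop = FALSE])
  }
  out <- matrix(0L, nrow = 0L, ncol = order)
  keys <- character(0)
  while (nrow(out) < n) {
    need <- n - nrow(out)
    draw <- t(vapply(
      seq_len(need),
      function(i) sort(sample.int(n_markers, order)),
      integer(order)
    ))
    key <- apply(draw, 1L, paste, collapse = "-")
    fresh <- !duplicated(key) & !(key %in% keys)
    out <- rbind(out, draw[fresh, , drop = FALSE])
    keys <- c(keys, key[fresh])
  }
  out
}

# Pre-enumerate combinations once when the design is small enough to reuse
# across replicates.
enumerate_if_small <- function(n_markers, order, limit = 2e5) {
  if (order > 1L && choose(n_markers, order) <= limit) {
    t(combn(n_markers, order))
  } else {
    NULL
  }
}

#' Null-permutation samples of the unscaled W sum, stratified by k
#'
#' Runs B bootstrap replicates: in each, the phenotype labels are randomly
#' permuted (breaking any genotype-phenotype association while preserving the
#' genotype structure and case/control totals), `n_sample` marker sets of the
#' requested order are drawn uniformly without replacement, and for each set
#' the unscaled sum \eqn{S = \sum_i (\log OR_i / SE_i)^2} and its category
#' count k are recorded.
#'
#' @param g Genotype matrix (subjects x markers), entries 0/1/2/NA.
#' @param y Binary phenotype vector.
#' @param order Interaction order of the sets drawn (>= 1).
#' @param B Number of permutation replicates.
#' @param n_sample Marker sets drawn per replicate.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `replicate`, `k`, `s` (one row per drawn
#'   set; sets with k < 2 are dropped).
#' @export
bootstrap_null_stats <- function(g, y, order = 1L, B = 400L, n_sample = 1000L,
                                 seed = NULL) {
  g <- as_genotype_matrix(g)
  y <- as_phenotype(y, nrow(g))
  order <- as.integer(order)
  if (order < 1L) abort("`order` must be >= 1")
  if (order > ncol(g)) abort("`order` exceeds the number of markers")
  if (B < 1L || n_sample < 1L) abort("`B` and `n_sample` must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  all_sets <- enumerate_if_small(ncol(g), order)
  res <- vector("list", B)
  for (b in seq_len(B)) {
    yp <- sample(y)
    sets <- sample_marker_sets(ncol(g), order, n_sample, all_sets)
    ks <- w_set_sums_cpp(g, yp, sets)
    keep <- !is.na(ks$k)
    res[[b]] <- tibble::tibble(replicate = b, k = ks$k[keep], s = ks$s[keep])
  }
  dplyr::bind_rows(res)
}

#' Moment-match (h, f) per k stratum from null samples
#'
#' Given null draws of the unscaled sum S stratified by k, fits per stratum
#' the scale and degrees of freedom under which h*S matches a chi-squared
#' distribution in its first two moments: with m = mean(S) and v = var(S),
#' h = 2m/v and f = 2m^2/v (so that h*m = f and h^2*v = 2f exactly).
#' Strata with fewer than `min_per_k` draws or zero variance fall back to
#' [default_hf()] with a warning.
#'
#' @param samples A tibble/data frame with columns `k` and `s` (as returned by
#'   [bootstrap_null_stats()]).
#' @param min_per_k Minimum draws required to calibrate a stratum (>= 2).
#' @param compat Default-h convention for fallback strata; see [default_hf()].
#' @return An `hf` table: tibble with columns `k`, `h`, `f`, `n_draws`,
#'   `source` ("calibrated" or "default"), class `wscan_hf`.
#' @export
moment_match_hf <- function(samples, min_per_k = 100L, compat = "or_equivalent") {
  if (is.null(samples$k) || is.null(samples$s) || nrow(samples) == 0L) {
    abort("`samples` must be a non-empty table with columns `k` and `s`")
  }
  if (min_per_k < 2L) abort("`min_per_k` must be >= 2")

  fit_one <- function(d) {
    k <- d$k[1]
    m <- mean(d$s)
    v <- var(d$s)
    if (nrow(d) >= min_per_k && is.finite(v) && v > 0 && m > 0) {
      tibble::tibble(
        k = k, h = 2 * m / v, f = 2 * m^2 / v,
        n_draws = nrow(d), source = "calibrated"
      )
    } else {
      warn(sprintf(
        "k = %d stratum has %d draw(s)%s; falling back to default (h, f)",
        k, nrow(d), if (nrow(d) >= min_per_k) " with zero variance" else ""
      ))
      d0 <- default_hf(k, compat = compat)
      d0$n_draws <- nrow(d)
      d0
    }
  }
  out <- samples |>
    dplyr::group_by(.data$k) |>
    dplyr::group_split() |>
    purrr::map(fit_one) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$k)
  class(out) <- c("wscan_hf", class(out))
  out
}

#' Calibrate (h, f) from a cohort by permutation-null bootstrap
#'
#' Composition of [bootstrap_null_stats()] and [moment_match_hf()]: the
#' standard first step of a W-test analysis.  Deterministic given `seed`.
#'
#' @inheritParams bootstrap_null_stats
#' @inheritParams moment_match_hf
#' @return A calibrated `wscan_hf` table (see [moment_match_hf()]), with
#'   attributes `B`, `n_sample`, `order`.
#' @examples
#' g <- sim_genotypes(200, maf = rep(0.3, 20), seed = 1)
#' y <- sim_phenotype(g, prevalence = 0.5, seed = 2)
#' w_calibrate(g, y, order = 1, B = 20, n_sample = 20, min_per_k = 50, seed = 3)
#' @export
w_calibrate <- function(g, y, order = 1L, B = 400L, n_sample = 1000L,
                        min_per_k = 100L, seed = NULL, compat = "or_equivalent") {
  samples <- bootstrap_null_stats(g, y, order = order, B = B,
                                  n_sample = n_sample, seed = seed)
  out <- moment_match_hf(samples, min_per_k = min_per_k, compat = compat)
  attr(out, "B") <- B
  attr(out, "n_sample") <- n_sample
  attr(out, "order") <- order
  out
}

#' Calibrate (h, f) for SNP-CpG pair tests
#'
#' Same permutation-null scheme as [w_calibrate()], but each drawn set is a
#' (SNP, recoded CpG) pair, so the null category structure (k <= 6) matches
#' the SNP-CpG interaction test.
#'
#' @param g Genotype matrix (subjects x SNPs).
#' @param m Methylation beta-value matrix (subjects x CpGs) in [0, 1]; it is
#'   binarized internally with [recode_methylation()].
#' @inheritParams bootstrap_null_stats
#' @inheritParams moment_match_hf
#' @return A calibrated `wscan_hf` table.
#' @export
w_calibrate_snp_cpg <- function(g, m, y, B = 400L, n_sample = 1000L,
                                min_per_k = 100L, seed = NULL,
                                compat = "or_equivalent") {
  g <- as_genotype_matrix(g)
  mc <- recode_methylation(m)
  y <- as_phenotype(y, nrow(g))
  if (nrow(mc) != nrow(g)) abort("genotype and methylation matrices must share subjects")
  if (B < 1L || n_sample < 1L) abort("`B` and `n_sample` must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  comb <- cbind(g, mc)
  ng <- ncol(g)
  total <- as.numeric(ng) * ncol(mc)
  res <- vector("list", B)
  for (b in seq_len(B)) {
    yp <- sample(y)
    n <- min(n_sample, total)
    pick <- if (total <= 2e5) {
      sample.int(total, n)
    } else {
      unique(sample.int(total, min(total, 2L * n)))[seq_len(n)]
    }
    sets <- cbind((pick - 1L) %% ng + 1L, ng + (pick - 1L) %/% ng + 1L)
    ks <- w_set_sums_cpp(comb, yp, sets)
    keep <- !is.na(ks$k)
    res[[b]] <- tibble::tibble(replicate = b, k = ks$k[keep], s = ks$s[keep])
  }
  out <- moment_match_hf(dplyr::bind_rows(res), min_per_k = min_per_k, compat = compat)
  attr(out, "B") <- B
  attr(out, "n_sample") <- n_sample
  attr(out, "order") <- 2L
  out
}

#' @export
tidy.wscan_hf <- function(x, ...) {
  tibble::tibble(k = x$k, h = x$h, f = x$f, n_draws = x$n_draws,
                 source = x$source)
}

#' @export
glance.wscan_hf <- function(x, ...) {
  tibble::tibble(
    n_strata = nrow(x),
    n_calibrated = sum(x$source == "calibrated"),
    B = attr(x, "B") %||% NA_integer_,
    n_sample = attr(x, "n_sample") %||% NA_integer_,
    order = attr(x, "order") %||% NA_integer_
  )
}

#' Cache an (h, f) calibration table to / from delimited text
#'
#' @param hf_table A `wscan_hf` table.
#' @param path File path (tab-delimited, columns `k`, `h`, `f`, `n_draws`,
#'   `source`).
#' @return `read_hf()` returns the `wscan_hf` table; `write_hf()` returns
#'   `path` invisibly.
#' @export
write_hf <- function(hf_table, path) {
  readr::write_tsv(tidy.wscan_hf(hf_table), path)
  invisible(path)
}

#' @rdname write_hf
#' @export
read_hf <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      k = readr::col_integer(), h = readr::col_double(),
      f = readr::col_double(), n_draws = readr::col_integer(),
      source = readr::col_character()
    )
  )
  if (any(out$h <= 0, na.rm = TRUE) || any(out$f <= 0, na.rm = TRUE)) {
    abort("hf table must have h > 0 and f > 0")
  }
  class(out) <- c("wscan_hf", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
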