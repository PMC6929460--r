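#' Per-category log odds ratios and squared standardized terms
#'
#' For each non-empty category i of a partition table, computes the log odds
#' ratio of category membership between cases and controls,
#' \eqn{\log[(\hat p_{1i}/(1-\hat p_{1i})) / (\hat p_{0i}/(1-\hat p_{0i}))]}
#' with \eqn{\hat p_{1i} = n_{1i}/N_1} and \eqn{\hat p_{0i} = n_{0i}/N_0},
#' its Woolf large-sample standard error
#' \eqn{SE_i = \sqrt{1/n_{1i} + 1/(N_1-n_{1i}) + 1/n_{0i} + 1/(N_0-n_{0i})}},
#' and the squared standardized term \eqn{z_i^2 = (\log OR_i / SE_i)^2}.
#'
#' Categories sitting on the table margin (a zero count, or a count equal to
#' its class total) get the Haldane-Anscombe correction: 0.5 is added to all
#' four counts entering that category's odds ratio, leaving other categories
#' untouched, so every term is finite.
#'
#' @param t A partition table from [partition_table()].
#' @return A tibble with one row per category: the genotype columns of `t`
#'   plus `n1`, `n0`, `log_or`, `se`, `z2`.
#' @examples
#' g <- cbind(snp1 = rep(0:1, c(100, 100)))
#' y <- rep(c(1, 0, 1, 0), c(30, 70, 70, 30))
#' cell_stats(partition_table(g, y, 1))
#' @export
cell_stats <- function(t) {
  k <- attr(t, "k")
  if (is.null(k)) abort("`t` must be a partition table from partition_table()")
  if (k < 2L) abort("single category: statistic undefined")
  N1 <- attr(t, "N1")
  N0 <- attr(t, "N0")

  a <- as.numeric(t$n1)
  c_ <- as.numeric(t$n0)
  b <- N1 - a
  d <- N0 - c_
  corr <- a <= 0 | b <= 0 | c_ <= 0 | d <= 0
  a[corr] <- a[corr] + 0.5
  b[corr] <- b[corr] + 0.5
  c_[corr] <- c_[corr] + 0.5
  d[corr] <- d[corr] + 0.5

  log_or <- log(a / b) - log(c_ / d)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  out <- dplyr::mutate(tibble::as_tibble(t),
    log_or = log_or, se = se, z2 = (log_or / se)^2
  )
  class(out) <- setdiff(class(out), "wscan_table")
  out
}

#' Default (h, f) parameters for a given category count
#'
#' Without calibration the W-test uses f = k - 1 degrees of freedom and the
#' scale h = (k - 1)/k, under which the k = 2 case coincides exactly with the
#' squared Wald log odds-ratio z-statistic of the 2-by-2 table.  The
#' alternative convention h = k/(k - 1), printed in some descriptions of the
#' statistic, is available via `compat = "printed"`; it breaks the 2-by-2
#' odds-ratio equivalence (quadrupling the statistic at k = 2) and is provided
#' for comparison only.
#'
#' @param k Number of non-empty joint categories (integer >= 2); vectorized.
#' @param compat `"or_equivalent"` (default, h = (k-1)/k) or `"printed"`
#'   (h = k/(k-1)).
#' @return A tibble with columns `k`, `h`, `f`, `n_draws` (NA for defaults)
#'   and `source = "default"`, one row per k.
#' @examples
#' default_hf(2:4)
#' @export
default_hf <- function(k, compat = c("or_equivalent", "printed")) {
  compat <- match.arg(compat)
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 2L)) abort("`k` must be >= 2")
  h <- if (compat == "printed") k / (k - 1) else (k - 1) / k
  tibble::tibble(k = k, h = h, f = k - 1, n_draws = NA_integer_, source = "default")
}

# Look up (h, f) for one k in a calibration table, falling back to defaults.
lookup_hf <- function(k, hf_table = NULL, compat = "or_equivalent") {
  if (!is.null(hf_table)) {
    hit <- which(hf_table$k == k)
    if (length(hit) == 1L) {
      return(list(h = hf_table$h[hit], f = hf_table$f[hit], source = hf_table$source[hit]))
    }
  }
  d <- default_hf(k, compat = compat)
  list(h = d$h, f = d$f, source = "default")
}

#' The W statistic and p-value for one marker set
#'
#' Computes \eqn{W = h \sum_{i=1}^{k} (\log OR_i / SE_i)^2} from a partition
#' table and refers it to a chi-squared distribution with f degrees of freedom
#' (f may be fractional when calibrated).
#'
#' @param t A partition table from [partition_table()].
#' @param hf Optional one-row (h, f) specification: a list or one-row data
#'   frame with elements `h` and `f`.  Defaults to [default_hf()] at the
#'   table's k.
#' @return A one-row tibble: `marker_ids` (comma-joined), `order`, `k`, `h`,
#'   `f`, `w`, `p`.
#' @examples
#' g <- cbind(snp1 = rep(0:1, c(100, 100)))
#' y <- rep(c(1, 0, 1, 0), c(30, 70, 70, 30))
#' w_statistic(partition_table(g, y, 1))
#' @export
w_statistic <- function(t, hf = NULL) {
  k <- attr(t, "k")
  cs <- cell_stats(t)
  if (is.null(hf)) hf <- default_hf(k)
  if (!is.null(hf$k) && length(hf$k) == 1L && hf$k != k) {
    abort(sprintf("hf parameters are for k = %d but the table has k = %d", hf$k, k))
  }
  h <- as.numeric(hf$h)
  f <- as.numeric(hf$f)
  if (length(h) != 1L || length(f) != 1L || h <= 0 || f <= 0) {
    abort("`hf` must supply scalar h > 0 and f > 0")
  }
  w <- h * sum(cs$z2)
  p <- min(1, max(0, pchisq(w, df = f, lower.tail = FALSE)))
  ids <- attr(t, "marker_ids")
  tibble::tibble(
    marker_ids = paste(ids, collapse = ","),
    order = length(ids), k = k, h = h, f = f, w = w, p = p
  )
}
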