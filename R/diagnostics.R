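# Post-test distributional diagnostics: per-k goodness of fit of the
# calibrated chi-squared reference, and p-value QQ data.

#' Per-k goodness-of-fit data for observed W statistics
#'
#' Groups observed W values by their category count k and pairs each group
#' with the chi-squared density at that k's (calibrated or default) degrees
#' of freedom.  Close agreement of histogram and curve indicates a good
#' (h, f) estimation; a Kolmogorov-Smirnov comparison per k provides the
#' numeric summary of the visual check.
#'
#' @param results A scan report (or any data frame with columns `w` and `k`).
#' @param hf_table Optional calibrated `wscan_hf` table; defaults per k
#'   otherwise.
#' @param compat Default-h convention; see [default_hf()].
#' @return A `wscan_diagnosis` object (list of tibbles):
#'   * `hist` — per-k histogram on the density scale (`k`, `mid`, `width`,
#'     `density`), Freedman-Diaconis bins with a floor of 10;
#'   * `curve` — per-k chi-squared density (`k`, `f`, `w`, `density`) on a
#'     grid covering `[0, max(W) * 1.1]`;
#'   * `gof` — per-k KS distance and p-value (`k`, `f`, `n`, `ks_stat`,
#'     `ks_p`).
#'   Plot with [autoplot()].
#' @export
w_diagnosis <- function(results, hf_table = NULL, compat = "or_equivalent") {
  if (is.null(results$w) || is.null(results$k) || nrow(results) == 0L) {
    abort("`results` must be a non-empty table with columns `w` and `k`")
  }
  groups <- split(results$w, results$k)

  one_k <- function(w, k) {
    f <- lookup_hf(k, hf_table, compat)$f
    nb <- max(10L, grDevices::nclass.FD(w))
    edges <- seq(min(w), max(w), length.out = nb + 1L)
    if (min(w) == max(w)) edges <- c(min(w) - 0.5, max(w) + 0.5)
    hh <- graphics::hist(w, breaks = edges, plot = FALSE)
    grid <- seq(0, max(w) * 1.1, length.out = 512L)
    list(
      hist = tibble::tibble(k = k, mid = hh$mids, width = diff(hh$breaks),
                            density = hh$density),
      curve = tibble::tibble(k = k, f = f, w = grid, density = dchisq(grid, df = f)),
      gof = {
        ks <- suppressWarnings(ks.test(w, "pchisq", df = f))
        tibble::tibble(k = k, f = f, n = length(w),
                       ks_stat = unname(ks$statistic), ks_p = ks$p.value)
      }
    )
  }
  parts <- purrr::imap(groups, function(w, kc) one_k(w, as.integer(kc)))
  out <- list(
    hist = purrr::map_dfr(parts, "hist"),
    curve = purrr::map_dfr(parts, "curve"),
    gof = purrr::map_dfr(parts, "gof")
  )
  class(out) <- "wscan_diagnosis"
  out
}

#' @export
tidy.wscan_diagnosis <- function(x, ...) x$gof

#' @export
print.wscan_diagnosis <- function(x, ...) {
  cat("W-test distributional diagnosis (", nrow(x$gof), " k stratum/strata)\n", sep = "")
  print(x$gof)
  invisible(x)
}

#' @export
autoplot.wscan_diagnosis <- function(object, ...) {
  ggplot2::ggplot(object$hist) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$mid - .data$width / 2,
                   xmax = .data$mid + .data$width / 2,
                   ymin = 0, ymax = .data$density),
      fill = "grey75", colour = "grey40", linewidth = 0.2
    ) +
    ggplot2::geom_line(
      data = object$curve,
      ggplot2::aes(x = .data$w, y = .data$density),
      colour = "red", linewidth = 0.6
    ) +
    ggplot2::facet_wrap(~k, scales = "free", labeller = ggplot2::label_both) +
    ggplot2::labs(x = "W statistic", y = "density",
                  title = "Observed W vs fitted chi-squared reference, by k") +
    ggplot2::theme_minimal()
}

#' Expected-vs-observed p-value quantiles for a QQ plot
#'
#' Sorts the observed p-values ascending and pairs them with the uniform
#' quantiles (i - 0.5)/n, both on the -log10 scale, plus the
#' genomic-inflation-style lambda (median observed chi-squared quantile over
#' the median of chi-squared_1).
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return A `wscan_qq` tibble with columns `expected` and `observed`
#'   (-log10 scale) and attribute `lambda`.  Plot with [autoplot()].
#' @examples
#' qq_data(runif(100))
#' @export
qq_data <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) == 0L || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`pvalues` must be a non-empty vector of values in [0, 1]")
  }
  n <- length(p)
  obs <- sort(p)
  expd <- (seq_len(n) - 0.5) / n
  lambda <- median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
  out <- tibble::tibble(expected = -log10(expd), observed = -log10(obs))
  attr(out, "lambda") <- lambda
  class(out) <- c("wscan_qq", class(out))
  out
}

#' @export
autoplot.wscan_qq <- function(object, ...) {
  lambda <- attr(object, "lambda")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red", linetype = 2) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      title = sprintf("P-value QQ (lambda = %.3f)", lambda)
    ) +
    ggplot2::theme_minimal()
}
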