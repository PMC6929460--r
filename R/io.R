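# Delimited-text readers and writers for genotypes, phenotypes, beta values,
# position tables and scan reports.  Comma or tab is auto-detected from the
# first line; subjects are rows, markers are columns.

detect_delim <- function(path) {
  first <- readr::read_lines(path, n_max = 1L)
  if (length(first) == 0L) abort(sprintf("`%s` is empty", path))
  if (grepl("\t", first)) "\t" else ","
}

read_cells <- function(path, delim = NULL) {
  delim <- delim %||% detect_delim(path)
  df <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE,
    name_repair = "minimal"
  )
  if (anyDuplicated(names(df))) abort(sprintf("duplicate column ids in `%s`", path))
  df
}

#' Read and write a genotype matrix
#'
#' Delimited text (comma or tab auto-detected), header row of marker ids, one
#' row per subject, entries 0/1/2; `NA`, an empty cell or a negative integer
#' denotes missing.  Any other entry is rejected with its row and column.
#'
#' @param path File path.
#' @param delim Optional delimiter override (`","` or `"\t"`).
#' @return `read_genotypes()` returns an integer matrix (subjects x markers).
#' @export
read_genotypes <- function(path, delim = NULL) {
  df <- read_cells(path, delim)
  out <- matrix(NA_integer_, nrow(df), ncol(df), dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    x <- trimws(df[[j]])
    miss <- x %in% c("NA", "") | grepl("^-\\d+$", x)
    ok <- miss | x %in% c("0", "1", "2")
    if (!all(ok)) {
      i <- which(!ok)[1]
      abort(sprintf("invalid genotype \"%s\" at row %d, column %d (%s) of `%s`",
                    x[i], i, j, names(df)[j], path))
    }
    xi <- rep(NA_integer_, length(x))
    xi[!miss] <- as.integer(x[!miss])
    out[, j] <- xi
  }
  out
}

#' @rdname read_genotypes
#' @param g Integer genotype matrix.
#' @export
write_genotypes <- function(g, path, delim = "\t") {
  df <- tibble::as_tibble(as.data.frame(g))
  readr::write_delim(df, path, delim = delim, na = "NA")
  invisible(path)
}

#' Read and write a binary phenotype vector
#'
#' Plain text, one 0/1 value per line, no header.
#'
#' @param path File path.
#' @return `read_phenotype()` returns an integer 0/1 vector.
#' @export
read_phenotype <- function(path) {
  x <- trimws(readr::read_lines(path))
  x <- x[x != ""]
  if (!all(x %in% c("0", "1"))) {
    i <- which(!x %in% c("0", "1"))[1]
    abort(sprintf("invalid phenotype \"%s\" at line %d of `%s` (need 0/1)", x[i], i, path))
  }
  as_phenotype(as.integer(x))
}

#' @rdname read_phenotype
#' @param y Integer 0/1 vector.
#' @export
write_phenotype <- function(y, path) {
  readr::write_lines(as.integer(y), path)
  invisible(path)
}

#' Read and write a methylation beta-value matrix
#'
#' Delimited text, header row of CpG ids, one row per subject, numeric
#' entries in [0, 1] (no missing values).
#'
#' @param path File path.
#' @param delim Optional delimiter override.
#' @return `read_beta()` returns a numeric matrix (subjects x CpGs).
#' @export
read_beta <- function(path, delim = NULL) {
  df <- read_cells(path, delim)
  out <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    x <- suppressWarnings(as.numeric(df[[j]]))
    bad <- is.na(x) | x < 0 | x > 1
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("invalid beta value \"%s\" at row %d, column %d (%s) of `%s`",
                    df[[j]][i], i, j, names(df)[j], path))
    }
    out[, j] <- x
  }
  out
}

#' @rdname read_beta
#' @param m Numeric beta matrix.
#' @export
write_beta <- function(m, path, delim = "\t") {
  df <- tibble::as_tibble(as.data.frame(m))
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Read and write a marker position table
#'
#' Delimited text with columns `id`, `chr`, `pos` (1-based base pairs).
#'
#' @param path File path.
#' @param delim Optional delimiter override.
#' @return `read_positions()` returns a tibble with columns `id`, `chr`,
#'   `pos`.
#' @export
read_positions <- function(path, delim = NULL) {
  delim <- delim %||% detect_delim(path)
  df <- readr::read_delim(
    path, delim = delim, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      id = readr::col_character(), chr = readr::col_character(),
      pos = readr::col_integer()
    )
  )
  as_position_table(df, path)
}

#' @rdname read_positions
#' @param pos A position table (columns `id`, `chr`, `pos`).
#' @export
write_positions <- function(pos, path, delim = "\t") {
  readr::write_delim(as_position_table(pos), path, delim = delim)
  invisible(path)
}

#' Write a scan report as a delimited table
#'
#' Marker-id columns, `k`, `w`, `p` and `rank`, with `w` and `p` in
#' scientific notation at 6 significant digits; one header line.
#'
#' @param report A scan report from [w_scan_main()], [w_scan_interactions()]
#'   or [w_scan_snp_cpg()].
#' @param path File path.
#' @param delim Delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(report, path, delim = "\t") {
  out <- tibble::as_tibble(report)
  for (col in intersect(c("w", "p"), names(out))) {
    out[[col]] <- sprintf("%.6e", out[[col]])
  }
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}
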