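# Input coercion and validation shared across modules.

# Coerce genotypes to an integer matrix (subjects x markers) with 0/1/2/NA
# entries.  Accepts a matrix or data frame; negative values become NA.
as_genotype_matrix <- function(g, arg = "g") {
  if (is.data.frame(g)) g <- as.matrix(g)
  if (!is.matrix(g)) abort(sprintf("`%s` must be a matrix or data frame", arg))
  storage.mode(g) <- "integer"
  g[!is.na(g) & g < 0L] <- NA_integer_
  bad <- !is.na(g) & (g < 0L | g > 2L)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "genotype entries must be 0, 1, 2 or NA; found %d at row %d, column %d",
      g[bad][1], idx[1], idx[2]
    ))
  }
  if (is.null(colnames(g))) colnames(g) <- paste0("m", seq_len(ncol(g)))
  if (anyDuplicated(colnames(g))) abort("marker ids must be unique")
  g
}

# Binary phenotype with at least one case and one control.
as_phenotype <- function(y, n_subjects = NULL) {
  y <- as.integer(unlist(y, use.names = FALSE))
  if (any(is.na(y)) || !all(y %in% c(0L, 1L))) {
    abort("phenotype must contain only 0 (control) and 1 (case)")
  }
  if (!is.null(n_subjects) && length(y) != n_subjects) {
    abort(sprintf(
      "phenotype length (%d) does not match number of subjects (%d)",
      length(y), n_subjects
    ))
  }
  if (all(y == 1L) || all(y == 0L)) abort("degenerate phenotype: need at least one case and one control")
  y
}

# Resolve marker identifiers (names or positions) to column indices.
resolve_markers <- function(g, markers) {
  if (is.character(markers)) {
    idx <- match(markers, colnames(g))
    if (anyNA(idx)) abort(sprintf("unknown marker id(s): %s", paste(markers[is.na(idx)], collapse = ", ")))
  } else {
    idx <- as.integer(markers)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > ncol(g))) {
      abort("marker indices out of bounds")
    }
  }
  if (anyDuplicated(idx)) abort("marker set must contain distinct markers")
  idx
}

# "chr6", "Chr6" and "6" refer to the same chromosome.
normalize_chrom <- function(chr) {
  sub("^chr", "", tolower(as.character(chr)))
}
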