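# Small in-code fixtures shared across tests.

# A genotype column engineered to give exact category counts:
# cases/controls per category supplied as vectors indexed by genotype value.
fixture_table <- function(n1, n0, values = seq_along(n1) - 1L) {
  g <- cbind(snp = rep(as.integer(values), n1 + n0))
  y <- unlist(mapply(function(a, b) c(rep(1L, a), rep(0L, b)), n1, n0,
                     SIMPLIFY = FALSE))
  partition_table(g, y, 1L)
}

# Null cohort: independent HWE genotypes, phenotype independent of genotype.
fixture_null_cohort <- function(n = 200, m = 10, maf = 0.3, seed = 1) {
  g <- sim_genotypes(n, maf = rep_len(maf, m), seed = seed)
  y <- sim_phenotype(g, prevalence = 0.5, seed = seed + 1000)
  list(g = g, y = y)
}

# Pure-R reference route for one marker set: partition_table + cell_stats +
# w_statistic, used as the oracle against the compiled kernel.
r_route_w <- function(g, y, markers, hf = NULL) {
  w_statistic(partition_table(g, y, markers), hf = hf)
}
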