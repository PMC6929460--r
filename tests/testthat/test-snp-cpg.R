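test_that("two-means recoding matches hand-run Lloyd iterations", {
  # well-separated clusters
  expect_equal(as.vector(recode_methylation(cbind(cg = c(0.1, 0.1, 0.9, 0.9)))),
               c(0L, 0L, 1L, 1L))
  # worked 5-point example: 0.5 joins the high cluster after one update
  expect_equal(as.vector(recode_methylation(cbind(cg = c(0.1, 0.2, 0.8, 0.85, 0.5)))),
               c(0L, 0L, 1L, 1L, 1L))
})

test_that("recoding is monotone and translation-invariant within a CpG", {
  set.seed(11)
  for (i in 1:20) {
    x <- runif(50)
    code <- as.vector(recode_methylation(cbind(cg = x)))
    # monotone: a larger beta never gets a smaller code
    ord <- order(x)
    expect_true(all(diff(code[ord]) >= 0))
    # translation by a constant (staying in [0,1]) preserves the split
    shift <- (1 - max(x)) / 2
    code2 <- as.vector(recode_methylation(cbind(cg = x + shift)))
    expect_equal(code2, code)
  }
})

test_that("constant CpGs are excluded and fully-constant input errors", {
  m <- cbind(cg1 = c(0.1, 0.2, 0.8, 0.9), cg2 = rep(0.5, 4))
  expect_warning(r <- recode_methylation(m), "cg2")
  expect_equal(colnames(r), "cg1")
  expect_equal(attr(r, "excluded_cpgs"), "cg2")
  expect_error(recode_methylation(cbind(a = rep(0.3, 5))), "no recodable")
  expect_error(recode_methylation(cbind(a = c(0.5, 1.5))), "beta values")
})

test_that("cis-window pairing matches an O(n^2) brute-force scan", {
  set.seed(12)
  snp_pos <- tibble::tibble(
    id = paste0("rs", 1:50),
    chr = sample(c("1", "2", "chr3"), 50, replace = TRUE),
    pos = sample.int(200000, 50)
  )
  cpg_pos <- tibble::tibble(
    id = paste0("cg", 1:50),
    chr = sample(c("chr1", "2", "3"), 50, replace = TRUE),
    pos = sample.int(200000, 50)
  )
  window <- 10000
  got <- pair_within_window(snp_pos, cpg_pos, window)
  brute <- list()
  for (i in 1:50) {
    for (j in 1:50) {
      same <- sub("^chr", "", snp_pos$chr[i]) == sub("^chr", "", cpg_pos$chr[j])
      if (same && abs(snp_pos$pos[i] - cpg_pos$pos[j]) <= window) {
        brute[[length(brute) + 1]] <- paste(snp_pos$id[i], cpg_pos$id[j])
      }
    }
  }
  expect_setequal(paste(got$snp_id, got$cpg_id), unlist(brute))
  expect_true(all(got$distance <= window))

  # invariant to row shuffling of either table
  got2 <- pair_within_window(snp_pos[sample(50), ], cpg_pos[sample(50), ], window)
  expect_equal(got, got2)
})

test_that("window boundaries are inclusive and chromosome-aware", {
  snps <- tibble::tibble(id = c("rs1", "rs2"), chr = c("6", "6"), pos = c(1000L, 1000L))
  cpgs <- tibble::tibble(id = c("cgA", "cgB", "cgC"),
                         chr = c("chr6", "6", "7"),
                         pos = c(1000L, 11000L, 1000L))
  got <- pair_within_window(snps, cpgs, 10000)
  expect_true("cgA" %in% got$cpg_id)            # distance 0
  expect_true("cgB" %in% got$cpg_id)            # distance == window, inclusive
  expect_false("cgC" %in% got$cpg_id)           # other chromosome
  got2 <- pair_within_window(snps, cpgs, 9999)
  expect_false("cgB" %in% got2$cpg_id)          # just beyond the window
  expect_error(
    pair_within_window(snps, cpgs, 1000, snp_ids = c("rs1", "rs9")),
    "rs9"
  )
})

test_that("SNP-CpG scan forms joint genotype-by-methylation categories", {
  set.seed(13)
  g <- sim_genotypes(300, maf = rep(0.3, 4))
  m <- sim_methylation(300, 3, seed = 14)
  y <- sim_phenotype(g, prevalence = 0.5, seed = 15)
  pairs <- tidyr::expand_grid(snp_id = colnames(g), cpg_id = colnames(m))
  res <- w_scan_snp_cpg(g, m, y, pairs)
  expect_equal(nrow(res), 12L)
  expect_true(all(res$k <= 6))
  expect_equal(res$p, sort(res$p))

  # k equals the brute-force joint category count, and w matches the R route
  mc <- recode_methylation(m)
  for (i in 1:3) {
    comb <- cbind(g, mc)
    ref <- r_route_w(comb, y, c(res$snp[i], res$cpg[i]))
    expect_equal(res$k[i], ref$k)
    expect_equal(res$w[i], ref$w, tolerance = 1e-10)
    brute_k <- nrow(unique(cbind(g[, res$snp[i]], mc[, res$cpg[i]])))
    expect_equal(res$k[i], brute_k)
  }

  expect_error(w_scan_snp_cpg(g, m, y, pairs[0, ]), "non-empty")
  bad <- tibble::tibble(snp_id = "nope", cpg_id = "cg1")
  expect_error(w_scan_snp_cpg(g, m, y, bad), "nope")
})

test_that("pairs with constant CpGs are skipped with a warning", {
  set.seed(16)
  g <- sim_genotypes(200, maf = rep(0.3, 2))
  m <- cbind(cg1 = runif(200), cg2 = rep(0.4, 200))
  y <- sim_phenotype(g, prevalence = 0.5)
  pairs <- tidyr::expand_grid(snp_id = colnames(g), cpg_id = colnames(m))
  expect_warning(
    expect_warning(res <- w_scan_snp_cpg(g, m, y, pairs), "cg2"),
    "constant-after-recode"
  )
  expect_equal(sort(unique(res$cpg)), "cg1")
})

test_that("a planted SNP-CpG interaction ranks first among null pairs", {
  set.seed(17)
  hits <- 0L
  reps <- 30L
  for (r in seq_len(reps)) {
    g <- sim_genotypes(1500, maf = rep(0.4, 21))
    m <- sim_methylation(1500, 21, seed = NULL)
    mc <- recode_methylation(m)
    y <- sim_phenotype(cbind(g, mc), prevalence = 0.3,
      effects = list(list(markers = c("snp1", "cg1"), category = c(2, 1), or = 6)))
    pairs <- tibble::tibble(snp_id = colnames(g), cpg_id = colnames(m))
    res <- w_scan_snp_cpg(g, m, y, pairs)
    if (res$snp[1] == "snp1" && res$cpg[1] == "cg1") hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})
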