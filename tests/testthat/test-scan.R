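test_that("design counts and Bonferroni thresholds are exact", {
  expect_equal(count_tests(5, 2), 10)
  expect_equal(count_tests(46181, 2), 1066319290)
  expect_equal(count_tests(46181, 3), 16413852830970)
  expect_equal(bonferroni_threshold(46181, 1), 0.05 / 46181)
  expect_equal(signif(bonferroni_threshold(46181, 1), 2), 1.1e-6)
  expect_equal(signif(bonferroni_threshold(46181, 2), 3), 4.69e-11)
  expect_equal(signif(bonferroni_threshold(46181, 3), 3), 3.05e-15)
  expect_error(bonferroni_threshold(10, 2, alpha = 0), "alpha")
})

test_that("expected-cell feasibility follows HWE arithmetic", {
  f1 <- sample_size_feasibility(100, 1, maf = 0.3)
  expect_equal(f1$n_cells, 3L)
  expect_equal(f1$fraction_below, 0)
  expect_true(f1$feasible)

  f2 <- sample_size_feasibility(50, 2, maf = 0.3)
  expect_equal(f2$n_cells, 9L)
  expect_equal(f2$n_below_2, 3L)
  expect_equal(f2$fraction_below, 1 / 3)
  expect_false(f2$feasible)

  f0 <- sample_size_feasibility(0, 2, maf = 0.3)
  expect_equal(f0$fraction_below, 1)
  expect_false(f0$feasible)
  expect_error(sample_size_feasibility(100, 1, maf = 0.7), "maf")
})

test_that("main-effect scan tests every polymorphic marker", {
  set.seed(2)
  g <- sim_genotypes(400, maf = runif(20, 0.2, 0.5))
  y <- sim_phenotype(g, prevalence = 0.5)
  res <- w_scan_main(g, y)
  expect_equal(nrow(res), 20L)
  expect_equal(res$p, sort(res$p))
  expect_equal(res$rank, 1:20)
  gl <- glance(res)
  expect_equal(gl$n_tests_performed, 20)
  expect_equal(gl$n_tests_total_design, 20)
  expect_equal(gl$bonferroni_threshold, 0.05 / 20)

  # constant markers are skipped but stay in the design count
  g2 <- cbind(g, fixed = rep(0L, 400))
  expect_message(res2 <- w_scan_main(g2, y), "constant")
  expect_equal(nrow(res2), 20L)
  expect_equal(glance(res2)$n_tests_total_design, 21)
})

test_that("a marker with identical case/control proportions gives w=0, p=1", {
  g <- cbind(bal = rep(c(0L, 0L, 1L, 1L, 2L, 2L), 10))
  y <- rep(c(1, 0), 30)
  res <- w_scan_main(g, y)
  expect_equal(res$w, 0)
  expect_equal(res$p, 1)
})

test_that("main-effect p matches the Wald odds-ratio test on a 2x2 marker", {
  set.seed(4)
  g <- cbind(bi = rbinom(500, 1L, 0.4))
  y <- sim_phenotype(g, prevalence = 0.4,
                     effects = list(list(markers = 1, category = 1, or = 2)))
  res <- w_scan_main(g, y)
  tab <- table(g[, 1], y)
  lor <- log(tab[2, 2] / tab[2, 1]) - log(tab[1, 2] / tab[1, 1])
  se <- sqrt(sum(1 / tab))
  expect_equal(res$w, (lor / se)^2, tolerance = 1e-10)
  expect_equal(res$p, pchisq((lor / se)^2, 1, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("null main-effect rejection rate stays near the nominal level", {
  set.seed(5)
  g <- sim_genotypes(500, maf = runif(100, 0.2, 0.5))
  y <- sim_phenotype(g, prevalence = 0.5)
  res <- w_scan_main(g, y)
  expect_lte(mean(res$p < 0.05), 0.12) # binomial 99.9% bound at 100 trials
})

test_that("screening selects candidates by main-effect p-value", {
  rep <- tibble::tibble(marker = c("a", "b", "c"), p = c(0.5, 1e-4, 0.02))
  expect_equal(screen_candidates(rep, 0.001), "b")
  expect_equal(screen_candidates(rep, NULL), c("a", "b", "c"))
  expect_equal(screen_candidates(rep, 1.0), c("a", "b", "c"))
  expect_error(screen_candidates(rep, 0), "input_pval")
  # monotone: smaller threshold never adds candidates
  for (thr in c(0.5, 0.05, 0.005)) {
    expect_true(all(screen_candidates(rep, thr / 10) %in% screen_candidates(rep, thr)))
  }
})

test_that("interaction scan enumerates exactly the screened combinations", {
  set.seed(6)
  g <- sim_genotypes(200, maf = rep(0.4, 5))
  y <- sim_phenotype(g, prevalence = 0.5)

  res <- w_scan_interactions(g, y, order = 2)
  expect_equal(nrow(res), 10L) # C(5,2)
  got <- apply(cbind(res$marker1, res$marker2), 1, function(r) paste(sort(r), collapse = "+"))
  want <- apply(combn(colnames(g), 2), 2, function(r) paste(sort(r), collapse = "+"))
  expect_setequal(got, want)
  expect_equal(glance(res)$n_tests_total_design, 10)

  # order 3 brute force
  res3 <- w_scan_interactions(g, y, order = 3)
  expect_equal(nrow(res3), choose(5, 3))

  # each reported pair agrees with the pure-R route
  for (i in 1:3) {
    ref <- r_route_w(g, y, c(res$marker1[i], res$marker2[i]))
    expect_equal(res$w[i], ref$w, tolerance = 1e-10)
    expect_equal(res$k[i], ref$k)
  }
})

test_that("screening and output thresholds shape the interaction report", {
  set.seed(61)
  g <- sim_genotypes(600, maf = rep(0.35, 5))
  y <- sim_phenotype(g, prevalence = 0.4,
                     effects = list(list(markers = 1, category = 2, or = 3),
                                    list(markers = 2, category = 2, or = 3)))
  main <- w_scan_main(g, y)
  thr <- sort(main$p)[2] # keep exactly two candidates
  res <- w_scan_interactions(g, y, order = 2, input_pval = thr)
  expect_equal(nrow(res), 1L)
  expect_equal(glance(res)$n_tests_performed, 1)
  expect_equal(glance(res)$n_tests_total_design, 10) # design stays C(5,2)

  # output_pval filters reported rows but not the performed count
  all_res <- w_scan_interactions(g, y, order = 2)
  some <- w_scan_interactions(g, y, order = 2, output_pval = median(all_res$p))
  expect_lt(nrow(some), nrow(all_res))
  expect_true(all(some$p <= median(all_res$p)))
  expect_equal(glance(some)$n_tests_performed, glance(all_res)$n_tests_performed)

  # too few candidates -> empty report with warning
  expect_warning(empty <- w_scan_interactions(g, y, order = 2, input_pval = 1e-12),
                 "candidate")
  expect_equal(nrow(empty), 0L)
  expect_error(w_scan_interactions(g, y, order = 1), "order")
})

test_that("a planted epistatic pair dominates an order-2 scan", {
  set.seed(62)
  g <- sim_genotypes(2000, maf = rep(0.4, 6))
  y <- sim_phenotype(g, prevalence = 0.3,
                     effects = list(list(markers = 1:2, category = c(2, 2), or = 8)))
  res <- w_scan_interactions(g, y, order = 2)
  top <- sort(c(res$marker1[1], res$marker2[1]))
  expect_equal(top, c("snp1", "snp2"))
})
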