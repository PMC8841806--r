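test_that("compute_tlr: ratio, scale invariance, positivity errors", {
  expect_equal(as.numeric(compute_tlr(2.2, 2.2)), 1.0)
  expect_equal(as.numeric(compute_tlr(6.8, 2.0)), 3.4)
  expect_equal(as.numeric(compute_tlr(3 * 6.8, 3 * 2.0)), 3.4)
  expect_error(compute_tlr(-1, 2), "suv_max")
  expect_error(compute_tlr(1, 0), "suv_mean")
})

test_that("tlr_phenotype uses the at-or-above-median rule", {
  res <- tlr_phenotype(c(1.1, 1.7, 6.8))
  expect_equal(res$median, 1.7)
  expect_identical(unname(res$labels), c("low", "high", "high"))

  expect_identical(unname(tlr_phenotype(rep(2, 4))$labels), rep("high", 4))

  set.seed(8)
  for (i in 1:10) {
    v <- round(runif(sample(4:15, 1), 1, 7), 2)
    got <- tlr_phenotype(v)
    med <- median(v)  # independent midpoint-of-order-statistics median
    expect_identical(got$labels, ifelse(v >= med, "high", "low"))
  }
  expect_error(tlr_phenotype(1.5), "2 patients")
})

test_that("gess is the per-sample mean z over present genes", {
  z <- matrix(c(0.5, 1, -1), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(as.numeric(gess(z, "a")), c(0.5, 0.5))
  expect_equal(as.numeric(gess(z, c("b", "c"))), c(0, 0))

  set.seed(12)
  zz <- matrix(rnorm(200), 20, 10,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  set10 <- sample(rownames(zz), 10)
  got <- gess(zz, set10)
  brute <- apply(zz[set10, ], 2, mean)
  expect_equal(got, brute, ignore_attr = TRUE)
  # permutation of genes within the set does not matter
  expect_equal(as.numeric(gess(zz, rev(set10))), as.numeric(got))
  # missing genes are logged, not fatal
  got2 <- gess(zz, c(set10, "absent"))
  expect_identical(attr(got2, "genes_missing"), "absent")
  expect_error(gess(zz, c("x", "y")), "no genes")
})

test_that("metabolic balance score: arithmetic, cancellation, antisymmetry", {
  set.seed(13)
  z <- matrix(rnorm(300), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  glu <- paste0("g", 1:5); lip <- paste0("g", 6:12)
  sc <- metabolic_balance_score(z, glu, lip)
  expect_equal(sc$mbs, sc$gess_glucose - sc$gess_lipid)
  expect_equal(sc$gess_glucose, as.numeric(gess(z, glu)))

  same <- metabolic_balance_score(z, glu, glu)
  expect_equal(same$mbs, rep(0, 10))

  swapped <- metabolic_balance_score(z, lip, glu)
  expect_equal(swapped$mbs, -sc$mbs)
})

test_that("stratify_by_cutoff assigns ties to high and saturates", {
  res <- stratify_by_cutoff(c(-0.1, 0, 0.1), cutoff = 0)
  expect_identical(unname(res$labels), c("low", "high", "high"))
  expect_equal(unname(res$sizes), c(2, 1))

  v <- rnorm(20)
  all_high <- stratify_by_cutoff(v, cutoff = min(v) - 1)
  expect_true(all(all_high$labels == "high"))

  set.seed(14)
  for (i in 1:10) {
    v <- rnorm(sample(3:30, 1))
    cut <- rnorm(1)
    got <- stratify_by_cutoff(v, cut)
    expect_identical(unname(got$labels), ifelse(v >= cut, "high", "low"))
  }
  expect_error(stratify_by_cutoff(numeric(0)), "1 sample")
})

test_that("on simulated cohorts MBS tracks uptake more than noise scores", {
  co <- fixture_cohort()
  d <- discovery_matrices(co)
  sc <- metabolic_balance_score(d$z, co$gene_sets$glucose,
                                co$gene_sets$lipid)
  r_mbs <- cor(sc$mbs, d$log2_tlr)
  expect_gt(r_mbs, 0)
  noise_genes <- names(co$truth$gene_labels)[
    co$truth$gene_labels == "background"][1:30]
  r_noise <- abs(cor(unname(gess(d$z, noise_genes)), d$log2_tlr))
  expect_gt(r_mbs, r_noise)
})
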