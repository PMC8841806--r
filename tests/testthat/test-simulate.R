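test_that("parameter validation lists offending fields", {
  expect_error(simulation_params(n_glucose = 800, n_lipid = 500,
                                 n_genes = 1000), "program sizes")
  expect_error(simulation_params(sigma_fc = -1), "positive")
  expect_error(simulation_params(seed = 2.5), "seed")
  expect_error(simulation_params(nonsense = 1), "unknown parameter")
})

test_that("same seed gives identical cohorts; component invariants hold", {
  a <- simulate_cohort(simulation_params(seed = 99, n_patients = 20,
                                         n_genes = 100))
  b <- simulate_cohort(simulation_params(seed = 99, n_patients = 20,
                                         n_genes = 100))
  expect_identical(a, b)
  c2 <- simulate_cohort(simulation_params(seed = 100, n_patients = 20,
                                          n_genes = 100))
  expect_false(identical(a$counts$counts, c2$counts$counts))

  expect_s3_class(a$counts, "counts_table")
  expect_true(all(a$counts$counts >= 0))
  expect_length(a$counts$pairing, 20)
  expect_true(all(a$clinical$tlr >= 1))
  expect_true(all(a$clinical$dfs_time > 0))
  expect_true(all(a$clinical$os_event %in% 0:1))
  expect_equal(as.numeric(a$clinical$tlr),
               a$clinical$suv_max / a$clinical$suv_mean_liver)
  expect_length(a$truth$latent, 20)
  expect_length(a$truth$mbs_true, 20)
  expect_equal(sum(a$truth$gene_labels == "glucose"), 9)
  expect_equal(sum(a$truth$gene_labels == "lipid"), 21)
})

test_that("global null simulation is calibrated at the 0.05 level", {
  null_params <- function(seed) simulation_params(
    seed = seed, n_genes = 300, n_glucose = 5, n_lipid = 5,
    beta_glu = 0, beta_lip = 0, gamma1 = 0, surv_beta = 0)
  hits <- 0; total <- 0
  for (seed in 1:10) {
    co <- simulate_cohort(null_params(seed))
    d <- discovery_matrices(co)
    scr <- screen_genes(d$fc, d$log2_tlr, rownames(d$fc), alpha = 0.05)
    hits <- hits + length(scr$positive) + length(scr$negative)
    total <- total + nrow(scr$records)
  }
  rate <- hits / total
  bound <- 2.576 * sqrt(0.05 * 0.95 / total)
  expect_gt(rate, 0.05 - bound)
  expect_lt(rate, 0.05 + bound)
})

test_that("true MBS tracks simulated uptake more tightly as TLR noise falls", {
  rs <- vapply(c(1.0, 0.5, 0.1), function(s) {
    co <- simulate_cohort(simulation_params(seed = 5, sigma_tlr = s,
                                            n_patients = 100,
                                            n_genes = 200))
    cor(co$truth$mbs_true, log2(pmax(co$clinical$tlr, 1)))
  }, numeric(1))
  expect_true(all(rs > 0))
  expect_true(all(diff(rs) > 0))
})

test_that("mutation asymmetry follows the latent axis", {
  co <- simulate_cohort(simulation_params(seed = 6, n_patients = 400,
                                          n_genes = 100))
  grp <- stratify_by_cutoff(co$truth$mbs_true, 0)$labels
  mut <- co$mutations
  rate <- function(gene, g) {
    flagged <- mut$sample[mut$gene == gene & mut$mutated == 1]
    mean(names(grp[grp == g]) %in% flagged)
  }
  expect_gt(rate("TP53", "high"), rate("TP53", "low"))
  expect_gt(rate("CTNNB1", "low"), rate("CTNNB1", "high"))
})

test_that("written cohort round-trips through the package readers", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(simulation_params(seed = 17, n_patients = 12,
                                          n_genes = 60))
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))

  back <- read_counts_tsv(paths[["counts"]], paths[["pairing"]])
  expect_equal(back$counts, co$counts$counts)
  expect_equal(back$pairing, co$counts$pairing)

  gmt <- read_gmt(paths[["gmt"]])
  expect_identical(gmt$glucose$genes, co$gene_sets$glucose)
  expect_identical(gmt$lipid$genes, co$gene_sets$lipid)
  expect_identical(gmt$candidates$genes, co$gene_sets$candidates)

  cl <- read_clinical_tsv(paths[["clinical"]])
  expect_equal(cl$tlr, co$clinical$tlr, tolerance = 1e-6)

  mt <- read_maf_lite(paths[["maf"]])
  flagged <- co$mutations[co$mutations$mutated == 1, ]
  expect_setequal(paste(mt$sample, mt$gene),
                  paste(flagged$sample, flagged$gene))
})
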