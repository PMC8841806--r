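#' @title Synthetic paired-cohort generator
#' @name simulate
#' @description Generates paired tumor/normal RNA-seq counts, PET uptake
#'   values, proportional-hazards survival and binary mutation labels
#'   with the statistical structure the analysis assumes: one latent
#'   per-patient axis drives the planted glucose program up, the planted
#'   lipid program down, log2 TLR, the hazard (through the true
#'   metabolic balance score) and the TP53/CTNNB1 mutation odds. All
#'   randomness flows from a single seed through fixed per-component
#'   substreams, so the same seed always reproduces the same cohort.
NULL

#' Default simulation parameters
#'
#' The defaults state the emulated study design: 60 patients with paired
#' tumor/normal samples, 1000 genes of which 9 form the glucose program
#' and 21 the lipid program, TLR centered so the cohort median is near
#' 1.7 with values spanning roughly 1.1-6.8, liver SUVmean ~ N(2.2,
#' 0.3), a survival log hazard ratio of 0.4 per MBS unit, and opposite
#' TP53/CTNNB1 mutation coupling to the latent axis.
#'
#' @param ... overrides for any parameter field.
#' @return validated parameter list.
#' @export
simulation_params <- function(...) {
  p <- list(
    n_patients = 60, n_genes = 1000,
    n_glucose = 9, n_lipid = 21,
    beta_glu = 1.0, beta_lip = 1.0,      # log2-FC units per latent SD
    gamma0 = 0.85, gamma1 = 0.55,        # log2-TLR intercept / slope
    sigma_fc = 0.8, sigma_tlr = 0.25,    # noise SDs
    nb_dispersion = 0.1,
    baseline_meanlog = log(200), baseline_sdlog = 1.2,
    lib_size_sdlog = 0.2,
    suv_mean_liver = 2.2, suv_mean_sd = 0.3,
    surv_h0 = 0.015,                     # baseline hazard per month
    surv_beta = 0.4,                     # log-HR per true-MBS unit
    cens_window = 120,                   # uniform censoring, months
    mut_delta0 = c(TP53 = -0.85, CTNNB1 = -1.0),
    mut_delta1 = 0.8,                    # TP53 slope; CTNNB1 uses -delta1
    seed = 1L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  errs <- character(0)
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(p$n_patients >= 2, "n_patients must be >= 2")
  chk(p$n_genes >= p$n_glucose + p$n_lipid,
      "program sizes exceed n_genes")
  chk(p$n_glucose >= 1 && p$n_lipid >= 1, "program sizes must be >= 1")
  chk(all(c(p$sigma_fc, p$sigma_tlr, p$nb_dispersion, p$surv_h0,
            p$cens_window, p$suv_mean_liver) > 0),
      "noise/hazard parameters must be positive")
  chk(is.numeric(p$seed) && p$seed >= 0 && p$seed == round(p$seed),
      "seed must be a non-negative integer")
  if (length(errs)) stop("invalid parameters: ", paste(errs, collapse = "; "))
  p$seed <- as.integer(p$seed)
  p
}

# Fixed substream seeds derived from the master seed; adding a component
# at the end never perturbs earlier components.
substream_seeds <- function(seed, n = 8L) {
  (as.numeric(seed) * 97L + 13L * seq_len(n)) %% (2^31 - 1)
}

#' Simulate a paired radiogenomic cohort
#'
#' Generative model: (1) latent axis `a_i ~ N(0,1)` per patient;
#' (2) per-gene baseline mean from a log-normal; (3) true log2 fold
#' change: glucose genes `+beta_glu * a_i`, lipid genes
#' `-beta_lip * a_i`, background 0, all plus `N(0, sigma_fc)` noise;
#' (4) paired normal/tumor counts drawn negative-binomial around the
#' implied means (library-size variation included); (5) `log2 TLR_i =
#' gamma0 + gamma1 * a_i + N(0, sigma_tlr)`, TLR floored at 1 (tumors
#' are never colder than liver); (6) exponential survival per endpoint
#' with hazard `h0 * exp(surv_beta * MBS_true_i)` and uniform censoring
#' over the window; (7) TP53 mutations `Bernoulli(plogis(delta0 +
#' delta1 * a_i))`, CTNNB1 with slope `-delta1`. The true MBS is the
#' balance score computed from the noiseless fold changes.
#'
#' @param params list from [simulation_params()].
#' @return list of class `synthetic_cohort`: `counts` (a
#'   [counts_table()] of tumor + paired normal samples), `clinical`
#'   (per-patient SUVs, TLR and DFS/OS columns), `mutations` (long
#'   mutation table), `gene_sets` (planted glucose/lipid programs),
#'   `truth` (latent axis, true fold changes, true MBS, planted labels,
#'   parameters).
#' @export
simulate_cohort <- function(params = simulation_params()) {
  params <- do.call(simulation_params, params)
  n <- params$n_patients; ng <- params$n_genes
  ss <- substream_seeds(params$seed)
  patients <- sprintf("P%03d", seq_len(n))
  tum <- paste0(patients, "_T"); nor <- paste0(patients, "_N")
  genes <- sprintf("G%04d", seq_len(ng))
  glu <- genes[seq_len(params$n_glucose)]
  lip <- genes[params$n_glucose + seq_len(params$n_lipid)]

  set.seed(ss[1]); a <- stats::rnorm(n)
  set.seed(ss[2])
  base_mu <- stats::rlnorm(ng, params$baseline_meanlog,
                           params$baseline_sdlog)
  set.seed(ss[3])
  slope <- stats::setNames(numeric(ng), genes)
  slope[glu] <- params$beta_glu
  slope[lip] <- -params$beta_lip
  fc_noise <- matrix(stats::rnorm(ng * n, 0, params$sigma_fc), ng, n)
  fc_true <- outer(slope, a) + fc_noise
  dimnames(fc_true) <- list(genes, patients)

  set.seed(ss[4])
  lib_scale <- stats::rlnorm(2 * n, 0, params$lib_size_sdlog)
  size <- 1 / params$nb_dispersion
  mu_n <- outer(base_mu, lib_scale[seq_len(n)])
  mu_t <- (base_mu * 2^fc_true) * rep(lib_scale[n + seq_len(n)],
                                      each = ng)
  counts_n <- matrix(stats::rnbinom(ng * n, mu = mu_n, size = size), ng, n)
  counts_t <- matrix(stats::rnbinom(ng * n, mu = mu_t, size = size), ng, n)
  cm <- cbind(counts_t, counts_n)
  dimnames(cm) <- list(genes, c(tum, nor))
  counts <- counts_table(cm, pairing = stats::setNames(nor, tum))

  # true MBS from the noiseless signal: balance of standardized true FCs
  z_true <- gene_zscores(fc_true)
  mbs_true <- metabolic_balance_score(z_true, glu, lip)$mbs

  set.seed(ss[5])
  log2_tlr <- params$gamma0 + params$gamma1 * a +
    stats::rnorm(n, 0, params$sigma_tlr)
  tlr <- pmax(2^log2_tlr, 1.0)
  suv_mean <- pmax(stats::rnorm(n, params$suv_mean_liver,
                                params$suv_mean_sd), 0.5)
  suv_max <- tlr * suv_mean

  set.seed(ss[6])
  hazard <- params$surv_h0 * exp(params$surv_beta * mbs_true)
  surv_one <- function() {
    ev_t <- stats::rexp(n, rate = hazard)
    cn_t <- stats::runif(n, 0, params$cens_window)
    list(time = pmin(ev_t, cn_t), event = as.integer(ev_t <= cn_t))
  }
  dfs <- surv_one(); os <- surv_one()

  set.seed(ss[7])
  p_tp53 <- stats::plogis(params$mut_delta0[["TP53"]] +
                          params$mut_delta1 * a)
  p_ctnnb1 <- stats::plogis(params$mut_delta0[["CTNNB1"]] -
                            params$mut_delta1 * a)
  mut_tp53 <- stats::rbinom(n, 1, p_tp53)
  mut_ctnnb1 <- stats::rbinom(n, 1, p_ctnnb1)
  mutations <- rbind(
    data.frame(sample = patients, gene = "TP53", mutated = mut_tp53),
    data.frame(sample = patients, gene = "CTNNB1", mutated = mut_ctnnb1))

  clinical <- data.frame(
    sample = patients, suv_max = suv_max, suv_mean_liver = suv_mean,
    tlr = tlr, dfs_time = dfs$time, dfs_event = dfs$event,
    os_time = os$time, os_event = os$event, stringsAsFactors = FALSE)

  # curated candidate list: the planted programs plus enough background
  # genes to reach 404 (the size of a manually curated metabolism list)
  n_extra <- min(max(404 - length(glu) - length(lip), 0),
                 ng - length(glu) - length(lip))
  candidates <- c(glu, lip,
                  setdiff(genes, c(glu, lip))[seq_len(n_extra)])

  structure(list(
    counts = counts, clinical = clinical, mutations = mutations,
    gene_sets = list(glucose = glu, lipid = lip,
                     candidates = candidates),
    truth = list(latent = stats::setNames(a, patients),
                 fc_true = fc_true, mbs_true =
                   stats::setNames(mbs_true, patients),
                 gene_labels = stats::setNames(
                   ifelse(genes %in% glu, "glucose",
                          ifelse(genes %in% lip, "lipid", "background")),
                   genes),
                 params = params)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(
    "synthetic_cohort: %d patients (paired), %d genes (%d glucose / %d lipid planted), seed=%d\n",
    p$n_patients, p$n_genes, p$n_glucose, p$n_lipid, p$seed))
  invisible(x)
}

#' Write a synthetic cohort to the pipeline's file formats
#'
#' Emits the exact formats the readers consume: counts TSV, pairing TSV,
#' clinical TSV, MAF-lite TSV (mutated pairs only), a GMT of the planted
#' programs, and a truth TSV (latent axis + true MBS per patient).
#'
#' @param cohort from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return named character vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cohort$truth$params$seed
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    expression = file.path(dir, "expression.tsv"),
    pairing = file.path(dir, "pairing.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    maf = file.path(dir, "mutations.maf.tsv"),
    gmt = file.path(dir, "planted_sets.gmt"),
    truth = file.path(dir, "truth.tsv"))
  write_counts_tsv(cohort$counts, paths[["counts"]],
                   header_comment = output_header(seed))
  # tumor-only expression keyed by patient id (validation-style input)
  tum <- cohort$counts$counts[, names(cohort$counts$pairing),
                              drop = FALSE]
  colnames(tum) <- sub("_T$", "", colnames(tum))
  write_counts_tsv(tum, paths[["expression"]],
                   header_comment = output_header(seed))
  write_tsv(data.frame(tumor_id = names(cohort$counts$pairing),
                       normal_id = unname(cohort$counts$pairing)),
            paths[["pairing"]], seed = seed)
  write_tsv(cohort$clinical, paths[["clinical"]], seed = seed)
  mut <- cohort$mutations[cohort$mutations$mutated == 1, ]
  write_tsv(data.frame(Hugo_Symbol = mut$gene,
                       Tumor_Sample_Barcode = mut$sample),
            paths[["maf"]], seed = seed)
  write_gmt(list(
    glucose = list(description = "planted glucose program",
                   genes = cohort$gene_sets$glucose),
    lipid = list(description = "planted lipid program",
                 genes = cohort$gene_sets$lipid),
    candidates = list(description = "curated metabolism candidate list",
                      genes = cohort$gene_sets$candidates)),
    paths[["gmt"]])
  write_tsv(data.frame(sample = names(cohort$truth$latent),
                       latent = unname(cohort$truth$latent),
                       mbs_true = unname(cohort$truth$mbs_true)),
            paths[["truth"]], seed = seed)
  paths
}

#' Write the small fixture cohort used by the test suite
#'
#' 60 patients, 1000 genes, default parameters, fixed seed.
#'
#' @param dir output directory.
#' @param seed master seed.
#' @return file paths, invisibly.
#' @export
write_fixture_cohort <- function(dir, seed = 20260911) {
  cohort <- simulate_cohort(simulation_params(seed = seed))
  invisible(write_cohort(cohort, dir))
}
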