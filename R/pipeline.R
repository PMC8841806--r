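#' @title Discovery and validation pipeline orchestration
#' @name pipeline
#' @description End-to-end runs driven by a YAML config: discovery
#'   (counts + TLR -> screened gene programs + signature scores + ORA)
#'   and validation (expression + survival -> Cox tables, prognostic
#'   index, risk groups, KM/log-rank, mutation tests). Every run writes
#'   a JSON manifest with input/output digests so identical inputs and
#'   seed reproduce identical outputs.
NULL

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE))
}

file_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  stats::setNames(as.character(tools::md5sum(paths)), basename(paths))
}

write_manifest <- function(out_dir, cfg, inputs, outputs, timings) {
  manifest <- list(
    package = "petmetab",
    version = as.character(utils::packageVersion("petmetab")),
    seed = cfg$seed, config = cfg,
    input_digests = as.list(file_digest(unlist(inputs))),
    output_digests = as.list(file_digest(unlist(outputs))),
    stage_seconds = timings)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the discovery analysis
#'
#' Normalization (TMM + CPM), paired log2 fold changes, per-gene
#' z-scores, Pearson screening against log2 TLR, sign-split gene
#' programs, GESS/MBS scoring and (when an ORA collection is supplied)
#' hypergeometric over-representation analysis. Writes screen records,
#' scores, the derived glucose/lipid GMT, reject/miss logs and a
#' manifest to `out_dir`.
#'
#' @param config YAML path or list; requires `paths$counts`,
#'   `paths$pairing`, `paths$clinical`, `paths$candidates` (GMT whose
#'   sets are pooled into the candidate list), optional
#'   `paths$ora_collection`.
#' @param out_dir output directory.
#' @return list with `screen`, `scores`, `ora`, `gene_sets`,
#'   `tlr_phenotype`, `manifest` (path).
#' @export
run_discovery <- function(config, out_dir) {
  cfg <- read_config(config)
  need <- c("counts", "pairing", "clinical", "candidates")
  miss <- setdiff(need, names(cfg$paths))
  if (length(miss))
    stop("config lacks input path(s): ", paste(miss, collapse = ", "))
  for (p in unlist(cfg$paths))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]; timings <- list()
  tick <- function(nm) {
    timings[[nm]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    t0 <<- proc.time()[["elapsed"]]
  }

  counts <- stage("read", read_counts_tsv(cfg$paths$counts,
                                          cfg$paths$pairing))
  clinical <- stage("read", read_clinical_tsv(cfg$paths$clinical))
  candidates_gmt <- stage("read", read_gmt(cfg$paths$candidates))
  candidates <- unique(unlist(lapply(candidates_gmt, `[[`, "genes")))
  tick("read")

  factors <- stage("normalize", tmm_factors(counts))
  mat <- stage("normalize", cpm(counts, factors))
  fc <- stage("normalize",
              paired_log2_fc(mat, mat, counts$pairing,
                             pseudocount = cfg$pseudocount))
  z <- stage("normalize", gene_zscores(fc))
  tick("normalize")

  rownames(clinical) <- clinical$sample
  patients <- sub("_T$", "", colnames(fc))
  pt_ids <- if (all(patients %in% clinical$sample)) patients else
    colnames(fc)
  if (!all(pt_ids %in% clinical$sample))
    stop("[stage screen] clinical table lacks patients: ",
         paste(setdiff(pt_ids, clinical$sample), collapse = ", "))
  tlr <- clinical[pt_ids, "tlr"]
  uptake <- if (cfg$tlr_scale == "log2") log2(tlr) else tlr
  screen_mat <- if (cfg$screen_input == "fold_change") fc else
    log2(mat[, colnames(fc), drop = FALSE] + cfg$pseudocount)
  scr <- stage("screen",
               screen_genes(screen_mat, uptake, candidates,
                            alpha = cfg$screen_alpha,
                            adjust = cfg$screen_adjust))
  message(sprintf(
    "[screen] seed=%s candidates=%d tested=%d positive=%d negative=%d",
    cfg$seed, length(candidates), nrow(scr$records),
    length(scr$positive), length(scr$negative)))
  tick("screen")

  gene_sets <- list(glucose = scr$positive, lipid = scr$negative)
  mbs <- stage("scoring",
               metabolic_balance_score(z, gene_sets$glucose,
                                       gene_sets$lipid))
  phen <- stage("scoring", tlr_phenotype(stats::setNames(tlr, pt_ids)))
  mbs$tlr <- tlr
  mbs$tlr_phenotype <- unname(phen$labels)
  ora <- NULL
  if (!is.null(cfg$paths$ora_collection)) {
    collection <- stage("ora", read_gmt(cfg$paths$ora_collection))
    ora <- list(
      positive = stage("ora", ora_hypergeometric(
        scr$positive, collection, candidates)),
      negative = stage("ora", ora_hypergeometric(
        scr$negative, collection, candidates)))
  }
  tick("scoring")

  outs <- c(
    screen = file.path(out_dir, "screen_records.tsv"),
    scores = file.path(out_dir, "signature_scores.tsv"),
    gmt = file.path(out_dir, "derived_programs.gmt"),
    rejects = file.path(out_dir, "gene_rejects.tsv"))
  write_tsv(scr$records, outs[["screen"]], seed = cfg$seed)
  write_tsv(mbs, outs[["scores"]], seed = cfg$seed)
  write_gmt(list(
    glucose = list(description = "positive correlation with uptake",
                   genes = gene_sets$glucose),
    lipid = list(description = "negative correlation with uptake",
                 genes = gene_sets$lipid)), outs[["gmt"]])
  rejects <- rbind(
    data.frame(gene = character(0), reason = character(0)),
    attr(z, "rejected"),
    if (length(scr$missing)) data.frame(gene = scr$missing,
                                        reason = "absent from matrix"),
    if (length(scr$skipped)) data.frame(gene = scr$skipped,
                                        reason = "constant"))
  write_tsv(rejects, outs[["rejects"]], seed = cfg$seed)
  if (!is.null(ora)) {
    outs[["ora_positive"]] <- file.path(out_dir, "ora_positive.tsv")
    outs[["ora_negative"]] <- file.path(out_dir, "ora_negative.tsv")
    write_tsv(ora$positive, outs[["ora_positive"]], seed = cfg$seed)
    write_tsv(ora$negative, outs[["ora_negative"]], seed = cfg$seed)
  }
  tick("write")
  manifest <- write_manifest(out_dir, cfg, cfg$paths, outs, timings)
  list(screen = scr, scores = mbs, ora = ora, gene_sets = gene_sets,
       tlr_phenotype = phen, outputs = outs, manifest = manifest)
}

#' Run the survival validation analysis
#'
#' Per endpoint: univariable Cox screen (p < `cox_alpha`), candidate
#' intersection across endpoints, greedy collinearity exclusion,
#' multivariable Cox, prognostic index with median split, KM and
#' log-rank. Then per-gene t-tests between risk groups, MBS scoring of
#' the validation expression with zero-cutoff stratification (with Cox
#' HR per risk group), and, when a mutation table is supplied,
#' chi-square tests for TP53 and CTNNB1 between MBS risk groups.
#'
#' @param config YAML path or list; requires `paths$expression`
#'   (gene x sample TSV), `paths$clinical` (with `<endpoint>_time` /
#'   `<endpoint>_event` columns), `paths$programs` (GMT with sets
#'   `glucose` and `lipid`), optional `paths$mutations` (MAF-lite).
#' @param out_dir output directory.
#' @return list with per-endpoint results (`cox_table`, `fit`,
#'   `risk_groups`, `km`, `logrank`), `biomarkers`, `ttests`, `mbs`
#'   (scores + groups + per-endpoint log-rank/HR), `mutation_tests`,
#'   `manifest`.
#' @export
run_validation <- function(config, out_dir) {
  cfg <- read_config(config)
  need <- c("expression", "clinical", "programs")
  miss <- setdiff(need, names(cfg$paths))
  if (length(miss))
    stop("config lacks input path(s): ", paste(miss, collapse = ", "))
  for (p in unlist(cfg$paths))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list(); t0 <- proc.time()[["elapsed"]]
  tick <- function(nm) {
    timings[[nm]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    t0 <<- proc.time()[["elapsed"]]
  }

  raw <- stage("read", read_counts_tsv(cfg$paths$expression))$counts
  expr <- if (cfg$expression_transform == "log2p1") log2(raw + 1) else raw
  clinical <- stage("read", read_clinical_tsv(cfg$paths$clinical,
                                              endpoints = cfg$endpoints))
  rownames(clinical) <- clinical$sample
  programs <- stage("read", read_gmt(cfg$paths$programs))
  tick("read")

  endpoints <- list()
  screens <- list()
  for (ep in cfg$endpoints) {
    tc <- paste0(ep, "_time"); ec <- paste0(ep, "_event")
    if (!all(c(tc, ec) %in% names(clinical))) next
    keep <- clinical$sample[!is.na(clinical[[tc]]) &
                            !is.na(clinical[[ec]])]
    keep <- intersect(keep, colnames(expr))
    if (!length(keep))
      stop("[stage screen_", ep,
           "] no overlap between expression samples and clinical table")
    scr <- stage(paste0("screen_", ep), univariable_screen(
      expr[, keep, drop = FALSE], clinical[keep, tc],
      clinical[keep, ec], alpha = cfg$cox_alpha, ties = cfg$ties))
    screens[[ep]] <- list(screen = scr, samples = keep)
    message(sprintf("[cox screen %s] seed=%s genes=%d retained=%d",
                    ep, cfg$seed, nrow(expr), nrow(scr$candidates)))
  }
  if (length(screens) < 1)
    stop("[stage screen] no endpoint has usable survival columns")
  tick("screen")

  biomarkers <- if (length(screens) >= 2)
    stage("intersect", intersect_candidates(screens[[1]]$screen,
                                            screens[[2]]$screen))
  else screens[[1]]$screen$candidates$gene
  message(sprintf("[intersect] biomarkers=%d (%s)", length(biomarkers),
                  paste(biomarkers, collapse = ", ")))

  outs <- c()
  for (ep in names(screens)) {
    keep <- screens[[ep]]$samples
    scr <- screens[[ep]]$screen
    cand <- scr$candidates$gene
    filt <- stage(paste0("collinearity_", ep), collinearity_filter(
      expr[, keep, drop = FALSE], cand, r_cutoff = cfg$collinearity_r))
    tc <- paste0(ep, "_time"); ec <- paste0(ep, "_event")
    fit <- if (length(filt$kept)) stage(paste0("cox_", ep), cox_fit(
      t(expr[filt$kept, keep, drop = FALSE]),
      clinical[keep, tc], clinical[keep, ec], ties = cfg$ties))
    bio_kept <- stage(paste0("pi_", ep), collinearity_filter(
      expr[, keep, drop = FALSE], biomarkers,
      r_cutoff = cfg$collinearity_r))
    bio_fit <- stage(paste0("pi_", ep), cox_fit(
      t(expr[bio_kept$kept, keep, drop = FALSE]),
      clinical[keep, tc], clinical[keep, ec], ties = cfg$ties))
    pi <- stage(paste0("pi_", ep),
                prognostic_index(bio_fit, expr[, keep, drop = FALSE]))
    rg <- stage(paste0("pi_", ep), median_split(pi))
    km <- stage(paste0("km_", ep), km_estimate(
      clinical[keep, tc], clinical[keep, ec], rg$labels))
    lr <- stage(paste0("km_", ep), logrank_test(
      clinical[keep, tc], clinical[keep, ec], rg$labels))

    uni <- scr$candidates
    names(uni)[-1] <- paste0("uni_", names(uni)[-1])
    if (!is.null(fit)) {
      multi <- fit$table
      names(multi) <- c("gene", paste0("multi_", names(multi)[-1]))
      tab <- merge(uni, multi, by = "gene", all.x = TRUE, sort = FALSE)
    } else tab <- uni
    tab <- tab[order(tab$uni_p), ]
    tab$excluded <- ifelse(tab$gene %in% filt$excluded$gene,
                           "collinearity", "")
    outs[[paste0("cox_", ep)]] <-
      file.path(out_dir, paste0("cox_", ep, ".tsv"))
    write_tsv(tab, outs[[paste0("cox_", ep)]], seed = cfg$seed)
    km_df <- do.call(rbind, lapply(names(km), function(g)
      cbind(group = g, km[[g]])))
    outs[[paste0("km_", ep)]] <-
      file.path(out_dir, paste0("km_", ep, ".tsv"))
    write_tsv(km_df, outs[[paste0("km_", ep)]], seed = cfg$seed)
    endpoints[[ep]] <- list(
      screen = scr, collinearity = filt, cox_table = tab, fit = fit,
      pi_fit = bio_fit, pi = pi, risk_groups = rg, km = km,
      logrank = lr, samples = keep)
  }
  tick("cox")

  # per-gene expression differences between risk groups (last endpoint's
  # grouping, i.e. OS when both endpoints are present)
  ep_t <- names(endpoints)[length(endpoints)]
  rg_t <- endpoints[[ep_t]]$risk_groups
  tt_rows <- lapply(biomarkers, function(g) {
    ht <- ttest_by_group(expr[g, endpoints[[ep_t]]$samples],
                         rg_t$labels, welch = cfg$welch)
    data.frame(gene = g, mean_high = ht$means[["high"]],
               mean_low = ht$means[["low"]], t = ht$t, p = ht$p)
  })
  ttests <- if (length(tt_rows)) do.call(rbind, tt_rows) else NULL

  # MBS scoring of the validation cohort: z-scores of the transformed
  # expression, zero-cutoff stratification, per-endpoint log-rank + HR
  z <- stage("mbs", gene_zscores(expr))
  scores <- stage("mbs", metabolic_balance_score(
    z, programs$glucose$genes, programs$lipid$genes))
  groups <- stage("mbs", stratify_by_cutoff(
    stats::setNames(scores$mbs, scores$sample), cutoff = cfg$mbs_cutoff))
  mbs_results <- list(scores = scores, groups = groups)
  for (ep in names(endpoints)) {
    keep <- endpoints[[ep]]$samples
    tc <- paste0(ep, "_time"); ec <- paste0(ep, "_event")
    lab <- groups$labels[keep]
    mbs_results[[ep]] <- list(
      logrank = logrank_test(clinical[keep, tc], clinical[keep, ec],
                             lab),
      cox = cox_fit(stats::setNames(
        data.frame(as.numeric(lab == "high")), "mbs_high"),
        clinical[keep, tc], clinical[keep, ec], ties = cfg$ties))
  }
  tick("mbs")

  mutation_tests <- NULL
  if (!is.null(cfg$paths$mutations)) {
    muts <- stage("mutations", read_maf_lite(cfg$paths$mutations))
    mutation_tests <- list()
    for (g in c("TP53", "CTNNB1")) {
      mutated <- unique(muts$sample[muts$gene == g])
      samples <- intersect(names(groups$labels), clinical$sample)
      tab <- table(
        factor(ifelse(samples %in% mutated, "mutant", "wildtype"),
               levels = c("mutant", "wildtype")),
        factor(groups$labels[samples], levels = c("high", "low")))
      mutation_tests[[g]] <- c(
        list(table = tab),
        stage("mutations", chisq_2x2(tab, yates = cfg$yates)))
    }
  } else {
    message("[mutations] no mutation table supplied; chi-square stage skipped")
  }
  tick("mutations")

  outs[["scores"]] <- file.path(out_dir, "validation_scores.tsv")
  sc_out <- scores
  sc_out$risk_group <- unname(groups$labels[sc_out$sample])
  write_tsv(sc_out, outs[["scores"]], seed = cfg$seed)
  if (!is.null(ttests)) {
    outs[["ttests"]] <- file.path(out_dir, "biomarker_ttests.tsv")
    write_tsv(ttests, outs[["ttests"]], seed = cfg$seed)
  }
  manifest <- write_manifest(out_dir, cfg, cfg$paths, outs, timings)
  list(endpoints = endpoints, biomarkers = biomarkers, ttests = ttests,
       mbs = mbs_results, mutation_tests = mutation_tests,
       outputs = outs, manifest = manifest,
       skipped_stages = if (is.null(mutation_tests)) "mutations" else
         character(0))
}
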