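#' @title Table and gene-set readers/writers
#' @description Readers for the plain-text formats the pipeline consumes:
#'   gene x sample count TSVs, tumor/normal pairing TSVs, clinical TSVs,
#'   GMT gene-set collections and MAF-lite mutation tables. All matching of
#'   gene and sample identifiers is exact and case-sensitive after
#'   whitespace stripping; no alias resolution is attempted.
#' @name io_formats
NULL

#' Construct a counts table
#'
#' A counts table holds non-negative integer read counts for genes (rows)
#' by samples (columns), optionally together with a tumor-to-normal sample
#' pairing used by the paired fold-change step.
#'
#' @param counts numeric matrix with unique rownames (genes) and colnames
#'   (samples); all values must be non-negative integers.
#' @param pairing optional named character vector mapping tumor sample id
#'   (name) to its paired normal sample id (value); every id must be a
#'   column of `counts`.
#' @return an object of class `counts_table` with elements `counts` and
#'   `pairing`.
#' @export
counts_table <- function(counts, pairing = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g))
    stop("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "double"
  if (!is.null(pairing)) {
    pairing <- stats::setNames(trimws(as.character(pairing)),
                               trimws(names(pairing)))
    miss <- setdiff(c(names(pairing), pairing), colnames(counts))
    if (length(miss))
      stop("pairing references unknown sample(s): ",
           paste(miss, collapse = ", "))
    if (anyDuplicated(names(pairing)) || anyDuplicated(pairing))
      stop("pairing must map each tumor sample to exactly one normal sample")
  }
  structure(list(counts = counts, pairing = pairing),
            class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  cat(sprintf("counts_table: %d genes x %d samples (%s paired)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$pairing)) "none" else length(x$pairing)))
  invisible(x)
}

#' Read a gene x sample count matrix from TSV
#'
#' First column holds gene identifiers, header row holds sample
#' identifiers. Row and column order are preserved. Optionally attaches a
#' two-column pairing TSV (`tumor_id<TAB>normal_id`, with header).
#'
#' @param path path to the counts TSV.
#' @param pairing_path optional path to the pairing TSV.
#' @return a [counts_table()].
#' @export
read_counts_tsv <- function(path, pairing_path = NULL) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("counts file needs a gene column plus >=1 sample: ",
                         path)
  genes <- trimws(as.character(df[[1]]))
  sample_ids <- colnames(df)[-1]  # as.matrix would dedup duplicate names
  m <- as.matrix(df[, -1, drop = FALSE])
  colnames(m) <- sample_ids
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                 !is.na(m), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric count at row %d, column '%s'",
                   bad[1, 1], colnames(m)[bad[1, 2]]))
    storage.mode(m) <- "double"
  }
  rownames(m) <- genes
  colnames(m) <- trimws(colnames(m))
  pairing <- if (!is.null(pairing_path)) read_pairing_tsv(pairing_path)
  counts_table(m, pairing = pairing)
}

#' Read a tumor/normal sample pairing TSV
#'
#' @param path two-column TSV (tumor_id, normal_id) with a header row.
#' @return named character vector: tumor id -> normal id.
#' @export
read_pairing_tsv <- function(path) {
  if (!file.exists(path)) stop("pairing file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2) stop("pairing file needs two columns: ", path)
  stats::setNames(trimws(as.character(df[[2]])),
                  trimws(as.character(df[[1]])))
}

#' Write a counts table (or any gene x sample matrix) to TSV
#'
#' @param x `counts_table` or matrix with dimnames.
#' @param path output path.
#' @param gene_col header name for the identifier column.
#' @param header_comment optional `#`-prefixed provenance line.
#' @export
write_counts_tsv <- function(x, path, gene_col = "gene",
                             header_comment = NULL) {
  m <- if (inherits(x, "counts_table")) x$counts else as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  writeLines(paste(c(gene_col, colnames(m)), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Expects one row per sample with a `sample` identifier column; imaging
#' columns (`tlr`, or `suv_max` plus `suv_mean_liver`) and survival
#' endpoint columns (`<endpoint>_time`, `<endpoint>_event`) are validated
#' when present. Missing cells may be empty or "NA". If `tlr` is absent
#' but both SUV components are present, TLR is derived as
#' `suv_max / suv_mean_liver`.
#'
#' @param path TSV path.
#' @param endpoints character vector of endpoint names to validate
#'   (e.g. `c("dfs","os")`); endpoints absent from the file are ignored.
#' @return data.frame keyed by `sample`.
#' @export
read_clinical_tsv <- function(path, endpoints = c("dfs", "os")) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings =
                            c("NA", ""), comment.char = "#")
  if (!"sample" %in% names(df)) stop("clinical table lacks a 'sample' column")
  df$sample <- trimws(as.character(df$sample))
  if (anyDuplicated(df$sample))
    stop("duplicate sample id(s) in clinical table: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  if (!"tlr" %in% names(df) &&
      all(c("suv_max", "suv_mean_liver") %in% names(df)))
    df$tlr <- df$suv_max / df$suv_mean_liver
  for (col in intersect(c("tlr", "suv_max", "suv_mean_liver"), names(df)))
    if (any(df[[col]] <= 0, na.rm = TRUE))
      stop("non-positive values in clinical column '", col, "'")
  for (ep in endpoints) {
    tc <- paste0(ep, "_time"); ec <- paste0(ep, "_event")
    if (tc %in% names(df) && ec %in% names(df)) {
      ok <- !is.na(df[[tc]]) & !is.na(df[[ec]])
      if (any(df[[tc]][ok] <= 0))
        stop("non-positive survival time in '", tc, "'")
      if (!all(df[[ec]][ok] %in% c(0, 1)))
        stop("events in '", ec, "' must be 0/1")
    }
  }
  df
}

#' Read a GMT gene-set collection
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Empty trailing fields are dropped and gene identifiers are stripped of
#' surrounding whitespace.
#'
#' @param path GMT path.
#' @return named list; each element is `list(description=, genes=)`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    f <- f[nzchar(f) | seq_along(f) <= 2]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nm <- f[[1]]
    if (nm %in% names(sets))
      stop("duplicate gene-set name in GMT: ", nm)
    genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (!length(genes))
      stop(sprintf("GMT line %d ('%s') has no genes", i, nm))
    sets[[nm]] <- list(description = f[[2]], genes = genes)
  }
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param collection named list as returned by [read_gmt()]; elements may
#'   also be bare character vectors of gene ids.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    if (is.character(s)) s <- list(description = "", genes = s)
    paste(c(nm, if (nzchar(s$description)) s$description else "na",
            s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a MAF-lite mutation table
#'
#' Accepts any tab-separated file carrying the standard MAF columns
#' `Hugo_Symbol` and `Tumor_Sample_Barcode`; all other columns are
#' ignored. Every (sample, gene) pair appearing at least once is flagged
#' mutated; duplicate variant rows collapse to one flag. No variant
#' classification filtering is applied: any listed variant counts.
#'
#' @param path MAF(-lite) TSV path.
#' @return data.frame with columns `sample`, `gene`, `mutated` (all 1).
#' @export
read_maf_lite <- function(path) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("MAF file missing required column(s): ",
         paste(miss, collapse = ", "))
  pairs <- unique(data.frame(
    sample = trimws(as.character(df$Tumor_Sample_Barcode)),
    gene = trimws(as.character(df$Hugo_Symbol)),
    stringsAsFactors = FALSE))
  pairs$mutated <- 1L
  rownames(pairs) <- NULL
  pairs
}

#' Read and validate an analysis configuration (YAML)
#'
#' Fills defaults for thresholds and numerical choices; validates ranges.
#'
#' @param path YAML path, or a pre-parsed list.
#' @return validated config list.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    screen_alpha = 0.05, cox_alpha = 0.1, collinearity_r = 0.8,
    mbs_cutoff = 0, pseudocount = 0.5, seed = 1L,
    tlr_scale = "log2",        # or "raw": uptake variable for screening
    screen_input = "fold_change",  # or "tumor": expression fed to screen
    expression_transform = "log2p1",  # validation expression: log2(x+1)
    screen_adjust = "none",    # or "BH"
    ties = "efron", welch = TRUE, yates = TRUE,
    endpoints = c("dfs", "os"), paths = list())
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (a in c("screen_alpha", "cox_alpha"))
    if (!(cfg[[a]] > 0 && cfg[[a]] < 1))
      stop("config: ", a, " must lie in (0, 1)")
  if (cfg$pseudocount <= 0) stop("config: pseudocount must be > 0")
  if (!(is.numeric(cfg$seed) && cfg$seed >= 0 && cfg$seed == round(cfg$seed)))
    stop("config: seed must be a non-negative integer")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# Shared provenance line for TSV outputs.
output_header <- function(seed) {
  sprintf("petmetab %s seed=%s",
          as.character(utils::packageVersion("petmetab")), seed)
}

#' Write a data frame to TSV with a provenance comment line
#'
#' @param df data.frame.
#' @param path output path.
#' @param seed seed recorded in the header comment.
#' @export
write_tsv <- function(df, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", output_header(seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
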