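#' @title Imaging and gene-set signature scoring
#' @name scoring
#' @description The tumor-to-liver uptake ratio (TLR), gene-set signature
#'   scores (GESS, the per-sample mean z-score over a gene set), the
#'   metabolic balance score (MBS = GESS glucose - GESS lipid) and
#'   cutoff-based phenotype/risk assignment. Ties at a cutoff are always
#'   assigned to the high group (score >= cutoff), mirroring the
#'   at-or-above-median TLR phenotype rule.
NULL

#' Tumor-to-liver SUV ratio
#'
#' `TLR = SUVmax(tumor) / SUVmean(normal liver)`; dimensionless and
#' invariant under common rescaling of both inputs.
#'
#' @param suv_max tumor SUVmax (> 0); vectorized.
#' @param suv_mean normal-liver SUVmean (> 0); vectorized.
#' @return numeric TLR with attributes `suv_max`, `suv_mean`.
#' @export
compute_tlr <- function(suv_max, suv_mean) {
  if (any(!is.finite(suv_max)) || any(suv_max <= 0))
    stop("suv_max must be positive")
  if (any(!is.finite(suv_mean)) || any(suv_mean <= 0))
    stop("suv_mean must be positive")
  structure(suv_max / suv_mean, suv_max = suv_max, suv_mean = suv_mean)
}

#' High/low TLR phenotype by median split
#'
#' A tumor is "high" iff its TLR is at or above the cohort median (the
#' midpoint-of-order-statistics median for even n).
#'
#' @param tlrs per-patient TLR values (>= 2 patients).
#' @return list with `labels` ("high"/"low", named if `tlrs` is) and
#'   `median`.
#' @export
tlr_phenotype <- function(tlrs) {
  if (length(tlrs) < 2) stop("need at least 2 patients")
  med <- stats::median(tlrs)
  labels <- ifelse(tlrs >= med, "high", "low")
  names(labels) <- names(tlrs)
  list(labels = labels, median = med)
}

#' Gene expression signature score (GESS)
#'
#' Per sample, the unweighted mean z-score over the genes of a set.
#' Genes absent from the matrix are skipped and recorded, not errors:
#' external cohorts rarely carry a curated set in full.
#'
#' @param z gene x sample z-score matrix (see [gene_zscores()]).
#' @param set character vector of gene ids (or a `list(genes=)` GMT
#'   entry).
#' @param set_name label used in error messages and logs.
#' @return named per-sample numeric vector with attributes `genes_used`
#'   and `genes_missing`.
#' @export
gess <- function(z, set, set_name = deparse(substitute(set))) {
  genes <- if (is.list(set)) set$genes else set
  genes <- unique(trimws(genes))
  used <- intersect(genes, rownames(z))
  if (!length(used))
    stop("gene set '", set_name, "' has no genes in the matrix")
  scores <- colMeans(z[used, , drop = FALSE])
  structure(scores, genes_used = used,
            genes_missing = setdiff(genes, used))
}

#' Metabolic balance score (MBS)
#'
#' `MBS = GESS(glucose program) - GESS(lipid program)` per sample;
#' positive values indicate glycolytic dominance over fatty-acid
#' metabolism.
#'
#' @param z gene x sample z-score matrix.
#' @param glucose,lipid gene sets (character vectors or GMT entries).
#' @return data.frame (sample, gess_glucose, gess_lipid, mbs) with
#'   attributes `genes_used` and `genes_missing` (per-set lists).
#' @export
metabolic_balance_score <- function(z, glucose, lipid) {
  g <- gess(z, glucose, set_name = "glucose")
  l <- gess(z, lipid, set_name = "lipid")
  structure(
    data.frame(sample = colnames(z), gess_glucose = as.numeric(g),
               gess_lipid = as.numeric(l),
               mbs = as.numeric(g) - as.numeric(l),
               stringsAsFactors = FALSE),
    genes_used = list(glucose = attr(g, "genes_used"),
                      lipid = attr(l, "genes_used")),
    genes_missing = list(glucose = attr(g, "genes_missing"),
                         lipid = attr(l, "genes_missing")))
}

#' Two-group stratification by a score cutoff
#'
#' "high" iff score >= cutoff (zero by default, the balanced-metabolism
#' point of the MBS).
#'
#' @param scores per-sample numeric values.
#' @param cutoff threshold.
#' @return list of class `risk_groups`: `labels` ("high"/"low"),
#'   `threshold`, `rule`, `sizes`.
#' @export
stratify_by_cutoff <- function(scores, cutoff = 0) {
  if (!length(scores)) stop("need at least 1 sample")
  labels <- ifelse(scores >= cutoff, "high", "low")
  names(labels) <- names(scores)
  structure(list(labels = labels, threshold = cutoff,
                 rule = "score >= cutoff",
                 sizes = c(high = sum(labels == "high"),
                           low = sum(labels == "low"))),
            class = "risk_groups")
}

#' @export
print.risk_groups <- function(x, ...) {
  cat(sprintf("risk_groups (%s, threshold=%g): high=%d low=%d\n",
              x$rule, x$threshold, x$sizes[["high"]], x$sizes[["low"]]))
  invisible(x)
}
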