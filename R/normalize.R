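#' @title Count normalization, paired fold changes and z-scores
#' @name normalize
#' @description TMM scaling factors (trimmed mean of M-values), CPM,
#'   paired tumor/normal log2 fold changes and per-gene z-scores. TMM is
#'   implemented from its published definition; the trim fractions default
#'   to the canonical 30% (M) and 5% (A) per tail.
NULL

# Weighted trimmed mean of M-values for one sample against the reference.
# Returns 2^(precision-weighted mean of doubly trimmed M), with weights
# from the delta-method binomial variance of M.
tmm_pair_factor <- function(obs, ref, lib_obs, lib_ref,
                            trim_m = 0.30, trim_a = 0.05) {
  m <- log2((obs / lib_obs) / (ref / lib_ref))
  a <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  w <- (lib_obs - obs) / lib_obs / obs + (lib_ref - ref) / lib_ref / ref
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (!length(m)) return(NA_real_)
  if (max(abs(m)) < 1e-6) return(1)  # identical composition: factor 1 exactly
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
          rank(a) >= lo_a & rank(a) <= hi_a
  f <- sum(m[keep] / w[keep], na.rm = TRUE) / sum(1 / w[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' TMM scaling factors
#'
#' Computes per-sample trimmed-mean-of-M-values normalization factors.
#' The reference is the sample whose upper-quartile count proportion is
#' closest to the mean upper quartile (ties broken by lexicographically
#' first sample id). Per sample, gene-wise log ratios M and average
#' abundances A against the reference are formed over genes nonzero in
#' both; both tails of M and A are trimmed; the factor is 2 to the
#' precision-weighted mean of the surviving M values. Factors are finally
#' rescaled to geometric mean 1.
#'
#' @param counts a [counts_table()] or gene x sample matrix.
#' @param trim_m fraction trimmed from each tail of M.
#' @param trim_a fraction trimmed from each tail of A.
#' @return named numeric vector of factors (geometric mean 1) with
#'   attribute `reference` (the reference sample id).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  x <- if (inherits(counts, "counts_table")) counts$counts else
    as.matrix(counts)
  if (ncol(x) < 2) stop("TMM needs at least 2 samples")
  x <- x[rowSums(x > 0) > 0, , drop = FALSE]  # all-zero genes carry no signal
  lib <- colSums(x)
  if (any(lib <= 0))
    stop("sample(s) with no nonzero counts: ",
         paste(colnames(x)[lib <= 0], collapse = ", "))
  uq <- apply(x, 2, function(col) stats::quantile(col, 0.75)) / lib
  d <- abs(uq - mean(uq))
  cand <- colnames(x)[d == min(d)]
  ref_id <- sort(cand)[1]
  ref <- x[, ref_id]
  f <- vapply(colnames(x), function(s) {
    fs <- tmm_pair_factor(x[, s], ref, lib[[s]], lib[[ref_id]],
                          trim_m, trim_a)
    if (is.na(fs))
      stop("sample '", s, "' shares no co-nonzero genes with the reference")
    fs
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  attr(f, "reference") <- ref_id
  f
}

#' Counts per million with TMM-scaled library sizes
#'
#' `cpm[g, s] = count[g, s] / (library_size[s] * factor[s]) * 1e6`.
#'
#' @param counts a [counts_table()] or matrix.
#' @param factors named factors from [tmm_factors()]; defaults to 1 for
#'   every sample when `NULL`.
#' @return gene x sample numeric matrix.
#' @export
cpm <- function(counts, factors = NULL) {
  x <- if (inherits(counts, "counts_table")) counts$counts else
    as.matrix(counts)
  if (is.null(factors))
    factors <- stats::setNames(rep(1, ncol(x)), colnames(x))
  miss <- setdiff(colnames(x), names(factors))
  if (length(miss))
    stop("factors missing for sample(s): ", paste(miss, collapse = ", "))
  lib <- colSums(x)
  sweep(x, 2, lib * factors[colnames(x)], "/") * 1e6
}

#' Paired tumor/normal log2 fold changes
#'
#' `fc = log2((tumor + pseudocount) / (normal + pseudocount))`, one
#' column per tumor-normal pair (named by tumor sample). The pseudocount
#' keeps fold changes finite and antisymmetric under pair swap.
#'
#' @param tumor_cpm,normal_cpm gene x sample matrices (may be one matrix
#'   holding both sets of columns).
#' @param pairing named character vector tumor id -> normal id.
#' @param pseudocount added to both numerator and denominator.
#' @return gene x patient matrix of log2 fold changes.
#' @export
paired_log2_fc <- function(tumor_cpm, normal_cpm = tumor_cpm, pairing,
                           pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  miss_t <- setdiff(names(pairing), colnames(tumor_cpm))
  if (length(miss_t))
    stop("tumor sample(s) missing from matrix: ",
         paste(miss_t, collapse = ", "))
  miss_n <- setdiff(unname(pairing), colnames(normal_cpm))
  if (length(miss_n))
    stop("normal sample(s) missing from matrix: ",
         paste(miss_n, collapse = ", "))
  fc <- log2(tumor_cpm[, names(pairing), drop = FALSE] + pseudocount) -
    log2(normal_cpm[, unname(pairing), drop = FALSE] + pseudocount)
  colnames(fc) <- names(pairing)
  fc
}

#' Per-gene z-scores across samples
#'
#' Standardizes every gene row to mean 0, sample SD 1 (n-1 denominator).
#' Zero-variance genes are dropped and listed in the `rejected`
#' attribute rather than producing NaN rows.
#'
#' @param matrix gene x sample numeric matrix with >= 3 samples.
#' @return z-score matrix; attribute `rejected` is a data.frame
#'   (gene, reason) of dropped rows.
#' @export
gene_zscores <- function(matrix) {
  m <- as.matrix(matrix)
  if (ncol(m) < 3) stop("z-scoring needs at least 3 samples")
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  keep <- sd > 0
  z <- (m[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  attr(z, "rejected") <- data.frame(
    gene = rownames(m)[!keep],
    reason = rep("zero variance", sum(!keep)),
    stringsAsFactors = FALSE)
  z
}
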