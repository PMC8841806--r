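#' @title Correlation screening and over-representation analysis
#' @name screen
#' @description Pearson screening of per-gene expression changes against
#'   tumor FDG uptake (log2 TLR by default), sign-splitting of the
#'   significant genes into glucose-like (positive) and lipid-like
#'   (negative) programs, and a generic hypergeometric ORA over
#'   user-supplied GMT collections.
NULL

#' Pearson correlation with a two-sided p-value
#'
#' p is derived from the t transform `t = r * sqrt((n-2)/(1-r^2))` on
#' n-2 degrees of freedom. A perfect correlation yields p = 0 (the
#' floating-point limit of the transform), not a clamped minimum:
#' downstream use is threshold-based only.
#'
#' @param x,y numeric vectors of equal length n >= 3, both non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Screen candidate genes for correlation with tumor FDG uptake
#'
#' Correlates every candidate gene's expression change with the uptake
#' variable and splits significant genes by sign: positive correlations
#' form the glucose-like program, negative the lipid-like program.
#' No multiple-testing correction is applied by default (raw p < alpha);
#' set `adjust = "BH"` to threshold Benjamini-Hochberg q-values instead.
#'
#' @param fc gene x patient matrix (paired log2 fold changes in the
#'   discovery design, or any expression matrix).
#' @param log2_tlr per-patient uptake values aligned with `colnames(fc)`.
#' @param candidates character vector of candidate gene ids.
#' @param alpha significance threshold.
#' @param adjust "none" (default) or "BH".
#' @return list of class `screen_result`: `records` (gene, r, p, n, and
#'   q when adjusted), `positive`, `negative`, `missing` (candidates
#'   absent from `fc`), `skipped` (constant genes), `alpha`.
#' @export
screen_genes <- function(fc, log2_tlr, candidates, alpha = 0.05,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(log2_tlr) != ncol(fc))
    stop("uptake vector length must match the number of patients")
  candidates <- unique(trimws(candidates))
  present <- intersect(candidates, rownames(fc))
  if (!length(present))
    stop("no candidate gene is present in the expression matrix")
  missing <- setdiff(candidates, present)
  skipped <- character(0)
  recs <- vector("list", length(present))
  for (i in seq_along(present)) {
    g <- present[[i]]
    v <- fc[g, ]
    if (stats::sd(v) == 0 || stats::sd(log2_tlr) == 0) {
      skipped <- c(skipped, g)
      next
    }
    recs[[i]] <- c(pearson_with_p(v, log2_tlr), list(gene = g))
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  records <- data.frame(
    gene = vapply(recs, `[[`, character(1), "gene"),
    r = vapply(recs, `[[`, numeric(1), "r"),
    p = vapply(recs, `[[`, numeric(1), "p"),
    n = vapply(recs, `[[`, numeric(1), "n"),
    stringsAsFactors = FALSE)
  crit <- records$p
  if (adjust == "BH") {
    records$q <- stats::p.adjust(records$p, method = "BH")
    crit <- records$q
  }
  sig <- crit < alpha
  structure(list(
    records = records,
    positive = records$gene[sig & records$r > 0],
    negative = records$gene[sig & records$r < 0],
    missing = missing, skipped = skipped, alpha = alpha),
    class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "screen_result: %d genes tested, %d positive / %d negative at alpha=%g (%d missing, %d skipped)\n",
    nrow(x$records), length(x$positive), length(x$negative), x$alpha,
    length(x$missing), length(x$skipped)))
  invisible(x)
}

# Upper-tail hypergeometric p: P(X >= overlap) drawing `draws` from a
# universe of size `universe` containing `successes` members of the set.
hyper_upper_p <- function(overlap, successes, universe, draws) {
  if (draws == 0 || overlap == 0) return(1)
  stats::phyper(overlap - 1, successes, universe - successes, draws,
                lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each collection set for over-representation of the query genes
#' against a stated universe. Sets and the query are intersected with the
#' universe before testing; p-values are BH-adjusted across the
#' collection.
#'
#' @param query character vector of query genes (must intersect the
#'   universe).
#' @param collection GMT collection as from [read_gmt()] (or a named
#'   list of character vectors).
#' @param universe character vector of background genes.
#' @return data.frame with set, overlap, set_size, query_size,
#'   universe_size, p, q; ordered by p.
#' @export
ora_hypergeometric <- function(query, collection, universe) {
  universe <- unique(trimws(universe))
  if (!length(universe)) stop("empty universe")
  query <- intersect(unique(trimws(query)), universe)
  if (!length(query)) stop("query does not intersect the universe")
  rows <- lapply(names(collection), function(nm) {
    s <- collection[[nm]]
    genes <- if (is.character(s)) s else s$genes
    genes <- intersect(genes, universe)
    ov <- length(intersect(genes, query))
    data.frame(set = nm, overlap = ov, set_size = length(genes),
               query_size = length(query),
               universe_size = length(universe),
               p = hyper_upper_p(ov, length(genes), length(universe),
                                 length(query)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
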