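#' Published TCGA-LIHC univariable candidate gene lists
#'
#' The metabolism-associated genes reported to pass the univariable Cox
#' screen (Wald p < 0.1) for disease-free and overall survival in the
#' published TCGA-LIHC validation of the FDG-avidity metabolic
#' signature, in ascending-p order as printed. These lists are bundled
#' as worked-example input for [intersect_candidates()]: their
#' intersection is the seven-gene biomarker set (PFKFB4, ALDOA, EGLN3,
#' EHHADH, GAPDH, HMGCS2, ENO2).
#'
#' @param endpoint "dfs" or "os"; `NULL` returns the full table.
#' @return character vector of gene symbols in rank order, or the full
#'   data.frame when `endpoint` is `NULL`.
#' @export
published_candidate_genes <- function(endpoint = NULL) {
  path <- system.file("extdata", "tcga_lihc_univariable_candidates.tsv",
                      package = "petmetab")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (is.null(endpoint)) return(tab)
  endpoint <- match.arg(tolower(endpoint), c("dfs", "os"))
  sub <- tab[tab$endpoint == endpoint, ]
  sub$gene[order(as.integer(sub$rank))]
}
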