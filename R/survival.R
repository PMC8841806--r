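#' @title Prognostic validation statistics
#' @name survival_stats
#' @description Cox proportional-hazards fitting (Efron ties by default),
#'   univariable screening, candidate intersection, greedy collinearity
#'   exclusion, the prognostic index, risk-group construction,
#'   Kaplan-Meier/log-rank, group t-tests and 2x2 chi-square tests.
NULL

# Validate (time, event) and return a clean data.frame.
as_survival <- function(time, event) {
  if (length(time) != length(event)) stop("time and event lengths differ")
  ok <- is.finite(time) & is.finite(event)
  if (any(time[ok] <= 0)) stop("survival times must be > 0")
  if (!all(event[ok] %in% c(0, 1))) stop("events must be 0/1")
  data.frame(time = time, event = event)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (Efron tie correction by
#' default) over the supplied covariates and reports per-covariate
#' hazard ratios with 95% Wald confidence limits `exp(beta +/- 1.96 SE)`
#' and two-sided Wald p-values.
#'
#' @param covariates sample x covariate numeric matrix (or a single
#'   numeric vector), samples aligned with `time`/`event`.
#' @param time,event survival times (> 0) and 0/1 event indicators.
#' @param ties "efron" (default) or "breslow".
#' @return object of class `cox_fit`: `table` (term, beta, se, hr, lo,
#'   hi, p), `loglik`, `n`, `events`, `ties`.
#' @export
cox_fit <- function(covariates, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.matrix(covariates)
  if (is.null(colnames(x)))
    colnames(x) <- if (ncol(x) == 1) "x" else paste0("x", seq_len(ncol(x)))
  sv <- as_survival(time, event)
  if (sum(sv$event) < 2) stop("need at least 2 observed events")
  const <- colnames(x)[apply(x, 2, function(v) stats::sd(v) == 0)]
  if (length(const))
    stop("constant covariate(s): ", paste(const, collapse = ", "))
  dat <- data.frame(x, check.names = FALSE)
  dat$..time <- sv$time; dat$..event <- sv$event
  fml <- stats::as.formula(paste(
    "survival::Surv(..time, ..event) ~",
    paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
    stop("Cox model did not converge: ", paste(fit$info, collapse = "; "))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(beta)) || any(!is.finite(se)))
    stop("Cox fit produced non-finite estimates (separation or collinearity)")
  tab <- data.frame(
    term = colnames(x), beta = unname(beta), se = unname(se),
    hr = exp(unname(beta)),
    lo = exp(unname(beta) - 1.96 * unname(se)),
    hi = exp(unname(beta) + 1.96 * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
    stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = fit$loglik[length(fit$loglik)],
                 n = fit$n, events = fit$nevent, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("cox_fit (%s ties): n=%d, events=%d\n", x$ties, x$n,
              x$events))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Univariable Cox screen over a gene expression matrix
#'
#' Fits one single-gene Cox model per gene and retains genes with Wald
#' p below `alpha`, ordered by p ascending. Per-gene fit failures
#' (constant genes, separation) are logged and skipped.
#'
#' @param expr gene x sample matrix, samples aligned with survival.
#' @param time,event survival data.
#' @param alpha retention threshold on the Wald p.
#' @param ties passed to [cox_fit()].
#' @return list: `candidates` (data.frame gene, beta, se, hr, lo, hi, p,
#'   ordered by p, retained only), `all` (every gene fitted), `failed`
#'   (gene, reason).
#' @export
univariable_screen <- function(expr, time, event, alpha = 0.1,
                               ties = "efron") {
  genes <- rownames(expr)
  rows <- vector("list", length(genes))
  failed <- list()
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    res <- tryCatch({
      f <- cox_fit(stats::setNames(data.frame(expr[g, ]), g),
                   time, event, ties = ties)
      cbind(gene = g, f$table[, c("beta", "se", "hr", "lo", "hi", "p")])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1]] <- data.frame(
        gene = g, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else rows[[i]] <- res
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop("every per-gene Cox fit failed; first reason: ",
         failed[[1]]$reason)
  all <- do.call(rbind, rows)
  rownames(all) <- NULL
  all <- all[order(all$p), , drop = FALSE]
  list(candidates = all[all$p < alpha, , drop = FALSE], all = all,
       failed = if (length(failed)) do.call(rbind, failed) else
         data.frame(gene = character(0), reason = character(0)))
}

#' Intersect per-endpoint candidate gene lists
#'
#' Genes passing the univariable screen for both endpoints form the
#' biomarker gene set, ordered as in the first (DFS) list — i.e. by the
#' DFS screening p when that list came from [univariable_screen()].
#'
#' @param dfs_candidates,os_candidates character vectors (or screen
#'   outputs; the `candidates$gene` column is used).
#' @return character vector.
#' @export
intersect_candidates <- function(dfs_candidates, os_candidates) {
  pick <- function(x) if (is.list(x) && !is.null(x$candidates))
    x$candidates$gene else as.character(x)
  dfs <- pick(dfs_candidates); os <- pick(os_candidates)
  dfs[dfs %in% os]
}

#' Greedy collinearity exclusion
#'
#' Walks the candidates in the supplied order (ascending univariable p)
#' and excludes any gene whose absolute Pearson correlation with an
#' already-kept gene reaches the cutoff; the exclusion record names the
#' kept partner.
#'
#' @param expr gene x sample matrix containing all candidates.
#' @param candidates ordered character vector.
#' @param r_cutoff absolute-correlation threshold (default 0.8).
#' @return list: `kept` (character), `excluded` (data.frame gene,
#'   partner, r).
#' @export
collinearity_filter <- function(expr, candidates, r_cutoff = 0.8) {
  miss <- setdiff(candidates, rownames(expr))
  if (length(miss))
    stop("candidate(s) absent from expression matrix: ",
         paste(miss, collapse = ", "))
  kept <- character(0)
  excl <- list()
  for (g in candidates) {
    hit <- NULL
    for (k in kept) {
      r <- stats::cor(expr[g, ], expr[k, ])
      if (is.finite(r) && abs(r) >= r_cutoff) { hit <- list(k = k, r = r); break }
    }
    if (is.null(hit)) kept <- c(kept, g)
    else excl[[length(excl) + 1]] <- data.frame(
      gene = g, partner = hit$k, r = hit$r, stringsAsFactors = FALSE)
  }
  list(kept = kept,
       excluded = if (length(excl)) do.call(rbind, excl) else
         data.frame(gene = character(0), partner = character(0),
                    r = numeric(0)))
}

#' Prognostic index (Cox linear predictor)
#'
#' `PI_i = sum_g beta_g * x_{g,i}`, with no baseline term.
#'
#' @param fit a [cox_fit()] whose terms are genes of `expr`.
#' @param expr gene x sample matrix.
#' @return named per-sample numeric vector.
#' @export
prognostic_index <- function(fit, expr) {
  genes <- fit$table$term
  miss <- setdiff(genes, rownames(expr))
  if (length(miss))
    stop("model gene(s) absent from expression matrix: ",
         paste(miss, collapse = ", "))
  drop(crossprod(expr[genes, , drop = FALSE], fit$table$beta))
}

#' Median split of the prognostic index
#'
#' High-risk iff PI at or above the cohort median (ties to high). The
#' threshold is computed within the cohort itself; no external cutoff is
#' assumed.
#'
#' @param pi per-sample prognostic index (>= 2 samples).
#' @return `risk_groups` object (see [stratify_by_cutoff()]) with
#'   rule "PI >= median".
#' @export
median_split <- function(pi) {
  if (length(pi) < 2) stop("need at least 2 samples")
  out <- stratify_by_cutoff(pi, cutoff = stats::median(pi))
  out$rule <- "PI >= median"
  out
}

#' Kaplan-Meier product-limit estimate per group
#'
#' At every distinct observed event time the survival probability drops
#' by the factor (1 - events / at-risk); censored subjects leave the
#' risk set after their censoring time. S(0) = 1.
#'
#' @param time,event survival data.
#' @param groups group label per subject (one level allowed).
#' @return named list of data.frames (time, n_risk, n_event, n_censor,
#'   surv), one per group, rows at distinct observed times.
#' @export
km_estimate <- function(time, event, groups = rep("all", length(time))) {
  sv <- as_survival(time, event)
  out <- list()
  for (g in unique(as.character(groups))) {
    idx <- as.character(groups) == g
    tt <- sv$time[idx]; ee <- sv$event[idx]
    ts <- sort(unique(tt))
    n_risk <- vapply(ts, function(u) sum(tt >= u), numeric(1))
    n_event <- vapply(ts, function(u) sum(tt == u & ee == 1), numeric(1))
    n_cens <- vapply(ts, function(u) sum(tt == u & ee == 0), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    out[[g]] <- data.frame(time = ts, n_risk = n_risk,
                           n_event = n_event, n_censor = n_cens,
                           surv = surv)
  }
  out
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank chi-square on 1 degree of freedom.
#'
#' @param time,event survival data.
#' @param groups two-level group labels.
#' @return list with `chisq`, `p`, `observed`, `expected` per group.
#' @export
logrank_test <- function(time, event, groups) {
  sv <- as_survival(time, event)
  g <- factor(groups)
  if (nlevels(g) != 2) stop("log-rank test needs exactly two groups")
  if (sum(sv$event) < 1) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(sv$time, sv$event) ~ g)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = stats::setNames(sd$obs, levels(g)),
       expected = stats::setNames(sd$exp, levels(g)))
}

#' Independent two-group t-test
#'
#' Welch (unequal-variance) by default; set `welch = FALSE` for the
#' pooled-variance test.
#'
#' @param values numeric vector.
#' @param groups two-level labels; each group needs >= 2 values.
#' @param welch use the Welch correction.
#' @return list with `t`, `df`, `p`, `means` (named per group).
#' @export
ttest_by_group <- function(values, groups, welch = TRUE) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("t-test needs exactly two groups")
  ns <- table(g)
  if (any(ns < 2)) stop("each group needs at least 2 values")
  if (all(vapply(split(values, g), stats::sd, numeric(1)) == 0) &&
      diff(vapply(split(values, g), mean, numeric(1))) == 0)
    return(list(t = 0, df = sum(ns) - 2, p = 1,
                means = vapply(split(values, g), mean, numeric(1))))
  ht <- stats::t.test(values ~ g, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, means = vapply(split(values, g), mean, numeric(1)))
}

#' Chi-square test on a 2x2 contingency table
#'
#' Yates continuity correction is applied by default.
#'
#' @param table 2x2 count matrix with all row/column margins > 0.
#' @param yates apply the continuity correction.
#' @return list with `chisq`, `p`, `yates`.
#' @export
chisq_2x2 <- function(table, yates = TRUE) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("need a 2x2 table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all margins of the 2x2 table must be > 0")
  ht <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(chisq = unname(ht$statistic), p = ht$p.value, yates = yates)
}
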