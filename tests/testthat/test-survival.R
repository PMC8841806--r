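test_that("cox_fit invariants: HR = exp(beta), CI from 1.96 SE, Wald p", {
  set.seed(41)
  d <- sim_surv_cov(120, beta = 0.5)
  fit <- cox_fit(d$x, d$time, d$event)
  tab <- fit$table
  expect_equal(tab$hr, exp(tab$beta))
  expect_equal(tab$lo, exp(tab$beta - 1.96 * tab$se))
  expect_equal(tab$hi, exp(tab$beta + 1.96 * tab$se))
  expect_equal(tab$p, 2 * pnorm(-abs(tab$beta / tab$se)))
  expect_identical(fit$ties, "efron")
})

test_that("cox_fit matches brute-force partial-likelihood maximization", {
  # 6-subject toy, single binary covariate, no ties
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 1, 0)
  x <- c(1, 0, 1, 1, 0, 0)
  fit <- cox_fit(x, time, event)
  brute <- optimize(function(b) cox_loglik_1d(b, time, event, x),
                    interval = c(-5, 5), maximum = TRUE,
                    tol = 1e-10)$maximum
  expect_equal(fit$table$beta, brute, tolerance = 1e-6)
})

test_that("cox_fit beta is invariant under duplicating every subject", {
  # duplication introduces ties, so exact proportionality of the partial
  # likelihood holds under the Breslow tie convention
  set.seed(42)
  d <- sim_surv_cov(60, beta = 0.4)
  f1 <- cox_fit(d$x, d$time, d$event, ties = "breslow")
  f2 <- cox_fit(rep(d$x, 2), rep(d$time, 2), rep(d$event, 2),
                ties = "breslow")
  expect_equal(f2$table$beta, f1$table$beta, tolerance = 1e-6)
})

test_that("cox_fit error paths", {
  set.seed(43)
  d <- sim_surv_cov(30, beta = 0)
  expect_error(cox_fit(rep(1, 30), d$time, d$event), "constant")
  expect_error(cox_fit(d$x, d$time, rep(0, 30)), "2 observed events")
  expect_error(cox_fit(d$x, -d$time, d$event), "> 0")
})

test_that("univariable screen retains a planted prognostic gene and orders by p", {
  planted_hits <- 0
  for (seed in 1:5) {
    set.seed(seed)
    n <- 300
    expr <- matrix(rnorm(51 * n), 51, n,
                   dimnames = list(c("planted", paste0("null", 1:50)),
                                   paste0("s", 1:n)))
    t_ev <- rexp(n, rate = 0.1 * exp(0.5 * expr["planted", ]))
    t_cn <- runif(n, 0, 15)
    scr <- univariable_screen(expr, pmin(t_ev, t_cn),
                              as.integer(t_ev <= t_cn), alpha = 0.1)
    expect_false(is.unsorted(scr$candidates$p))
    if ("planted" %in% scr$candidates$gene) planted_hits <- planted_hits + 1
  }
  expect_gte(planted_hits, 5 * 0.95 - 1)  # >= 95% of replicates, 5 used

  # alpha -> 0 empties the list
  expect_equal(nrow(scr$candidates[scr$candidates$p < 1e-300, ]), 0)
})

test_that("intersect_candidates reproduces ordered intersection semantics", {
  expect_identical(intersect_candidates(c("A", "B", "C"), c("X", "Y")),
                   character(0))
  expect_identical(intersect_candidates(c("A", "B"), c("A", "B")),
                   c("A", "B"))
  expect_identical(intersect_candidates(c("C", "A", "B"), c("B", "C")),
                   c("C", "B"))
})

test_that("collinearity filter applies the greedy rule", {
  set.seed(44)
  n <- 40
  base <- rnorm(n)
  expr <- rbind(g1 = base + rnorm(n, 0, 0.05),
                g2 = base + rnorm(n, 0, 0.05),   # r ~ 0.99 with g1
                g3 = rnorm(n))
  colnames(expr) <- paste0("s", 1:n)
  res <- collinearity_filter(expr, c("g1", "g2", "g3"), r_cutoff = 0.8)
  expect_identical(res$kept, c("g1", "g3"))
  expect_identical(res$excluded$gene, "g2")
  expect_identical(res$excluded$partner, "g1")

  res2 <- collinearity_filter(expr, c("g1", "g2", "g3"), r_cutoff = 1.01)
  expect_identical(res2$kept, c("g1", "g2", "g3"))

  # random correlated blocks vs brute-force application of the rule
  for (seed in 1:5) {
    set.seed(seed)
    b1 <- rnorm(n); b2 <- rnorm(n)
    em <- rbind(a1 = b1 + rnorm(n, 0, 0.1), a2 = b1 + rnorm(n, 0, 0.1),
                a3 = b2 + rnorm(n, 0, 0.1), a4 = b2 + rnorm(n, 0, 0.1),
                a5 = rnorm(n))
    colnames(em) <- paste0("s", 1:n)
    ord <- sample(rownames(em))
    got <- collinearity_filter(em, ord, 0.8)
    kept <- character(0)
    for (g in ord) {
      if (!any(vapply(kept, function(k)
        abs(cor(em[g, ], em[k, ])) >= 0.8, logical(1))))
        kept <- c(kept, g)
    }
    expect_identical(got$kept, kept)
  }
})

test_that("prognostic index is the linear predictor", {
  set.seed(45)
  d <- sim_surv_cov(80, beta = 0.5)
  expr <- rbind(gA = d$x, gB = rnorm(80), gC = rnorm(80))
  colnames(expr) <- paste0("s", 1:80)
  fit <- cox_fit(t(expr), d$time, d$event)
  pi <- prognostic_index(fit, expr)
  expect_equal(unname(pi),
               unname(colSums(expr * fit$table$beta)))
  # single gene with beta = 1 returns the expression row
  fit1 <- fit; fit1$table <- data.frame(term = "gA", beta = 1)
  expect_equal(unname(prognostic_index(fit1, expr)), unname(expr["gA", ]))
  fit0 <- fit; fit0$table$beta <- 0
  expect_equal(unname(prognostic_index(fit0, expr)), rep(0, 80))
  expect_error(prognostic_index(fit, expr[-1, ]), "gA")
})

test_that("median_split mirrors the >=-median tie rule", {
  rg <- median_split(c(a = 1, b = 2, c = 3))
  expect_identical(unname(rg$labels), c("low", "high", "high"))
  expect_true(all(median_split(rep(1, 5))$labels == "high"))
  set.seed(46)
  v <- rnorm(31)
  expect_identical(unname(median_split(v)$labels),
                   ifelse(v >= median(v), "high", "low"))
})

test_that("KM estimator: no-event saturation, hand example, oracle match", {
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))$all
  expect_true(all(km0$surv == 1))

  # 5 subjects, events at 1 and 3, censor at 2
  km <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 0))$all
  expect_equal(km$surv[km$time == 1], 4 / 5)
  expect_equal(km$surv[km$time == 3], 8 / 15)

  set.seed(47)
  for (i in 1:5) {
    n <- 40
    time <- round(rexp(n, 0.2), 2)
    event <- rbinom(n, 1, 0.7)
    got <- km_estimate(time, event)$all
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    expect_equal(got$surv, summary(sf, times = got$time)$surv,
                 tolerance = 1e-12)
    expect_true(all(diff(got$surv) <= 0))
    # with no censoring S equals the empirical survival function
    gotnc <- km_estimate(time, rep(1, n))$all
    expect_equal(gotnc$surv,
                 vapply(gotnc$time, function(u) mean(time > u),
                        numeric(1)))
  }
})

test_that("log-rank test equals the O-E/V closed form and detects separation", {
  # 10-subject toy
  time <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  grp <- rep(c("a", "b"), 5)
  got <- logrank_test(time, event, grp)
  expect_equal(got$chisq, brute_logrank(time, event, grp),
               tolerance = 1e-10)
  expect_equal(got$p, pchisq(got$chisq, 1, lower.tail = FALSE))

  # strongly separated hazards: p < 0.001 in >= 95% of replicates
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    g <- rep(c("hi", "lo"), each = n / 2)
    rate <- ifelse(g == "hi", 0.3, 0.1)
    t_ev <- rexp(n, rate)
    t_cn <- runif(n, 0, 15)
    lr <- logrank_test(pmin(t_ev, t_cn), as.integer(t_ev <= t_cn), g)
    if (lr$p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 9)
  expect_error(logrank_test(time, event, rep("a", 10)), "two groups")
})

test_that("t-test wrapper: identical groups, power, Welch hand formula", {
  v <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("a", "b"), each = 4)
  res <- ttest_by_group(v, g)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # textbook Welch on a 4+4 toy
  x1 <- c(1, 2, 3, 5); x2 <- c(2, 4, 6, 9)
  res2 <- ttest_by_group(c(x1, x2), g)
  se <- sqrt(var(x1) / 4 + var(x2) / 4)
  t_hand <- (mean(x1) - mean(x2)) / se
  df_hand <- se^4 / ((var(x1) / 4)^2 / 3 + (var(x2) / 4)^2 / 3)
  expect_equal(res2$t, t_hand)
  expect_equal(res2$df, df_hand)
  expect_equal(res2$p, 2 * pt(-abs(t_hand), df_hand))

  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    r <- ttest_by_group(c(rnorm(50, 0), rnorm(50, 1)),
                        rep(c("a", "b"), each = 50))
    if (r$p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 9)
  expect_error(ttest_by_group(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("2x2 chi-square: independence, closed form, Fisher direction", {
  res <- chisq_2x2(matrix(10, 2, 2))
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)

  # n(ad-bc)^2 / (r1 r2 c1 c2) without Yates
  m <- matrix(c(30, 10, 10, 30), 2, 2)
  res2 <- chisq_2x2(m, yates = FALSE)
  expect_equal(res2$chisq, 80 * (30 * 30 - 10 * 10)^2 / (40 * 40 * 40 * 40))
  expect_equal(res2$chisq, 20)

  # Yates p is conservative relative to the uncorrected test and close
  # to Fisher on small tables
  set.seed(48)
  for (i in 1:5) {
    tt <- matrix(rpois(4, 8) + 1, 2, 2)
    py <- chisq_2x2(tt, yates = TRUE)$p
    pn <- chisq_2x2(tt, yates = FALSE)$p
    pf <- fisher.test(tt)$p.value
    expect_gte(py, pn)
    expect_lt(abs(py - pf), 0.15)
  }
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "margins")
})
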