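# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written straight-line, sharing no code with
# the package implementations they check.

# Small random count matrix with gene/sample names.
rand_counts <- function(ng = 50, ns = 10, seed = 1, lambda = 100) {
  set.seed(seed)
  m <- matrix(rpois(ng * ns, lambda), ng, ns,
              dimnames = list(sprintf("g%03d", seq_len(ng)),
                              sprintf("s%02d", seq_len(ns))))
  m
}

# NB-simulated counts with depth and composition variation (for TMM).
rand_nb_counts <- function(ng = 200, ns = 4, seed = 1) {
  set.seed(seed)
  mu <- rlnorm(ng, log(100), 1)
  depth <- exp(rnorm(ns, 0, 0.4))
  m <- sapply(depth, function(d) rnbinom(ng, mu = mu * d, size = 10))
  dimnames(m) <- list(sprintf("g%03d", seq_len(ng)),
                      sprintf("s%02d", seq_len(ns)))
  m
}

# Default fixture cohort (computed once per test run).
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(
      simulation_params(seed = 20260911))
    cache
  }
})

# Run discovery: TMM -> CPM -> paired FC -> z-scores, returning pieces.
discovery_matrices <- function(cohort) {
  f <- tmm_factors(cohort$counts)
  m <- cpm(cohort$counts, f)
  fc <- paired_log2_fc(m, m, cohort$counts$pairing)
  list(factors = f, cpm = m, fc = fc, z = gene_zscores(fc),
       log2_tlr = log2(cohort$clinical$tlr))
}

# --- independent oracles -------------------------------------------------

# Exhaustive hypergeometric upper-tail p over all draws (|U| <= 12).
enum_hyper_p <- function(universe, set, query_size, min_overlap) {
  draws <- combn(universe, query_size, simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, set)) >= min_overlap,
              logical(1)))
}

# Hand-written Cox partial log-likelihood, no ties, single covariate.
cox_loglik_1d <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# Brute-force product-limit estimator.
brute_km <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  out <- numeric(0)
  for (u in ts) {
    n <- sum(time >= u)
    d <- sum(time == u & event == 1)
    s <- s * (1 - d / n)
    out <- c(out, s)
  }
  data.frame(time = ts, surv = out)
}

# Two-group log-rank statistic from the O-E/V closed form.
brute_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1
  o <- 0; e <- 0; v <- 0
  for (u in sort(unique(time[event == 1]))) {
    at <- time >= u
    n <- sum(at); n1 <- sum(at & g)
    d <- sum(time == u & event == 1)
    d1 <- sum(time == u & event == 1 & g)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# Simulated survival with a single normal covariate and known log-HR.
sim_surv_cov <- function(n, beta, h0 = 0.1, cens = 15) {
  x <- rnorm(n)
  t_ev <- rexp(n, rate = h0 * exp(beta * x))
  t_cn <- runif(n, 0, cens)
  list(x = x, time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn))
}
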