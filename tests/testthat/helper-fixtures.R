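# Small fixtures and independent oracles shared across test files.

tiny_counts <- function() {
  m <- matrix(c(5L, 0L, 2L,
                1L, 3L, 4L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("tA", "tB", "tC")))
  taxa_counts(m)
}

random_counts <- function(n = 20, g = 8, depth = 500, seed = 1) {
  withr::with_seed(seed, {
    m <- t(stats::rmultinom(n, size = depth, prob = runif(g) + 0.1))
    dimnames(m) <- list(sprintf("s%02d", seq_len(n)), sprintf("t%02d", seq_len(g)))
    taxa_counts(m)
  })
}

# All count vectors of length s summing to n (exhaustive lattice).
outcome_lattice <- function(n, s) {
  if (s == 1) return(matrix(n, ncol = 1))
  out <- NULL
  for (x1 in 0:n) {
    rest <- outcome_lattice(n - x1, s - 1)
    out <- rbind(out, cbind(x1, rest))
  }
  unname(out)
}

# Brute-force BH step-up q-values straight from the definition.
bh_brute <- function(p) {
  ok <- which(!is.na(p))
  m <- length(ok)
  q <- rep(NA_real_, length(p))
  ord <- ok[order(p[ok])]
  for (i in seq_len(m)) {
    js <- i:m
    q[ord[i]] <- min(pmin(p[ord[js]] * m / js, 1))
  }
  q
}

# Pearson chi-squared statistic straight from sum((O-E)^2 / E).
chisq_brute <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Cox partial log-likelihood for a single binary covariate, no ties.
cox_partial_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
    }
  }
  ll
}

# A two-cluster truth object for survival simulations.
two_cluster_truth <- function(n) {
  list(labels = rep(1:2, length.out = n), mixing_weights = c(0.5, 0.5))
}
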