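test_that("dm_log_pmf matches closed forms on degenerate and tiny cases", {
  # single taxon: the multinomial outcome is certain
  expect_equal(dm_log_pmf(7, 3.2), 0)
  expect_equal(dm_log_pmf(0, 0.4), 0)
  # Dirichlet(1,1) makes the 3 outcomes of n=2 equiprobable
  expect_equal(dm_log_pmf(c(1, 1), c(1, 1)), log(1 / 3))
  expect_equal(dm_log_pmf(c(2, 0), c(1, 1)), log(1 / 3))
  expect_error(dm_log_pmf(c(1, 1), c(1, 1, 1)), "length")
  expect_error(dm_log_pmf(c(1, 1), c(1, -1)), "positive")
  expect_error(dm_log_pmf(c(1.5, 1), c(1, 1)), "integer")
})

test_that("dm_log_pmf normalises over the exhaustive outcome lattice", {
  for (alpha in list(c(0.5, 2.0, 1.0), c(1, 1, 1), c(3, 0.2, 0.7))) {
    for (n in c(2, 4, 6)) {
      lattice <- outcome_lattice(n, 3)
      total <- sum(exp(apply(lattice, 1, dm_log_pmf, alpha = alpha)))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
})

test_that("dm_log_pmf agrees with a Monte-Carlo compound-sampling oracle", {
  x <- c(3, 1, 2)
  alpha <- c(0.5, 2.0, 1.0)
  est <- withr::with_seed(101, {
    B <- 2e5
    gm <- matrix(stats::rgamma(3 * B, shape = alpha), ncol = 3, byrow = TRUE)
    p <- gm / rowSums(gm)
    lw <- lgamma(sum(x) + 1) - sum(lgamma(x + 1)) + as.vector(log(p) %*% x)
    w <- exp(lw)
    c(mean = mean(w), se = stats::sd(w) / sqrt(B))
  })
  expect_lt(abs(exp(dm_log_pmf(x, alpha)) - est[["mean"]]), 3 * est[["se"]])
})

test_that("the K=1 fit equals the single-component DM maximum likelihood", {
  spec <- cohort_spec(n_samples = 80, n_genera = 6, K_true = 1,
                      alpha_matrix = matrix(c(2, 1, 0.5, 1.5, 3, 0.8), 1,
                                            dimnames = list(NULL, paste0("g", 1:6))),
                      mixing_weights = 1, depth_log_mean = log(500), seed = 5)
  gen <- generate_counts(spec)
  fit <- fit_dmm(gen$counts, K = 1, seed = 1, n_starts = 1)
  expect_equal(fit$pi, 1)
  X <- count_matrix(gen$counts)
  n <- rowSums(X)
  # independent route: Minka-style fixed-point iteration for the DM MLE
  a <- colMeans(X / n) * 10
  for (it in 1:2000) {
    A <- sum(a)
    num <- colSums(digamma(sweep(X, 2, a, "+"))) - nrow(X) * digamma(a)
    den <- sum(digamma(n + A)) - nrow(X) * digamma(A)
    a_new <- a * num / den
    if (max(abs(a_new - a) / a) < 1e-10) { a <- a_new; break }
    a <- a_new
  }
  ll_fp <- sum(apply(X, 1, dm_log_pmf, alpha = a))
  expect_equal(fit$log_likelihood, ll_fp, tolerance = 1e-7)
  expect_equal(unname(fit$alpha[1, ]), unname(a), tolerance = 1e-3)
})

test_that("EM recovers a well-separated two-component mixture", {
  alpha2 <- alpha_preset_3(30)[1:2, ]
  spec <- cohort_spec(n_samples = 400, alpha_matrix = alpha2,
                      mixing_weights = c(0.6, 0.4),
                      depth_log_mean = log(3000), seed = 21)
  gen <- generate_counts(spec)
  fit <- fit_dmm(gen$counts, K = 2, seed = 1, n_starts = 2)
  lab <- assign_clusters(fit, gen$counts)$cluster
  expect_gte(mclust::adjustedRandIndex(lab, gen$truth$labels), 0.9)
  expect_lte(max(abs(sort(fit$pi) - sort(spec$mixing_weights))), 0.05)
  # EM monotonicity: the observed-data log-likelihood never decreases
  expect_true(all(diff(fit$ll_trace) > -1e-6 * abs(fit$log_likelihood)))
})

test_that("different seeds reach the same optimum on separated data", {
  alpha2 <- alpha_preset_3(20)[c(1, 3), ]
  spec <- cohort_spec(n_samples = 200, alpha_matrix = alpha2,
                      mixing_weights = c(0.5, 0.5),
                      depth_log_mean = log(2000), seed = 8)
  gen <- generate_counts(spec)
  f1 <- fit_dmm(gen$counts, K = 2, seed = 11, n_starts = 2, tol = 1e-9)
  f2 <- fit_dmm(gen$counts, K = 2, seed = 202, n_starts = 2, tol = 1e-9)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-8)
  l1 <- assign_clusters(f1, gen$counts)$cluster
  l2 <- assign_clusters(f2, gen$counts)$cluster
  expect_equal(mclust::adjustedRandIndex(l1, l2), 1)
})

test_that("identical spec and seed give identical fits", {
  spec <- cohort_spec(n_samples = 120, n_genera = 15, seed = 3,
                      depth_log_mean = log(800))
  gen <- generate_counts(spec)
  f1 <- fit_dmm(gen$counts, K = 3, seed = 7, n_starts = 2)
  f2 <- fit_dmm(gen$counts, K = 3, seed = 7, n_starts = 2)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
})

test_that("duplicating a component always worsens the Laplace score", {
  spec <- cohort_spec(n_samples = 100, n_genera = 12, seed = 13,
                      depth_log_mean = log(1000))
  gen <- generate_counts(spec)
  X <- count_matrix(gen$counts)
  for (seed in 1:3) {
    fit <- fit_dmm(X, K = 2, seed = seed, n_starts = 1)
    base_score <- laplace_evidence(fit, X)
    dup <- fit
    dup$K <- 3L
    dup$alpha <- rbind(fit$alpha, fit$alpha[2, ])
    dup$pi <- c(fit$pi[1], fit$pi[2] / 2, fit$pi[2] / 2)
    dup$responsibilities <- cbind(fit$responsibilities[, 1],
                                  fit$responsibilities[, 2] / 2,
                                  fit$responsibilities[, 2] / 2)
    dup_score <- laplace_evidence(dup, X)
    expect_gt(dup_score, base_score)
  }
})

test_that("Laplace evidence is within a nat of a quadrature oracle", {
  amat <- matrix(c(2, 1, 0.5, 1.5), 1, dimnames = list(NULL, paste0("g", 1:4)))
  spec <- cohort_spec(n_samples = 30, alpha_matrix = amat, mixing_weights = 1,
                      depth_log_mean = log(50), depth_log_sd = 0.2, seed = 31)
  gen <- generate_counts(spec)
  X <- count_matrix(gen$counts)
  n <- rowSums(X)
  fit <- fit_dmm(X, K = 1, seed = 1, n_starts = 1, tol = 1e-9)
  score <- laplace_evidence(fit, X, prior_rate = 0.1)

  # brute-force integration of prod_i DM(x_i | alpha) * prod_j Exp(0.1) over
  # a log-spaced grid centred on the fitted concentrations
  npt <- 30
  grids <- lapply(fit$alpha[1, ], function(a)
    seq(log(a) - 3, log(a) + 3, length.out = npt))
  h <- vapply(grids, function(g) g[2] - g[1], numeric(1))
  # per-dimension additive pieces: sum_i lgamma(x_ij + a) - N lgamma(a)
  Sj <- lapply(1:4, function(j) {
    vapply(exp(grids[[j]]), function(a)
      sum(lgamma(X[, j] + a)) - nrow(X) * lgamma(a) +
        log(0.1) - 0.1 * a + log(a),   # prior density and log-space Jacobian
      numeric(1))
  })
  idx <- as.matrix(expand.grid(i1 = 1:npt, i2 = 1:npt, i3 = 1:npt, i4 = 1:npt))
  add <- Sj[[1]][idx[, 1]] + Sj[[2]][idx[, 2]] + Sj[[3]][idx[, 3]] + Sj[[4]][idx[, 4]]
  Avals <- exp(grids[[1]])[idx[, 1]] + exp(grids[[2]])[idx[, 2]] +
    exp(grids[[3]])[idx[, 3]] + exp(grids[[4]])[idx[, 4]]
  Tterm <- nrow(X) * lgamma(Avals) - vapply(Avals, function(A)
    sum(lgamma(n + A)), numeric(1))
  const <- sum(lgamma(n + 1)) - sum(lgamma(X + 1))
  logint <- add + Tterm + const
  mx <- max(logint)
  log_evidence <- mx + log(sum(exp(logint - mx))) + sum(log(h))
  expect_lt(abs(-score - log_evidence), 1)
})

test_that("posterior assignment is consistent, sharp and tie-stable", {
  spec <- cohort_spec(n_samples = 150, n_genera = 20, seed = 17,
                      depth_log_mean = log(5000))
  gen <- generate_counts(spec)
  fit <- fit_dmm(gen$counts, K = 3, seed = 1, n_starts = 2)
  asg <- assign_clusters(fit, gen$counts)
  expect_equal(asg$cluster, max.col(fit$responsibilities, ties.method = "first"))

  # a sample at a component's expected composition is assigned to it sharply
  m <- fit$alpha / rowSums(fit$alpha)
  probe <- round(m * 1e4)
  storage.mode(probe) <- "integer"
  rownames(probe) <- paste0("probe", 1:3)
  pa <- assign_clusters(fit, probe)
  expect_equal(pa$cluster, 1:3)
  expect_true(all(pa$max_posterior > 0.99))

  # identical components: all posteriors tie, label 1 everywhere
  tie <- fit
  tie$alpha <- rbind(fit$alpha[1, ], fit$alpha[1, ])
  tie$pi <- c(0.5, 0.5)
  tie$K <- 2L
  ta <- assign_clusters(tie, gen$counts)
  expect_true(all(ta$cluster == 1L))

  expect_error(assign_clusters(fit, count_matrix(gen$counts)[, 1:5]), "missing")
})

test_that("fit serialisation round-trips and reassigns identically", {
  spec <- cohort_spec(n_samples = 60, n_genera = 10, seed = 23,
                      depth_log_mean = log(500))
  gen <- generate_counts(spec)
  fit <- fit_dmm(gen$counts, K = 2, seed = 1, n_starts = 1)
  base <- withr::local_tempfile()
  write_dmm_fit(fit, base)
  back <- read_dmm_fit(base)
  expect_equal(back$alpha, fit$alpha, tolerance = 1e-12)
  expect_equal(assign_clusters(back, gen$counts), assign_clusters(fit, gen$counts))
})
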