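make_assoc_data <- function(n = 300, seed = 1, k = 3) {
  withr::with_seed(seed, {
    tibble::tibble(
      sample_id = sprintf("S%03d", seq_len(n)),
      cluster = sample(seq_len(k), n, replace = TRUE,
                       prob = (k:1 + 2) / sum(k:1 + 2)),
      gradient = stats::rnorm(n),
      age = stats::rnorm(n, 50, 10),
      bmi = stats::rnorm(n, 26, 4),
      gender = stats::rbinom(n, 1, 0.7),
      bristol = sample(1:7, n, replace = TRUE))
  })
}

test_that("chi-squared tests match the hand formula", {
  # perfectly balanced table: statistic 0, p 1
  d <- tibble::tibble(f = rep(c("a", "b"), each = 30),
                      cl = rep(rep(1:3, each = 10), 2))
  res <- associate_factor(d, "f", "categorical", "cl")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$test, "chi_squared")

  # 2x2 table [[20,10],[10,20]]: statistic 100/15, df 1
  d2 <- tibble::tibble(f = rep(c(0, 1, 0, 1), c(20, 10, 10, 20)),
                       cl = rep(c(1, 2), each = 30))
  res2 <- associate_factor(d2, "f", "categorical", "cl")
  expect_equal(res2$statistic, 100 / 15, tolerance = 1e-12)
  expect_equal(res2$df, 1L)

  # random tables equal the direct sum((O-E)^2/E)
  withr::with_seed(3, {
    for (r in 1:10) {
      dr <- tibble::tibble(f = sample(letters[1:3], 120, replace = TRUE),
                           cl = sample(1:4, 120, replace = TRUE))
      got <- associate_factor(dr, "f", "categorical", "cl")
      expect_equal(got$statistic, chisq_brute(table(dr$f, dr$cl)), tolerance = 1e-10)
    }
  })
  d$x <- seq_len(nrow(d))
  expect_error(associate_factor(d, "f", "categorical", "cl", covariates = "x"),
               "not supported")
})

test_that("regression LRTs equal two times the log-likelihood gap of refits", {
  d <- make_assoc_data(seed = 11)
  d$y <- withr::with_seed(2, rbinom(nrow(d), 1, plogis(-0.5 + 0.8 * (d$cluster == 2))))
  res <- associate_factor(d, "y", "binary", "cluster", covariates = c("age", "gender"))
  # independent refits
  dd <- d
  dd$cl <- relevel(factor(dd$cluster), ref = names(which.max(table(dd$cluster))))
  full <- glm(y ~ age + gender + cl, binomial(), dd)
  red <- glm(y ~ age + gender, binomial(), dd)
  expect_equal(res$statistic, as.numeric(2 * (logLik(full) - logLik(red))),
               tolerance = 1e-9)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, pchisq(res$statistic, 2, lower.tail = FALSE))

  d$z <- withr::with_seed(3, rnorm(nrow(d), 0.4 * d$gradient))
  resc <- associate_factor(d, "z", "continuous", "gradient")
  fullc <- lm(z ~ gradient, d)
  redc <- lm(z ~ 1, d)
  expect_equal(resc$statistic, as.numeric(2 * (logLik(fullc) - logLik(redc))),
               tolerance = 1e-9)
  expect_equal(resc$df, 1L)
})

test_that("constant factors and constant representations degrade gracefully", {
  d <- make_assoc_data(seed = 21)
  d$flat <- 1
  res <- associate_factor(d, "flat", "binary", "cluster")
  expect_true(is.na(res$p_value))
  expect_match(res$note, "constant")

  d$one <- withr::with_seed(5, rbinom(nrow(d), 1, 0.3))
  d$const_cl <- 1
  res2 <- associate_factor(d, "one", "binary", "const_cl")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
})

test_that("per-cluster summaries report raw means and proportions", {
  d <- tibble::tibble(y = c(1, 1, 0, 0, 1, 0), cl = c(1, 1, 1, 2, 2, 2))
  res <- associate_factor(d, "y", "binary", "cl")
  pcs <- res$per_cluster[[1]]
  expect_equal(pcs$mean[pcs$cluster == 1], 2 / 3)
  expect_equal(pcs$mean[pcs$cluster == 2], 1 / 3)
})

test_that("BH q-values obey the step-up definition", {
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(8, {
    for (r in 1:25) {
      p <- runif(sample(3:40, 1))
      if (r %% 5 == 0) p[sample(length(p), 2)] <- NA
      expect_equal(bh_fdr(p), bh_brute(p))
    }
  })
  # monotone: a larger p never gets a smaller q
  withr::with_seed(9, {
    p <- runif(30)
    q <- bh_fdr(p)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= p))
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("screen_factors partitions significant sets consistently", {
  d <- make_assoc_data(n = 400, seed = 31)
  withr::with_seed(32, {
    d$hit_both <- rbinom(400, 1, plogis(-1 + 1.5 * (d$cluster == 2)))
    d$null1 <- rnorm(400)
    d$null2 <- rbinom(400, 1, 0.2)
    d$nullcat <- sample(letters[1:3], 400, replace = TRUE)
  })
  kinds <- c(hit_both = "binary", null1 = "continuous", null2 = "binary",
             nullcat = "categorical")
  sc <- screen_factors(d, kinds, c(ET = "cluster", CT = "cluster", gradient = "gradient"))
  expect_equal(nrow(sc$results), 3 * length(kinds))
  expect_true(all(sc$results$q_value >= sc$results$p_value, na.rm = TRUE))
  # the ET/CT overlap partition sums to each family total
  et_total <- sc$summary$n_fdr_significant[sc$summary$representation == "ET"]
  ct_total <- sc$summary$n_fdr_significant[sc$summary$representation == "CT"]
  expect_equal(sc$overlap$shared + sc$overlap$et_specific, et_total)
  expect_equal(sc$overlap$shared + sc$overlap$ct_specific, ct_total)
  # identical representations: every significant factor is shared
  expect_equal(sc$overlap$et_specific, 0)
  expect_equal(sc$overlap$ct_specific, 0)
  # the spiked factor is found, within-family BH intact
  et_res <- sc$results[sc$results$representation == "ET", ]
  expect_lte(et_res$q_value[et_res$factor_name == "hit_both"], 0.1)
})

test_that("the confounding scan is vacuous without drugs and skips degenerate ones", {
  d <- make_assoc_data(n = 400, seed = 41)
  withr::with_seed(42, {
    d$dz <- rbinom(400, 1, plogis(-1.5 + 1.2 * (d$cluster == 2)))
  })
  scan0 <- drug_confounding_scan(d, "dz", "cluster", drugs = character())
  expect_false(scan0$confounded)
  expect_equal(length(scan0$confounding_drugs), 0)

  d$flat_drug <- 0
  d$same_as_dz <- d$dz
  scan1 <- drug_confounding_scan(d, "dz", "cluster",
                                 drugs = c("flat_drug", "same_as_dz"))
  expect_false(scan1$confounded)
  expect_match(scan1$drug_tests$note[1], "constant")
  expect_match(scan1$drug_tests$note[2], "identical")
})

test_that("representation comparison returns the AIC minimiser", {
  d <- make_assoc_data(n = 500, seed = 51, k = 5)
  names(d)[names(d) == "cluster"] <- "ct"
  d$et <- pmin(d$ct, 3)
  withr::with_seed(52, d$y <- rnorm(500, 0.8 * d$gradient))
  cmp <- compare_representations(d, "y", "continuous", et = "et", ct = "ct",
                                 gradient = "gradient")
  expect_false(cmp$partial)
  expect_equal(cmp$best, names(which.min(c(ET = cmp$aic_ET, CT = cmp$aic_CT,
                                           gradient = cmp$aic_gradient))))
  # AIC arithmetic cross-check against a direct fit
  dd <- d
  dd$.rep <- as.numeric(dd$gradient)
  direct <- lm(y ~ .rep, dd)
  expect_equal(cmp$aic_gradient, AIC(direct), tolerance = 1e-9)
  expect_equal(cmp$best, "gradient")
})

test_that("subdiagnosis distributions are compared by Pearson chi-squared", {
  # identical distributions across clusters: statistic 0
  sub <- rep(c("K29.3", "K29.7"), each = 20)
  cl <- rep(rep(1:2, each = 10), 2)
  res <- subdiagnosis_test(sub, cl)
  expect_equal(res$statistic, 0)

  withr::with_seed(61, {
    sub2 <- sample(c("E78.0", "E78.2", "E78.5"), 90, replace = TRUE)
    cl2 <- sample(1:3, 90, replace = TRUE)
    got <- subdiagnosis_test(sub2, cl2)
    expect_equal(got$statistic, chisq_brute(table(sub2, cl2)), tolerance = 1e-10)
  })

  one <- subdiagnosis_test(rep("K29.3", 15), rep(1:3, 5))
  expect_true(is.na(one$p_value))
  expect_match(one$note, "two subcodes")

  # pooling collapses rare subcodes
  sub3 <- c(rep("A", 30), rep("B", 30), "C", "D")
  cl3 <- rep(1:2, 31)
  pooled <- subdiagnosis_test(sub3, cl3, pool_below = 5)
  expect_equal(pooled$n_subcodes, 3L)
})
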