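test_that("cohort specs validate their invariants", {
  expect_error(cohort_spec(mixing_weights = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(cohort_spec(mixing_weights = c(0.5, 0.5)), "length")
  amat <- alpha_preset_3(10)
  amat[1, 1] <- -1
  expect_error(cohort_spec(alpha_matrix = amat), "> 0")
  expect_error(cohort_spec(depth_log_mean = Inf), "finite")
  expect_error(generate_counts(list()), "cohort_spec")
})

test_that("the same spec and seed regenerate byte-identical cohorts", {
  spec <- cohort_spec(n_samples = 50, n_genera = 12, seed = 77,
                      depth_log_mean = log(300))
  g1 <- generate_counts(spec)
  g2 <- generate_counts(spec)
  expect_identical(count_matrix(g1$counts), count_matrix(g2$counts))
  expect_identical(g1$truth$labels, g2$truth$labels)

  p1 <- generate_phenotypes(g1$truth, list(effect_spec("f", "binary")), seed = 5)
  p2 <- generate_phenotypes(g1$truth, list(effect_spec("f", "binary")), seed = 5)
  expect_identical(p1$phenotypes, p2$phenotypes)

  sp <- survival_spec("DZ", c(0, 0, 0.5))
  s1 <- generate_survival(g1$truth, sp, seed = 9)
  s2 <- generate_survival(g1$truth, sp, seed = 9)
  expect_identical(s1, s2)
  # and the generator does not disturb the caller's RNG stream
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(generate_counts(spec))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("a symmetric single component gives equal mean abundances", {
  amat <- matrix(1, 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  spec <- cohort_spec(n_samples = 1000, alpha_matrix = amat, mixing_weights = 1,
                      depth_log_mean = log(1e4), depth_log_sd = 0, seed = 3)
  gen <- generate_counts(spec)
  P <- count_matrix(gen$counts) / gen$truth$depth
  for (j in 1:3) {
    se <- stats::sd(P[, j]) / sqrt(nrow(P))
    expect_lt(abs(mean(P[, j]) - 1 / 3), 3 * se)
  }
})

test_that("per-component compositions converge to alpha_k / A_k", {
  alpha2 <- alpha_preset_3(20)[c(1, 2), ]
  spec <- cohort_spec(n_samples = 500, alpha_matrix = alpha2,
                      mixing_weights = c(0.5, 0.5),
                      depth_log_mean = log(5000), seed = 15)
  gen <- generate_counts(spec)
  P <- count_matrix(gen$counts) / gen$truth$depth
  for (k in 1:2) {
    rows <- gen$truth$labels == k
    m_target <- alpha2[k, ] / sum(alpha2[k, ])
    for (j in c(1, 2, 10)) {   # index genera and one background genus
      se <- stats::sd(P[rows, j]) / sqrt(sum(rows))
      expect_lt(abs(mean(P[rows, j]) - m_target[j]), 3 * se + 1e-8)
    }
  }
})

test_that("cluster-specific logistic effects raise the targeted cluster", {
  spec <- cohort_spec(n_samples = 3000, n_genera = 10, seed = 25,
                      depth_log_mean = log(500))
  gen <- generate_counts(spec)
  eff <- effect_spec("dz", "binary", "cluster_specific",
                     beta_cluster = c(0, 0, 2), baseline = -1.5)
  phen <- generate_phenotypes(gen$truth, list(eff), seed = 1)
  prev <- tapply(phen$phenotypes$dz, gen$truth$labels, mean)
  expect_true(prev[3] > prev[1] && prev[3] > prev[2])
})

test_that("covariates follow the declared families and effects error on unknowns", {
  spec <- cohort_spec(n_samples = 800, n_genera = 10, seed = 35,
                      depth_log_mean = log(300))
  gen <- generate_counts(spec)
  phen <- generate_phenotypes(gen$truth, list(), seed = 2)$phenotypes
  expect_true(all(phen$age >= 23 & phen$age <= 89))
  expect_true(all(phen$bristol %in% 1:7))
  expect_true(all(phen$gender %in% 0:1))
  expect_gt(mean(phen$gender), 0.6)   # female-majority cohort

  bad <- effect_spec("f", "continuous", covariate_betas = c(shoe_size = 1))
  expect_error(generate_phenotypes(gen$truth, list(bad), seed = 2), "shoe_size")
})

test_that("ordinal and categorical factors have the declared supports", {
  spec <- cohort_spec(n_samples = 500, n_genera = 10, seed = 45,
                      depth_log_mean = log(300))
  gen <- generate_counts(spec)
  effs <- list(effect_spec("ord", "ordinal", n_levels = 5),
               effect_spec("cat", "categorical", "cluster_specific",
                           beta_cluster = c(2, 0, 0), n_levels = 3))
  phen <- generate_phenotypes(gen$truth, effs, seed = 3)$phenotypes
  expect_true(all(phen$ord %in% 1:5))
  expect_true(all(phen$cat %in% 1:3))
})

test_that("confounding drugs are generated in both causal directions", {
  spec <- cohort_spec(n_samples = 2000, n_genera = 10, seed = 55,
                      depth_log_mean = log(300))
  gen <- generate_counts(spec)
  # indication: disease -> drug
  eff_ind <- effect_spec("dz", "binary", "cluster_specific",
                         beta_cluster = c(1, 0, 0), baseline = -1,
                         drug_confounder = list(atc_code = "A01",
                                                p_use_given_disease = 0.8,
                                                p_use_given_healthy = 0.05,
                                                drug_effect_on_factor = 0))
  ph1 <- generate_phenotypes(gen$truth, list(eff_ind), seed = 4)
  d1 <- ph1$phenotypes
  expect_gt(mean(d1$A01[d1$dz == 1]), mean(d1$A01[d1$dz == 0]))
  # mediation: cluster -> drug -> disease
  eff_med <- effect_spec("dz2", "binary", "cluster_specific",
                         beta_cluster = c(0, 0, 2), baseline = -2,
                         drug_confounder = list(atc_code = "B02",
                                                p_use_given_healthy = 0.1,
                                                drug_effect_on_factor = 2))
  ph2 <- generate_phenotypes(gen$truth, list(eff_med), seed = 5)
  d2 <- ph2$phenotypes
  use_by_cluster <- tapply(d2$B02, gen$truth$labels, mean)
  expect_gt(use_by_cluster[3], use_by_cluster[1])
  expect_gt(mean(d2$dz2[d2$B02 == 1]), mean(d2$dz2[d2$B02 == 0]))
})

test_that("survival generation respects censoring and hazard ordering", {
  truth <- two_cluster_truth(3000)
  sp <- survival_spec("DZ", c(0, 0.8), baseline_rate = 0.1,
                      admin_censor_time = 3.1, censor_jitter = 1)
  inc <- generate_survival(truth, sp, seed = 6)
  expect_true(all(inc$time >= 0 & inc$time <= 4.1))
  ev <- tapply(inc$event, truth$labels, mean)
  expect_gt(ev[2], ev[1])    # higher hazard, more events before censoring
  # administrative censoring at zero: everyone censored at time zero
  sp0 <- survival_spec("DZ", c(0, 0), admin_censor_time = 0, censor_jitter = 0)
  inc0 <- generate_survival(truth, sp0, seed = 6)
  expect_true(all(inc0$event == 0))
  expect_error(generate_survival(truth, survival_spec("X", c(0, 0, 0)), seed = 1),
               "per cluster")
})

test_that("the five-component preset collapses onto the three enterotype roles", {
  a5 <- alpha_preset_5(30)
  expect_equal(nrow(a5), 5)
  expect_true(all(a5 > 0))
  m <- a5 / rowSums(a5)
  # Bacteroides dominance decreasing 1 > 2; Prevotella 5 > 4
  expect_gt(m[1, "Bacteroides"], m[2, "Bacteroides"])
  expect_gt(m[2, "Bacteroides"], m[3, "Bacteroides"])
  expect_gt(m[5, "Prevotella"], m[4, "Prevotella"])
  expect_gt(m[4, "Prevotella"], m[3, "Prevotella"])
})
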