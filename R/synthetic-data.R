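#' Three-component concentration preset
#'
#' A well-separated Dirichlet concentration matrix mimicking the canonical
#' enterotype roles: component 1 Bacteroides-heavy, component 2
#' Prevotella-heavy, component 3 spread over many Firmicutes-like genera
#' (higher diversity). Columns 1..3 are named `Bacteroides`, `Prevotella`,
#' `Clostridium`; the rest `Genus04`, `Genus05`, ...
#'
#' @param n_genera Number of genus columns (>= 5), default 40.
#' @return `K = 3` x `n_genera` positive matrix with genus column names.
#' @export
alpha_preset_3 <- function(n_genera = 40) {
  assert_that(n_genera >= 5, "preset needs at least 5 genera")
  genera <- c("Bacteroides", "Prevotella", "Clostridium",
              sprintf("Genus%02d", seq_len(n_genera - 3) + 3))
  G <- n_genera
  # deterministic mild variation across the background genera
  bg <- 0.25 + 0.5 * (seq_len(G) %% 7) / 7
  a1 <- bg * 0.6; a1[1] <- 30; a1[2] <- 0.2; a1[3] <- 1.0   # Bacteroides-heavy
  a2 <- bg * 0.6; a2[1] <- 0.4; a2[2] <- 28; a2[3] <- 0.8   # Prevotella-heavy
  a3 <- bg * 2.2; a3[1] <- 2.0; a3[2] <- 0.3; a3[3] <- 4.0  # spread/Firmicutes
  alpha <- rbind(a1, a2, a3)
  dimnames(alpha) <- list(NULL, genera)
  alpha
}

#' Five-component concentration preset
#'
#' Extends [alpha_preset_3()] into the 5-cluster community-type layout:
#' components 1/5 are extreme Bacteroides-/Prevotella-dominated, 2/4 their
#' moderate counterparts, and 3 is spread over the background
#' (Firmicutes-like) genera. Collapsing components `c(1, 2) / 3 / c(4, 5)`
#' reproduces the three enterotype roles.
#'
#' @param n_genera Number of genus columns (>= 5), default 40.
#' @return `K = 5` x `n_genera` positive matrix with genus column names.
#' @export
alpha_preset_5 <- function(n_genera = 40) {
  assert_that(n_genera >= 5, "preset needs at least 5 genera")
  base <- alpha_preset_3(n_genera)
  G <- n_genera
  bg <- 0.25 + 0.5 * (seq_len(G) %% 7) / 7
  a1 <- bg * 0.35; a1[1] <- 55; a1[2] <- 0.15; a1[3] <- 0.6   # extreme Bacteroides
  a2 <- bg * 1.0;  a2[1] <- 12; a2[2] <- 0.3;  a2[3] <- 2.0   # moderate Bacteroides
  a3 <- base[3, ]                                             # spread/Firmicutes
  a4 <- bg * 1.0;  a4[1] <- 1.5; a4[2] <- 10;  a4[3] <- 1.5   # moderate Prevotella
  a5 <- bg * 0.35; a5[1] <- 0.3; a5[2] <- 50;  a5[3] <- 0.5   # extreme Prevotella
  alpha <- rbind(a1, a2, a3, a4, a5)
  dimnames(alpha) <- list(NULL, colnames(base))
  alpha
}

#' Specification of a synthetic cohort
#'
#' Bundles everything the count generator needs: the mixture (component
#' concentrations and mixing weights), the sequencing-depth model
#' (log-normal), and where the named index genera sit.
#'
#' @param n_samples Number of samples.
#' @param n_genera Number of genera (ignored when `alpha_matrix` is given).
#' @param K_true Number of mixture components (ignored when `alpha_matrix`
#'   is given).
#' @param mixing_weights Probability vector of length `K_true`; default
#'   `c(0.4, 0.25, 0.35)` for the 3-component preset, else uniform.
#' @param alpha_matrix `K_true` x `n_genera` positive matrix; default
#'   [alpha_preset_3()].
#' @param depth_log_mean,depth_log_sd Parameters of the per-sample
#'   LogNormal depth; defaults `log(1e4)` and 0.3.
#' @param seed Integer seed.
#' @return A `cohort_spec` list (validated).
#' @export
cohort_spec <- function(n_samples = 600, n_genera = 40, K_true = 3,
                        mixing_weights = NULL, alpha_matrix = NULL,
                        depth_log_mean = log(1e4), depth_log_sd = 0.3,
                        seed = 1) {
  if (is.null(alpha_matrix)) {
    assert_that(K_true == 3, "supply alpha_matrix for K_true != 3")
    alpha_matrix <- alpha_preset_3(n_genera)
  }
  K_true <- nrow(alpha_matrix)
  n_genera <- ncol(alpha_matrix)
  if (is.null(mixing_weights)) {
    mixing_weights <- if (K_true == 3) c(0.4, 0.25, 0.35)
                      else rep(1 / K_true, K_true)
  }
  assert_that(length(mixing_weights) == K_true,
              "mixing_weights length must equal the number of components")
  assert_that(abs(sum(mixing_weights) - 1) <= 1e-12,
              "mixing_weights must sum to 1")
  assert_that(all(alpha_matrix > 0), "all concentration entries must be > 0")
  assert_that(is.finite(depth_log_mean) && is.finite(depth_log_sd) && depth_log_sd >= 0,
              "depth parameters must be finite (and sd >= 0)")
  named <- intersect(c("Bacteroides", "Prevotella", "Clostridium"),
                     colnames(alpha_matrix))
  idx <- match(named, colnames(alpha_matrix))
  assert_that(!anyDuplicated(idx), "named genus indices must be distinct")
  structure(list(n_samples = as.integer(n_samples), n_genera = n_genera,
                 K_true = K_true, mixing_weights = mixing_weights,
                 alpha_matrix = alpha_matrix,
                 depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
                 named_genus_indices = setNames(idx, named),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a taxon count table from a DM mixture
#'
#' For each sample: draws a component label from the mixing weights, genus
#' proportions from that component's Dirichlet, a sequencing depth from the
#' log-normal depth model, and counts from the multinomial. The returned
#' truth object carries the labels, the generative parameters, and the log
#' Prevotella/Bacteroides gradient of the realised counts (when both index
#' genera exist), so downstream recovery and association tests have ground
#' truth to compare against. Identical spec + seed gives identical output.
#'
#' @param spec A [cohort_spec()].
#' @return List: `counts` ([taxa_counts]), `truth` (list: `labels`,
#'   `mixing_weights`, `alpha_matrix`, `depth`, `gradient`, `spec`).
#' @export
generate_counts <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  N <- spec$n_samples
  G <- spec$n_genera
  K <- spec$K_true
  out <- with_seed(spec$seed, {
    z <- sample.int(K, N, replace = TRUE, prob = spec$mixing_weights)
    depth <- pmax(1, round(stats::rlnorm(N, spec$depth_log_mean, spec$depth_log_sd)))
    X <- matrix(0L, N, G, dimnames = list(sprintf("S%04d", seq_len(N)),
                                          colnames(spec$alpha_matrix)))
    for (i in seq_len(N)) {
      a <- spec$alpha_matrix[z[i], ]
      p <- stats::rgamma(G, shape = a, rate = 1)
      p <- p / sum(p)
      X[i, ] <- stats::rmultinom(1, size = depth[i], prob = p)[, 1]
    }
    list(X = X, z = z, depth = depth)
  })
  counts <- taxa_counts(out$X)
  gradient <- NULL
  if (all(c("Prevotella", "Bacteroides") %in% colnames(out$X))) {
    gradient <- gradient_score(out$X)$gradient
  }
  truth <- list(labels = out$z, mixing_weights = spec$mixing_weights,
                alpha_matrix = spec$alpha_matrix, depth = out$depth,
                gradient = gradient, spec = spec)
  list(counts = counts, truth = truth)
}

#' Declare one synthetic phenotype factor
#'
#' Describes how a factor depends on the true cluster labels: a
#' cluster-specific effect (`beta_cluster`, log-odds or mean shifts per
#' cluster), a gradient effect (`beta_gradient` on the log
#' Prevotella/Bacteroides score), or no effect at all. Optionally a
#' confounding drug rides along (see Details).
#'
#' @details The `drug_confounder` list has fields `atc_code`,
#'   `p_use_given_disease`, `p_use_given_healthy` and
#'   `drug_effect_on_factor`. With `drug_effect_on_factor = 0` the drug is
#'   drawn conditional on the realised factor (confounding by indication).
#'   With a non-zero value the causal chain is cluster -> drug -> factor:
#'   the drug's usage logit carries `beta_cluster`, the factor depends on
#'   the drug (not directly on the cluster), so the cluster-factor
#'   association is fully mediated and a deconfounding scan should flag it.
#'
#' @param factor_name Column name.
#' @param factor_kind `"binary"`, `"continuous"`, `"categorical"` or
#'   `"ordinal"`.
#' @param effect_mode `"cluster_specific"`, `"gradient"` or `"null"`.
#' @param beta_cluster Per-cluster effect vector (log-odds / mean shifts).
#' @param beta_gradient Coefficient on the gradient score.
#' @param covariate_betas Named vector of effects of `age`, `bmi`, `gender`,
#'   `bristol` on the factor.
#' @param baseline Intercept (logit scale for binary, mean for continuous).
#' @param sd Residual SD for continuous factors, default 1.
#' @param n_levels Number of levels for categorical/ordinal factors.
#' @param drug_confounder Optional list, see Details.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(factor_name, factor_kind, effect_mode = "null",
                        beta_cluster = NULL, beta_gradient = NULL,
                        covariate_betas = NULL, baseline = 0, sd = 1,
                        n_levels = 4, drug_confounder = NULL) {
  factor_kind <- match.arg(factor_kind,
                           c("binary", "continuous", "categorical", "ordinal"))
  effect_mode <- match.arg(effect_mode, c("cluster_specific", "gradient", "null"))
  if (effect_mode == "cluster_specific")
    assert_that(!is.null(beta_cluster), "cluster_specific mode needs beta_cluster")
  if (effect_mode == "gradient")
    assert_that(!is.null(beta_gradient), "gradient mode needs beta_gradient")
  if (!is.null(drug_confounder)) {
    pr <- c(drug_confounder$p_use_given_disease %||% 0.5,
            drug_confounder$p_use_given_healthy %||% 0.05)
    assert_that(all(pr >= 0 & pr <= 1), "drug usage probabilities must be in [0, 1]")
  }
  structure(list(factor_name = factor_name, factor_kind = factor_kind,
                 effect_mode = effect_mode, beta_cluster = beta_cluster,
                 beta_gradient = beta_gradient,
                 covariate_betas = covariate_betas, baseline = baseline,
                 sd = sd, n_levels = n_levels,
                 drug_confounder = drug_confounder),
            class = "effect_spec")
}

default_covariates <- function(N, labels, K) {
  age <- pmin(pmax(stats::rnorm(N, 50, 10), 23), 89)
  gender <- stats::rbinom(N, 1, 0.7)            # 1 = female
  bmi <- stats::rnorm(N, 26, 4)
  # Bristol 1..7, centred at 4, mild cluster shift on the latent scale
  shift <- seq(-0.4, 0.4, length.out = K)[labels]
  bristol <- pmin(pmax(round(stats::rnorm(N, 4 + shift, 1.2)), 1), 7)
  tibble::tibble(age = age, gender = gender, bmi = bmi, bristol = bristol)
}

linear_predictor <- function(eff, truth, covs) {
  N <- length(truth$labels)
  lp <- rep(eff$baseline, N)
  if (eff$effect_mode == "cluster_specific")
    lp <- lp + eff$beta_cluster[truth$labels]
  if (eff$effect_mode == "gradient") {
    assert_that(!is.null(truth$gradient),
                "gradient effect requested but the cohort has no gradient score")
    lp <- lp + eff$beta_gradient * truth$gradient
  }
  if (!is.null(eff$covariate_betas)) {
    unknown <- setdiff(names(eff$covariate_betas), names(covs))
    assert_that(length(unknown) == 0,
                paste0("effect on unknown covariate: ", paste(unknown, collapse = ", ")))
    for (cv in names(eff$covariate_betas)) {
      v <- covs[[cv]]
      lp <- lp + eff$covariate_betas[[cv]] * (v - mean(v))
    }
  }
  lp
}

#' Simulate phenotype, drug and covariate columns for a cohort
#'
#' Draws the default covariates (age, gender, BMI, Bristol score) and then
#' each declared factor from its generative model: binary factors from a
#' logistic model on the cluster / gradient / covariate terms, continuous
#' from the analogous Gaussian model, ordinal from a thresholded latent
#' Gaussian, categorical from a cluster-tilted multinomial. Factors with a
#' `drug_confounder` also emit a 0/1 drug column (named by its ATC code).
#'
#' @param truth Truth object from [generate_counts()].
#' @param effects List of [effect_spec()]s.
#' @param seed Integer seed.
#' @return List: `phenotypes` (tibble `sample_id`, covariates, factors,
#'   drug columns), `kinds` (named vector factor -> kind), `drugs`
#'   (character vector of drug columns), `effects` (the echoed specs).
#' @export
generate_phenotypes <- function(truth, effects, seed = 1) {
  N <- length(truth$labels)
  K <- length(truth$mixing_weights)
  with_seed(seed, {
    covs <- default_covariates(N, truth$labels, K)
    out <- covs
    kinds <- character()
    drugs <- character()
    for (eff in effects) {
      dc <- eff$drug_confounder
      mediated <- !is.null(dc) && (dc$drug_effect_on_factor %||% 0) != 0
      drug <- NULL
      if (mediated) {
        # cluster -> drug: the cluster effect is routed through drug usage
        base_logit <- stats::qlogis(min(max(dc$p_use_given_healthy %||% 0.1, 1e-3), 1 - 1e-3))
        dl <- base_logit + (eff$beta_cluster %||% rep(0, K))[truth$labels]
        drug <- stats::rbinom(N, 1, stats::plogis(dl))
        lp <- rep(eff$baseline, N) + dc$drug_effect_on_factor * drug
        if (!is.null(eff$covariate_betas)) {
          for (cv in names(eff$covariate_betas)) {
            v <- covs[[cv]]
            lp <- lp + eff$covariate_betas[[cv]] * (v - mean(v))
          }
        }
      } else {
        lp <- linear_predictor(eff, truth, covs)
      }
      value <- switch(eff$factor_kind,
        binary = stats::rbinom(N, 1, stats::plogis(lp)),
        continuous = stats::rnorm(N, lp, eff$sd),
        ordinal = {
          latent <- stats::rnorm(N, lp, eff$sd)
          cuts <- stats::quantile(latent, probs = seq_len(eff$n_levels - 1) / eff$n_levels)
          as.integer(findInterval(latent, cuts) + 1L)
        },
        categorical = {
          L <- eff$n_levels
          base <- rep(1 / L, L)
          vapply(seq_len(N), function(i) {
            tilt <- rep(0, L)
            if (eff$effect_mode == "cluster_specific") {
              lev <- ((truth$labels[i] - 1) %% L) + 1
              tilt[lev] <- eff$beta_cluster[truth$labels[i]]
            }
            pr <- base * exp(tilt)
            sample.int(L, 1, prob = pr / sum(pr))
          }, integer(1))
        })
      out[[eff$factor_name]] <- value
      kinds[[eff$factor_name]] <- eff$factor_kind
      if (!is.null(dc)) {
        if (!mediated) {
          # factor -> drug (confounding by indication); needs a binary factor
          p_use <- ifelse(as.numeric(value) == 1,
                          dc$p_use_given_disease %||% 0.5,
                          dc$p_use_given_healthy %||% 0.05)
          drug <- stats::rbinom(N, 1, p_use)
        }
        out[[dc$atc_code]] <- drug
        drugs <- c(drugs, dc$atc_code)
      }
    }
    phen <- dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("S%04d", seq_len(N))), out)
    list(phenotypes = phen, kinds = kinds, drugs = drugs, effects = effects)
  })
}

#' Declare a synthetic incident-disease hazard model
#'
#' @param disease_id Disease code for the incident table.
#' @param log_hazard_ratios Per-cluster log hazard ratios (reference cluster
#'   has 0; give one value per cluster).
#' @param baseline_rate Weibull rate parameter (> 0), default 0.05 / year.
#' @param weibull_shape Shape (> 0), 1 = exponential.
#' @param admin_censor_time Administrative censoring horizon in years,
#'   default 3.1.
#' @param censor_jitter Half-width of the uniform entry jitter applied to
#'   the censoring time (years), default 1 — censoring times are drawn
#'   uniformly on `admin_censor_time` +/- `censor_jitter`, floored at 0.
#' @param covariate_log_hrs Named vector of covariate log hazard ratios.
#' @return A `survival_spec` list.
#' @export
survival_spec <- function(disease_id, log_hazard_ratios, baseline_rate = 0.05,
                          weibull_shape = 1, admin_censor_time = 3.1,
                          censor_jitter = 1, covariate_log_hrs = NULL) {
  assert_that(baseline_rate > 0, "baseline_rate must be > 0")
  assert_that(weibull_shape > 0, "weibull_shape must be > 0")
  assert_that(admin_censor_time >= 0, "admin_censor_time must be >= 0")
  structure(list(disease_id = disease_id,
                 log_hazard_ratios = log_hazard_ratios,
                 baseline_rate = baseline_rate, weibull_shape = weibull_shape,
                 admin_censor_time = admin_censor_time,
                 censor_jitter = censor_jitter,
                 covariate_log_hrs = covariate_log_hrs),
            class = "survival_spec")
}

#' Simulate incident-disease follow-up for a cohort
#'
#' Event times are Weibull with per-sample log hazard equal to the cluster
#' term plus centred covariate terms; observed time is the minimum of the
#' event time and the (jittered) administrative censoring time.
#'
#' @param truth Truth object from [generate_counts()].
#' @param spec A [survival_spec()].
#' @param covariates Optional tibble of covariates aligned with the samples
#'   (used when `covariate_log_hrs` is set).
#' @param seed Integer seed.
#' @return Tibble: `sample_id`, `disease_id`, `time`, `event`. All-censored
#'   output is allowed but signalled with a message.
#' @export
generate_survival <- function(truth, spec, covariates = NULL, seed = 1) {
  assert_that(inherits(spec, "survival_spec"), "spec must be a survival_spec")
  N <- length(truth$labels)
  K <- length(truth$mixing_weights)
  assert_that(length(spec$log_hazard_ratios) == K,
              "log_hazard_ratios must have one value per cluster")
  with_seed(seed, {
    lh <- spec$log_hazard_ratios[truth$labels]
    if (!is.null(spec$covariate_log_hrs)) {
      assert_that(!is.null(covariates), "covariate_log_hrs set but no covariates given")
      for (cv in names(spec$covariate_log_hrs)) {
        v <- covariates[[cv]]
        assert_that(!is.null(v), paste0("covariate not found: ", cv))
        lh <- lh + spec$covariate_log_hrs[[cv]] * (v - mean(v))
      }
    }
    # S(t) = exp(-rate * t^shape * e^lh)  =>  T = (E / (rate * e^lh))^(1/shape)
    e <- stats::rexp(N)
    t_event <- (e / (spec$baseline_rate * exp(lh)))^(1 / spec$weibull_shape)
    cens <- pmax(0, stats::runif(N, spec$admin_censor_time - spec$censor_jitter,
                                 spec$admin_censor_time + spec$censor_jitter))
    if (spec$admin_censor_time == 0) cens <- rep(0, N)
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens & cens > 0)
    if (all(event == 0)) inform(paste0("all follow-up censored for ", spec$disease_id))
    tibble::tibble(sample_id = sprintf("S%04d", seq_len(N)),
                   disease_id = spec$disease_id, time = time, event = event)
  })
}
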