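#' Build the bundled demo cohort
#'
#' Generates a complete synthetic cohort with known ground truth exercising
#' every analysis stage: a 3-component mixture of genus counts
#' (Bacteroides-, Prevotella- and Firmicutes-like components), phenotypic
#' factors with cluster-specific, gradient and null effects, one disease
#' whose cluster association is fully mediated by a drug (so the
#' deconfounding scan has something to find) and one with a direct cluster
#' effect, plus an incident-disease panel in which one disease has a
#' genuine per-cluster hazard difference.
#'
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @param n_samples Cohort size, default 1000.
#' @param n_genera Number of genera, default 50.
#' @return List: `counts`, `truth`, `phenotypes`, `kinds`, `drugs`,
#'   `diseases`, `prevalent`, `incident`, `effects`, `survival_specs`.
#' @export
make_demo <- function(seed = 1, n_samples = 1000, n_genera = 50) {
  spec <- cohort_spec(n_samples = n_samples, n_genera = n_genera,
                      K_true = 3, seed = seed)
  gen <- generate_counts(spec)

  effects <- list(
    # community-type-specific disease enrichment (type-2-diabetes-like)
    effect_spec("E11", "binary", "cluster_specific",
                beta_cluster = c(1.4, 0, 0), baseline = -2.2,
                covariate_betas = c(age = 0.03, bmi = 0.08)),
    # disease whose cluster signal is fully mediated by a drug; the chain is
    # strong so the marginal cluster association is clearly detectable
    effect_spec("F41", "binary", "cluster_specific",
                beta_cluster = c(0, 0, 2.5), baseline = -2.2,
                drug_confounder = list(atc_code = "N05B",
                                       p_use_given_healthy = 0.05,
                                       drug_effect_on_factor = 2.2)),
    # disease with a direct cluster effect and an indication drug
    effect_spec("M10", "binary", "cluster_specific",
                beta_cluster = c(1.2, 0, 0), baseline = -2.8,
                covariate_betas = c(gender = -0.5),
                drug_confounder = list(atc_code = "M04A",
                                       p_use_given_disease = 0.6,
                                       p_use_given_healthy = 0.02,
                                       drug_effect_on_factor = 0)),
    # gradient-shaped exposure (antibiotic-courses-like)
    effect_spec("abx_courses", "continuous", "gradient",
                beta_gradient = 0.5, baseline = 2, sd = 1),
    # null factors of each kind
    effect_spec("diet_fruit", "ordinal", "null", n_levels = 5),
    effect_spec("water_source", "categorical", "null", n_levels = 3),
    effect_spec("smoker", "binary", "null", baseline = -1),
    effect_spec("whr", "continuous", "null", baseline = 0.9, sd = 0.08))

  phen <- generate_phenotypes(gen$truth, effects, seed = seed + 1L)

  # prevalent records: carriers of the binary diseases
  diseases <- c("E11", "F41", "M10")
  prevalent <- purrr::map_dfr(diseases, function(dz) {
    tibble::tibble(sample_id = phen$phenotypes$sample_id[phen$phenotypes[[dz]] == 1],
                   icd10 = dz)
  })

  surv_specs <- list(
    survival_spec("G43", log_hazard_ratios = c(0, 0, -0.7),
                  baseline_rate = 0.06),
    survival_spec("J45", log_hazard_ratios = c(0, 0, 0),
                  baseline_rate = 0.05),
    survival_spec("I10", log_hazard_ratios = c(0, 0, 0),
                  baseline_rate = 0.04))
  incident <- purrr::map_dfr(seq_along(surv_specs), function(i) {
    generate_survival(gen$truth, surv_specs[[i]],
                      covariates = phen$phenotypes, seed = seed + 10L + i)
  })
  # a few prevalent carriers of the incident diseases, to exercise exclusion
  prev_inc <- with_seed(seed + 99L, {
    purrr::map_dfr(surv_specs, function(sp) {
      carriers <- which(stats::rbinom(n_samples, 1, 0.04) == 1)
      tibble::tibble(sample_id = phen$phenotypes$sample_id[carriers],
                     icd10 = sp$disease_id)
    })
  })
  prevalent <- dplyr::bind_rows(prevalent, prev_inc)

  list(counts = gen$counts, truth = gen$truth,
       phenotypes = phen$phenotypes, kinds = phen$kinds, drugs = phen$drugs,
       diseases = diseases, prevalent = prevalent, incident = incident,
       effects = effects, survival_specs = surv_specs, seed = seed)
}

flatten_results <- function(res) {
  res$per_cluster <- NULL
  res
}

#' Run the full community-typing analysis
#'
#' Orchestrates the pipeline end to end: optional preprocessing (low-depth
#' removal, prevalence/abundance filter, genus aggregation), the model-fit
#' curve with K selection, the enterotype (K = 3) and community-type
#' (selected K) models, correspondence and driving-genera tables, diversity
#' descriptors, the unadjusted factor screen with FDR control, AIC
#' representation comparison, adjusted disease tests with the
#' drug-confounding scan, and the incident-disease Cox screen. Every
#' artifact is written as TSV/YAML under `out_dir` together with a JSON run
#' manifest; the run is deterministic given the config.
#'
#' @param cohort A cohort list as produced by [make_demo()] (fields
#'   `counts`, `phenotypes`, `kinds`, optionally `drugs`, `diseases`,
#'   `prevalent`, `incident`).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the model fits.
#' @param k_max Largest K on the fit curve, default 5.
#' @param k_enterotype The enterotype K, fixed at 3.
#' @param n_starts EM starts per K, default 2.
#' @param tau Elbow threshold for [select_k()].
#' @param fdr_threshold,nominal,confound_alpha Analysis thresholds.
#' @param pseudocount Pseudocount for the gradient score.
#' @param min_reads Optional low-depth threshold applied before fitting.
#' @param prevalence_frac,rel_abund Optional taxon filter thresholds
#'   (applied when both are non-NULL).
#' @param covariates Covariate columns for the adjusted models.
#' @return Invisible list of all in-memory results (`curve`, `fit_et`,
#'   `fit_ct`, `assignments`, `screen`, `comparison`, `adjusted`,
#'   `confounding`, `survival`, `paths`).
#' @export
run_pipeline <- function(cohort, out_dir, seed = 1, k_max = 5,
                         k_enterotype = 3, n_starts = 2, tau = 0.05,
                         fdr_threshold = 0.1, nominal = 0.05,
                         confound_alpha = 0.05, pseudocount = 0.5,
                         min_reads = NULL, prevalence_frac = NULL,
                         rel_abund = NULL,
                         covariates = c("age", "bmi", "gender", "bristol")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  emit <- function(tbl, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(tbl, p)
    paths[[name]] <<- p
    p
  }

  counts <- cohort$counts
  stage("preprocess", {
    if (!is.null(min_reads)) {
      dropped <- drop_low_depth_samples(counts, min_reads = min_reads)
      counts <- dropped$counts
      emit(dropped$removed, "removed_samples.tsv")
    }
    if (!is.null(prevalence_frac) && !is.null(rel_abund)) {
      counts <- filter_prevalent_taxa(counts, prevalence_frac, rel_abund)
    }
    if (!is.null(taxonomy_of(counts))) {
      counts <- aggregate_to_genus(counts)
    }
    write_count_table(counts, file.path(out_dir, "counts_genus.tsv"))
    paths[["counts_genus.tsv"]] <- file.path(out_dir, "counts_genus.tsv")
  })

  curve <- stage("fit_curve",
                 fit_dmm_curve(counts, k_max = k_max, seed = seed,
                               n_starts = n_starts))
  k_sel <- stage("select_k", select_k(curve, tau = tau))
  emit(curve$curve, "fit_curve.tsv")

  fit_et <- if (k_enterotype <= k_max) curve$fits[[k_enterotype]] else
    stage("fit_enterotype", {
      f <- fit_dmm(counts, K = k_enterotype, seed = seed + 1000L * k_enterotype,
                   n_starts = n_starts)
      f$laplace_score <- laplace_evidence(f, counts)
      f
    })
  fit_ct <- curve$fits[[k_sel]]
  stage("serialize_fits", {
    write_dmm_fit(fit_et, file.path(out_dir, "fit_et"))
    write_dmm_fit(fit_ct, file.path(out_dir, "fit_ct"))
  })

  assign <- stage("assign", {
    et_asg <- assign_clusters(fit_et, counts)
    ct_asg <- assign_clusters(fit_ct, counts)
    grad <- gradient_score(counts, pseudocount = pseudocount)
    tibble::tibble(sample_id = et_asg$sample_id,
                   et = et_asg$cluster,
                   et_posterior = et_asg$max_posterior,
                   ct = ct_asg$cluster,
                   ct_posterior = ct_asg$max_posterior,
                   gradient = grad$gradient)
  })
  emit(assign, "assignments.tsv")

  stage("descriptors", {
    xt <- crosstab_models(assign$et, assign$ct)
    emit(dplyr::bind_cols(tibble::tibble(et = rownames(xt)),
                          tibble::as_tibble(xt, .name_repair = "minimal")),
         "correspondence.tsv")
    emit(driving_genera(fit_ct), "driving_genera.tsv")
    emit(alpha_diversity(counts), "diversity.tsv")
  })

  data <- dplyr::inner_join(cohort$phenotypes, assign, by = "sample_id")
  reps <- c(ET = "et", CT = "ct", gradient = "gradient")

  screen <- stage("associate", {
    screen_factors(data, cohort$kinds, reps,
                   fdr_threshold = fdr_threshold, nominal = nominal)
  })
  emit(flatten_results(screen$results), "association_results.tsv")
  emit(screen$summary, "association_summary.tsv")
  if (!is.null(screen$overlap)) emit(screen$overlap, "association_overlap.tsv")

  comp <- stage("compare_representations", {
    regress <- names(cohort$kinds)[cohort$kinds %in% c("binary", "continuous", "ordinal")]
    purrr::map_dfr(regress, function(fn)
      compare_representations(data, fn, cohort$kinds[[fn]],
                              et = "et", ct = "ct", gradient = "gradient"))
  })
  emit(comp, "representation_comparison.tsv")

  adjusted <- NULL
  confounding <- NULL
  if (length(cohort$diseases %||% character())) {
    adjusted <- stage("adjusted_disease", {
      purrr::map_dfr(names(reps)[1:2], function(lab) {
        purrr::map_dfr(cohort$diseases, function(dz)
          flatten_results(adjusted_disease_test(data, dz, reps[[lab]],
                                                representation_label = lab,
                                                covariates = covariates)))
      })
    })
    emit(adjusted, "adjusted_disease.tsv")
    if (length(cohort$drugs %||% character())) {
      confounding <- stage("deconfound", {
        sig <- adjusted[!is.na(adjusted$p_value) &
                          adjusted$p_value <= confound_alpha, ]
        purrr::map_dfr(seq_len(nrow(sig)), function(i) {
          rep_col <- reps[[sig$representation[i]]]
          scan <- drug_confounding_scan(data, sig$factor_name[i], rep_col,
                                        cohort$drugs, covariates = covariates,
                                        alpha = confound_alpha)
          tibble::tibble(disease = scan$disease,
                         representation = sig$representation[i],
                         baseline_p = scan$baseline_p,
                         confounded = scan$confounded,
                         confounding_drugs = paste(scan$confounding_drugs,
                                                   collapse = ","))
        })
      })
      emit(confounding, "confounding_report.tsv")
    }
  }

  surv <- NULL
  if (!is.null(cohort$incident)) {
    surv <- stage("survival", {
      screen_incident(cohort$incident,
                      cohort$prevalent %||%
                        tibble::tibble(sample_id = character(), icd10 = character()),
                      data, reps[1:2], covariates = covariates,
                      fdr_threshold = fdr_threshold)
    })
    emit(surv, "survival.tsv")
  } else {
    warn("no incident table supplied; survival stage skipped")
  }

  manifest <- list(
    package = "commtype",
    version = as.character(utils::packageVersion("commtype")),
    seed = seed,
    thresholds = list(k_max = k_max, k_enterotype = k_enterotype,
                      n_starts = n_starts, tau = tau,
                      fdr_threshold = fdr_threshold, nominal = nominal,
                      confound_alpha = confound_alpha,
                      pseudocount = pseudocount),
    selected_k = k_sel,
    n_samples = nrow(assign),
    n_genera = ncol(count_matrix(counts)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths[["manifest.json"]] <- file.path(out_dir, "manifest.json")

  invisible(list(counts = counts, curve = curve, selected_k = k_sel,
                 fit_et = fit_et, fit_ct = fit_ct, assignments = assign,
                 screen = screen, comparison = comp, adjusted = adjusted,
                 confounding = confounding, survival = surv, paths = paths))
}
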