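#' @importFrom stats glm lm logLik pchisq anova as.formula chisq.test
#'   complete.cases AIC coef binomial
NULL

# Recode a cluster label vector as a factor with the largest cluster as the
# reference level (the baseline every odds ratio is measured against).
cluster_factor <- function(labels) {
  f <- factor(labels)
  ref <- names(which.max(table(f)))
  stats::relevel(f, ref = ref)
}

lrt_pvalue <- function(fit_full, fit_reduced) {
  stat <- as.numeric(2 * (logLik(fit_full) - logLik(fit_reduced)))
  stat <- max(stat, 0)
  df <- attr(logLik(fit_full), "df") - attr(logLik(fit_reduced), "df")
  list(statistic = stat, df = as.integer(df),
       p_value = if (df >= 1) pchisq(stat, df, lower.tail = FALSE) else NA_real_)
}

empty_result <- function(factor_name, representation, test, note, adjusted,
                         covariates) {
  tibble::tibble(factor_name = factor_name, representation = representation,
                 test = test, statistic = NA_real_, df = NA_integer_,
                 p_value = NA_real_, n_used = NA_integer_,
                 adjusted = adjusted,
                 covariates = paste(covariates, collapse = ","),
                 note = note,
                 per_cluster = list(tibble::tibble()))
}

per_cluster_summary <- function(values, labels, kind) {
  if (is.null(labels)) return(tibble::tibble())
  tb <- tibble::tibble(cluster = labels, value = values)
  tb <- tb[!is.na(tb$value), ]
  if (kind %in% c("binary", "continuous", "ordinal")) {
    dplyr::summarise(dplyr::group_by(tb, .data$cluster),
                     n = dplyr::n(),
                     mean = mean(as.numeric(.data$value)), .groups = "drop")
  } else {
    dplyr::count(tb, .data$cluster, .data$value)
  }
}

#' Associate one phenotypic factor with a cluster or gradient representation
#'
#' Binary factors are tested by logistic regression of the factor on the
#' representation (plus optional covariates), with the global representation
#' p-value from a likelihood-ratio test against the covariate-only model;
#' continuous (and, by default, ordinal) factors likewise by linear
#' regression; categorical factors by a Pearson chi-squared test of the
#' factor-by-cluster table (no covariates, cluster representations only).
#' Complete cases only; the representation enters as a factor with the
#' largest cluster as reference, or as one numeric column for the gradient.
#'
#' @param data Data frame holding the factor, representation and covariates.
#' @param factor_name Column name of the factor to test.
#' @param kind One of `"binary"`, `"continuous"`, `"categorical"`, `"ordinal"`.
#' @param representation Column name of the representation (cluster labels or
#'   numeric gradient).
#' @param representation_label Label stored in the result (e.g. `"ET"`,
#'   `"CT"`, `"gradient"`); defaults to the column name.
#' @param covariates Character vector of covariate column names, or NULL.
#' @return One-row tibble: `factor_name`, `representation`, `test`,
#'   `statistic`, `df`, `p_value`, `n_used`, `adjusted`, `covariates`,
#'   `note`, and a `per_cluster` list-column of per-cluster summaries.
#' @export
associate_factor <- function(data, factor_name, kind, representation,
                             representation_label = representation,
                             covariates = NULL) {
  kind <- match.arg(kind, c("binary", "continuous", "categorical", "ordinal"))
  missing_cols <- setdiff(c(factor_name, representation, covariates), names(data))
  assert_that(length(missing_cols) == 0,
              paste0("columns not found: ", paste(missing_cols, collapse = ", ")))

  rep_raw <- data[[representation]]
  rep_is_gradient <- is.numeric(rep_raw) && length(unique(rep_raw[!is.na(rep_raw)])) > 12

  use <- complete.cases(data[, c(factor_name, representation, covariates), drop = FALSE])
  df_cc <- data[use, , drop = FALSE]
  y <- df_cc[[factor_name]]

  labels_for_summary <- if (rep_is_gradient) NULL else df_cc[[representation]]
  pcs <- per_cluster_summary(y, labels_for_summary, kind)
  adjusted <- length(covariates) > 0

  if (length(unique(y[!is.na(y)])) < 2) {
    out <- empty_result(factor_name, representation_label, "constant",
                        "factor is constant on complete cases", adjusted, covariates)
    out$per_cluster <- list(pcs)
    out$n_used <- sum(use)
    return(out)
  }

  if (kind == "categorical") {
    assert_that(!adjusted, "covariates are not supported for the chi-squared test")
    assert_that(!rep_is_gradient,
                "categorical factors need a cluster representation, not the gradient")
    tab <- table(y, df_cc[[representation]])
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    return(tibble::tibble(
      factor_name = factor_name, representation = representation_label,
      test = "chi_squared", statistic = unname(ct$statistic),
      df = as.integer(unname(ct$parameter)), p_value = unname(ct$p.value),
      n_used = sum(use), adjusted = FALSE, covariates = "",
      note = if (any(ct$expected < 1)) "expected cell count < 1" else "",
      per_cluster = list(pcs)))
  }

  model_df <- df_cc[, c(factor_name, covariates), drop = FALSE]
  model_df$.rep <- if (rep_is_gradient) as.numeric(df_cc[[representation]])
                   else cluster_factor(df_cc[[representation]])
  if (!rep_is_gradient && nlevels(model_df$.rep) < 2) {
    # nested models are identical: the LRT is exactly 0 and uninformative
    out <- empty_result(factor_name, representation_label, "constant_representation",
                        "representation is constant on complete cases",
                        adjusted, covariates)
    out$statistic <- 0
    out$df <- 0L
    out$p_value <- 1
    out$per_cluster <- list(pcs)
    out$n_used <- sum(use)
    return(out)
  }
  rhs_red <- if (adjusted) paste(covariates, collapse = " + ") else "1"
  f_full <- as.formula(paste0("`", factor_name, "` ~ ", rhs_red, " + .rep"))
  f_red <- as.formula(paste0("`", factor_name, "` ~ ", rhs_red))

  note <- ""
  if (kind == "binary") {
    assert_that(all(y %in% c(0, 1)), "binary factors must be coded 0/1")
    fit_full <- withCallingHandlers(
      glm(f_full, data = model_df, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          note <<- "possible separation in logistic fit"
        invokeRestart("muffleWarning")
      })
    fit_red <- suppressWarnings(glm(f_red, data = model_df, family = binomial()))
    test <- "logistic_LRT"
  } else {
    fit_full <- lm(f_full, data = model_df)
    fit_red <- lm(f_red, data = model_df)
    test <- "linear_LRT"
  }
  lrt <- lrt_pvalue(fit_full, fit_red)
  tibble::tibble(factor_name = factor_name, representation = representation_label,
                 test = test, statistic = lrt$statistic, df = lrt$df,
                 p_value = lrt$p_value, n_used = sum(use), adjusted = adjusted,
                 covariates = paste(covariates, collapse = ","), note = note,
                 per_cluster = list(pcs))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: with the m non-missing p-values sorted ascending,
#' `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1 and mapped back to
#' the input order. NAs are excluded from m and returned as NA.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  assert_that(all(p[ok] >= 0 & p[ok] <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen a factor panel against every representation
#'
#' Runs [associate_factor()] for each declared factor against each
#' representation, applies BH correction within each representation's family,
#' and summarises FDR-significant / nominally significant counts plus the
#' shared-vs-specific breakdown between the ET and CT models when both are
#' present.
#'
#' @param data Data frame with sample rows: factors, representations,
#'   covariates.
#' @param factor_kinds Named character vector: factor column -> kind.
#' @param representations Named character vector: representation label (e.g.
#'   `"ET"`, `"CT"`, `"gradient"`) -> column name in `data`.
#' @param covariates Optional covariate columns applied to every regression
#'   test (categorical factors are always unadjusted).
#' @param fdr_threshold FDR significance level, default 0.1.
#' @param nominal Nominal significance level, default 0.05.
#' @return List: `results` (tidy tibble with `q_value`),
#'   `summary` (per-representation counts), `overlap` (shared/specific
#'   counts for the ET/CT pair, if present).
#' @export
screen_factors <- function(data, factor_kinds, representations,
                           covariates = NULL, fdr_threshold = 0.1,
                           nominal = 0.05) {
  results <- purrr::map_dfr(names(representations), function(lab) {
    col <- representations[[lab]]
    purrr::map_dfr(names(factor_kinds), function(fn) {
      kind <- factor_kinds[[fn]]
      covs <- if (kind == "categorical") NULL else covariates
      tryCatch(
        associate_factor(data, fn, kind, col, representation_label = lab,
                         covariates = covs),
        error = function(e) empty_result(fn, lab, "error", conditionMessage(e),
                                         length(covs) > 0, covs))
    })
  })
  results <- dplyr::group_by(results, .data$representation)
  results <- dplyr::mutate(results, q_value = bh_fdr(.data$p_value))
  results <- dplyr::ungroup(results)

  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$representation),
    n_factors = dplyr::n(),
    n_fdr_significant = sum(.data$q_value <= fdr_threshold, na.rm = TRUE),
    n_nominal = sum(.data$p_value <= nominal, na.rm = TRUE),
    .groups = "drop")

  overlap <- NULL
  if (all(c("ET", "CT") %in% results$representation)) {
    sig <- function(lab) results$factor_name[
      results$representation == lab &
        !is.na(results$q_value) & results$q_value <= fdr_threshold]
    et <- sig("ET"); ct <- sig("CT")
    overlap <- tibble::tibble(shared = length(intersect(et, ct)),
                              et_specific = length(setdiff(et, ct)),
                              ct_specific = length(setdiff(ct, et)))
  }
  list(results = results, summary = summary, overlap = overlap)
}

#' Covariate-adjusted disease association
#'
#' Multivariate logistic regression of a binary (prevalent-disease)
#' indicator on the covariates plus the cluster representation, with the
#' cluster's contribution judged by a likelihood-ratio test against the
#' covariate-only model.
#'
#' @inheritParams associate_factor
#' @param disease Column name of the 0/1 disease indicator.
#' @param covariates Covariate columns, default
#'   `c("age", "bmi", "gender", "bristol")`.
#' @return One-row tibble as in [associate_factor()], with `adjusted = TRUE`.
#' @export
adjusted_disease_test <- function(data, disease, representation,
                                  representation_label = representation,
                                  covariates = c("age", "bmi", "gender", "bristol")) {
  associate_factor(data, disease, "binary", representation,
                   representation_label = representation_label,
                   covariates = covariates)
}

#' Post-hoc drug-confounding scan
#'
#' For a disease whose adjusted cluster association is significant, asks
#' whether any drug explains it away: for each drug column, the cluster term
#' is retested by LRT in a model already containing the covariates and that
#' drug. If for at least one drug the cluster no longer improves the fit
#' (cluster-term p > `alpha`), the disease-cluster association is flagged as
#' confounded and the drug(s) are listed.
#'
#' @param data Data frame with the disease, representation, covariates and
#'   drug indicator columns.
#' @param disease Column name of the 0/1 disease indicator.
#' @param representation Column name of the cluster representation.
#' @param drugs Character vector of 0/1 drug indicator columns.
#' @param covariates Covariate columns.
#' @param alpha Threshold on the cluster-term LRT p-value, default 0.05.
#' @return List: `disease`, `representation`, `baseline_p` (adjusted LRT p
#'   without drugs), `confounded` (logical), `drug_tests` (tibble with one
#'   row per drug: `drug`, `cluster_p`, `flagged`, `note`).
#' @export
drug_confounding_scan <- function(data, disease, representation, drugs,
                                  covariates = c("age", "bmi", "gender", "bristol"),
                                  alpha = 0.05) {
  base <- adjusted_disease_test(data, disease, representation,
                                covariates = covariates)
  drug_tests <- purrr::map_dfr(drugs, function(dr) {
    v <- data[[dr]]
    if (is.null(v)) return(tibble::tibble(drug = dr, cluster_p = NA_real_,
                                          flagged = FALSE, note = "column not found"))
    if (length(unique(v[!is.na(v)])) < 2) {
      return(tibble::tibble(drug = dr, cluster_p = NA_real_, flagged = FALSE,
                            note = "drug indicator constant; skipped"))
    }
    if (identical(as.numeric(v), as.numeric(data[[disease]]))) {
      return(tibble::tibble(drug = dr, cluster_p = NA_real_, flagged = FALSE,
                            note = "drug identical to disease; skipped"))
    }
    res <- tryCatch(
      associate_factor(data, disease, "binary", representation,
                       covariates = c(covariates, dr)),
      error = function(e) NULL)
    if (is.null(res) || is.na(res$p_value)) {
      return(tibble::tibble(drug = dr, cluster_p = NA_real_, flagged = FALSE,
                            note = "fit failed; skipped"))
    }
    tibble::tibble(drug = dr, cluster_p = res$p_value,
                   flagged = res$p_value > alpha, note = "")
  })
  if (nrow(drug_tests) == 0) {
    drug_tests <- tibble::tibble(drug = character(), cluster_p = numeric(),
                                 flagged = logical(), note = character())
  }
  confounded <- any(drug_tests$flagged)
  list(disease = disease, representation = representation,
       baseline_p = base$p_value, confounded = confounded,
       confounding_drugs = drug_tests$drug[drug_tests$flagged],
       drug_tests = drug_tests)
}

#' Compare cluster and gradient representations of one factor by AIC
#'
#' Fits three models of identical family (logistic for binary, linear for
#' continuous/ordinal factors) that differ only in the representation term —
#' enterotype labels, community-type labels, or the numeric gradient — and
#' reports each AIC and the winner.
#'
#' @param data Data frame with the factor, the three representation columns
#'   and any covariates.
#' @param factor_name Factor column.
#' @param kind `"binary"`, `"continuous"` or `"ordinal"`.
#' @param et,ct,gradient Column names of the three representations.
#' @param covariates Optional covariate columns included in every model.
#' @return One-row tibble: `factor_name`, `aic_ET`, `aic_CT`, `aic_gradient`,
#'   `best`, `partial`.
#' @export
compare_representations <- function(data, factor_name, kind, et = "et",
                                    ct = "ct", gradient = "gradient",
                                    covariates = NULL) {
  kind <- match.arg(kind, c("binary", "continuous", "ordinal"))
  cols <- c(factor_name, et, ct, gradient, covariates)
  missing_cols <- setdiff(cols, names(data))
  assert_that(length(missing_cols) == 0,
              paste0("columns not found: ", paste(missing_cols, collapse = ", ")))
  use <- complete.cases(data[, cols, drop = FALSE])
  df_cc <- data[use, , drop = FALSE]

  fit_one <- function(repcol, as_cluster) {
    md <- df_cc[, c(factor_name, covariates), drop = FALSE]
    md$.rep <- if (as_cluster) cluster_factor(df_cc[[repcol]])
               else as.numeric(df_cc[[repcol]])
    rhs <- paste(c(covariates, ".rep"), collapse = " + ")
    f <- as.formula(paste0("`", factor_name, "` ~ ", rhs))
    tryCatch({
      if (kind == "binary") AIC(suppressWarnings(glm(f, md, family = binomial())))
      else AIC(lm(f, md))
    }, error = function(e) NA_real_)
  }
  aics <- c(ET = fit_one(et, TRUE), CT = fit_one(ct, TRUE),
            gradient = fit_one(gradient, FALSE))
  partial <- any(is.na(aics))
  best <- if (all(is.na(aics))) NA_character_ else names(which.min(aics))
  tibble::tibble(factor_name = factor_name, aic_ET = aics[["ET"]],
                 aic_CT = aics[["CT"]], aic_gradient = aics[["gradient"]],
                 best = best, partial = partial)
}

#' Subdiagnosis distribution test
#'
#' Among carriers of a parent 3-digit diagnosis, tests whether the
#' 4-character subdiagnosis distribution differs across clusters by a
#' Pearson chi-squared test. Rare subcodes can optionally be pooled.
#'
#' @param subcodes Character vector of subdiagnosis codes (one per carrier;
#'   NA for non-carriers is dropped).
#' @param clusters Cluster labels aligned with `subcodes`.
#' @param pool_below Pool subcodes with fewer carriers than this into
#'   `"other"`; default 0 (no pooling).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n`, `n_subcodes`,
#'   `note`.
#' @export
subdiagnosis_test <- function(subcodes, clusters, pool_below = 0) {
  keep <- !is.na(subcodes) & !is.na(clusters)
  sub <- as.character(subcodes[keep])
  cl <- clusters[keep]
  if (pool_below > 0) {
    cnt <- table(sub)
    rare <- names(cnt)[cnt < pool_below]
    sub[sub %in% rare] <- "other"
  }
  if (length(unique(sub)) < 2) {
    return(tibble::tibble(statistic = NA_real_, df = NA_integer_,
                          p_value = NA_real_, n = length(sub),
                          n_subcodes = length(unique(sub)),
                          note = "fewer than two subcodes observed"))
  }
  tab <- table(sub, cl)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = as.integer(unname(ct$parameter)),
                 p_value = unname(ct$p.value), n = length(sub),
                 n_subcodes = nrow(tab),
                 note = if (any(ct$expected < 1)) "expected cell count < 1" else "")
}
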