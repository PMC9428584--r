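#' Exclude prevalent cases from an incident-disease cohort
#'
#' Samples with a prevalent record of the disease are removed before the
#' time-to-event analysis of that disease.
#'
#' @param cohort Data frame with a `sample_id` column (one row per subject
#'   at risk).
#' @param prevalent Tibble of prevalent records (`sample_id`, `icd10` or
#'   `disease_id`).
#' @param disease_id The disease code to exclude on.
#' @return List: `cohort` (filtered), `n_removed`, `removed_ids`.
#' @export
exclude_prevalent <- function(cohort, prevalent, disease_id) {
  code_col <- intersect(c("disease_id", "icd10"), names(prevalent))
  assert_that(length(code_col) >= 1,
              "prevalent table needs a 'disease_id' or 'icd10' column")
  hit <- unique(prevalent$sample_id[prevalent[[code_col[1]]] == disease_id])
  keep <- !(cohort$sample_id %in% hit)
  list(cohort = cohort[keep, , drop = FALSE],
       n_removed = sum(!keep),
       removed_ids = cohort$sample_id[!keep])
}

#' Cox proportional-hazards screen of one incident disease
#'
#' Fits `Surv(time, event) ~ covariates + cluster` with Efron tie handling,
#' the cluster entering as a factor with the largest cluster as reference
#' (or as a numeric column for the gradient). The headline p-value is the
#' likelihood-ratio test of the cluster term against the covariate-only
#' model; per-level hazard ratios with confidence intervals are reported
#' alongside.
#'
#' @param cohort Data frame with columns `time`, `event`, the cluster column
#'   and the covariates.
#' @param cluster Column name of the representation.
#' @param covariates Covariate columns, default
#'   `c("age", "bmi", "gender", "bristol")`.
#' @param conf_level Confidence level for hazard-ratio intervals.
#' @return A `cox_screen_result`: list with `n_at_risk`, `n_events`,
#'   `global` (tibble: LRT `statistic`, `df`, `p_value`), `terms` (tibble of
#'   per-level log-HRs, HRs and CIs), `fit` (the `coxph` object), `note`.
#' @export
cox_incident <- function(cohort, cluster, covariates = c("age", "bmi", "gender", "bristol"),
                         conf_level = 0.95) {
  needed <- c("time", "event", cluster, covariates)
  missing_cols <- setdiff(needed, names(cohort))
  assert_that(length(missing_cols) == 0,
              paste0("columns not found: ", paste(missing_cols, collapse = ", ")))
  use <- complete.cases(cohort[, needed, drop = FALSE])
  dd <- cohort[use, , drop = FALSE]
  assert_that(all(dd$time >= 0), "event times must be >= 0")

  out_shell <- function(note) {
    structure(list(cluster = cluster, n_at_risk = nrow(dd),
                   n_events = sum(dd$event),
                   global = tibble::tibble(statistic = NA_real_,
                                           df = NA_integer_, p_value = NA_real_),
                   terms = tibble::tibble(), fit = NULL, note = note),
              class = "cox_screen_result")
  }
  if (nrow(dd) == 0) return(out_shell("empty cohort"))
  if (sum(dd$event) < 1) return(out_shell("zero events"))

  rep_raw <- dd[[cluster]]
  rep_is_gradient <- is.numeric(rep_raw) && length(unique(rep_raw)) > 12
  dd$.rep <- if (rep_is_gradient) as.numeric(rep_raw) else cluster_factor(rep_raw)
  if (!rep_is_gradient && nlevels(dd$.rep) < 2) {
    res <- out_shell("cluster labels constant")
    res$global <- tibble::tibble(statistic = 0, df = 0L, p_value = 1)
    return(res)
  }

  rhs_red <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f_full <- as.formula(paste0("survival::Surv(time, event) ~ ", rhs_red, " + .rep"))
  f_red <- as.formula(paste0("survival::Surv(time, event) ~ ", rhs_red))
  fit <- tryCatch(survival::coxph(f_full, data = dd, ties = "efron"),
                  error = function(e) NULL,
                  warning = function(w) suppressWarnings(
                    survival::coxph(f_full, data = dd, ties = "efron")))
  if (is.null(fit)) return(out_shell("cox fit failed"))
  fit0 <- suppressWarnings(survival::coxph(f_red, data = dd, ties = "efron"))
  # the covariate-free model stores a single log-likelihood value
  ll1 <- fit$loglik[length(fit$loglik)]
  ll0 <- fit0$loglik[length(fit0$loglik)]
  stat <- max(0, as.numeric(2 * (ll1 - ll0)))
  df <- length(coef(fit)) - length(coef(fit0))
  if (length(coef(fit0)) == 0 && rhs_red == "1") df <- length(coef(fit))
  global <- tibble::tibble(statistic = stat, df = as.integer(df),
                           p_value = pchisq(stat, df, lower.tail = FALSE))

  sm <- summary(fit, conf.int = conf_level)
  keep_terms <- grepl("^\\.rep", rownames(sm$coefficients))
  terms <- tibble::tibble(
    term = sub("^\\.rep", "cluster ", rownames(sm$coefficients)[keep_terms]),
    log_hr = sm$coefficients[keep_terms, "coef"],
    hr = sm$conf.int[keep_terms, "exp(coef)"],
    hr_low = sm$conf.int[keep_terms, 3],
    hr_high = sm$conf.int[keep_terms, 4],
    p_value = sm$coefficients[keep_terms, "Pr(>|z|)"])

  structure(list(cluster = cluster, n_at_risk = nrow(dd),
                 n_events = sum(dd$event), global = global, terms = terms,
                 fit = fit, note = ""),
            class = "cox_screen_result")
}

#' @export
print.cox_screen_result <- function(x, ...) {
  cat(sprintf("<cox_screen_result> %d at risk, %d events\n",
              x$n_at_risk, x$n_events))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  if (!is.na(x$global$p_value))
    cat(sprintf("  cluster LRT: chi2 = %.3f, df = %d, p = %.4g\n",
                x$global$statistic, x$global$df, x$global$p_value))
  if (nrow(x$terms)) print(x$terms)
  invisible(x)
}

#' @param x A `cox_screen_result`.
#' @param ... Unused.
#' @rdname cox_incident
#' @export
tidy.cox_screen_result <- function(x, ...) x$terms

#' @rdname cox_incident
#' @export
glance.cox_screen_result <- function(x, ...) {
  tibble::tibble(n_at_risk = x$n_at_risk, n_events = x$n_events,
                 statistic = x$global$statistic, df = x$global$df,
                 p_value = x$global$p_value, note = x$note)
}

#' Proportional-hazards assumption test
#'
#' Tests the Cox model's proportional-hazards assumption via scaled
#' Schoenfeld residuals against a transform of time (Kaplan-Meier by
#' default), per term and globally.
#'
#' @param result A `cox_screen_result` (or a `coxph` fit).
#' @param transform Time transform, default `"km"`.
#' @return Tibble: `term`, `chisq`, `df`, `p_value` (last row `GLOBAL`), or
#'   an NA row with a `note` when the fit has too few events.
#' @export
ph_test <- function(result, transform = "km") {
  fit <- if (inherits(result, "cox_screen_result")) result$fit else result
  if (is.null(fit) || fit$nevent < 2) {
    return(tibble::tibble(term = NA_character_, chisq = NA_real_,
                          df = NA_integer_, p_value = NA_real_,
                          note = "too few events for a PH test"))
  }
  z <- survival::cox.zph(fit, transform = transform)
  tibble::tibble(term = rownames(z$table),
                 chisq = z$table[, "chisq"],
                 df = as.integer(z$table[, "df"]),
                 p_value = z$table[, "p"],
                 note = "")
}

#' Screen a panel of incident diseases
#'
#' For each disease: excludes its prevalent cases, fits the adjusted Cox
#' model per representation, runs the PH test, and applies BH correction
#' across diseases within each representation.
#'
#' @param incident Tibble (`sample_id`, `disease_id`, `time`, `event`).
#' @param prevalent Tibble of prevalent records (`sample_id`,
#'   `disease_id`/`icd10`).
#' @param samples Data frame with `sample_id`, the representation columns
#'   and covariates.
#' @param representations Named character vector: label -> column name.
#' @param covariates Covariate columns.
#' @param fdr_threshold FDR level, default 0.1.
#' @return Tidy tibble, one row per disease x representation: counts, global
#'   LRT statistic/df/`p_value`, `q_value`, `ph_global_p`, `n_prevalent_removed`,
#'   `note`.
#' @export
screen_incident <- function(incident, prevalent, samples, representations,
                            covariates = c("age", "bmi", "gender", "bristol"),
                            fdr_threshold = 0.1) {
  diseases <- sort(unique(incident$disease_id))
  rows <- purrr::map_dfr(diseases, function(dz) {
    inc <- incident[incident$disease_id == dz, , drop = FALSE]
    cohort <- dplyr::inner_join(samples, inc[, c("sample_id", "time", "event")],
                                by = "sample_id")
    exc <- exclude_prevalent(cohort, prevalent, dz)
    purrr::map_dfr(names(representations), function(lab) {
      res <- tryCatch(
        cox_incident(exc$cohort, representations[[lab]], covariates),
        error = function(e) NULL)
      if (is.null(res)) {
        return(tibble::tibble(disease_id = dz, representation = lab,
                              n_at_risk = NA_integer_, n_events = NA_integer_,
                              statistic = NA_real_, df = NA_integer_,
                              p_value = NA_real_, ph_global_p = NA_real_,
                              n_prevalent_removed = exc$n_removed,
                              note = "cox fit failed"))
      }
      phg <- tryCatch({
        pt <- ph_test(res)
        if ("note" %in% names(pt) && any(nzchar(pt$note))) NA_real_
        else pt$p_value[pt$term == "GLOBAL"]
      }, error = function(e) NA_real_)
      tibble::tibble(disease_id = dz, representation = lab,
                     n_at_risk = res$n_at_risk, n_events = res$n_events,
                     statistic = res$global$statistic, df = res$global$df,
                     p_value = res$global$p_value,
                     ph_global_p = if (length(phg)) phg else NA_real_,
                     n_prevalent_removed = exc$n_removed, note = res$note)
    })
  })
  rows <- dplyr::group_by(rows, .data$representation)
  rows <- dplyr::mutate(rows, q_value = bh_fdr(.data$p_value))
  dplyr::ungroup(rows)
}
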