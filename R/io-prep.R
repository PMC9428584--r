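#' Read a taxon count table from TSV
#'
#' Reads a tab-separated count table in either orientation. In the
#' taxa-in-rows layout the first column holds taxon ids and an optional
#' `taxonomy` column holds semicolon-separated lineage strings; in the
#' samples-in-rows layout the first column is `sample_id`. Lines starting
#' with `#` are ignored.
#'
#' @param path Path to a TSV file.
#' @param orientation One of `"auto"`, `"taxa_rows"`, `"samples_rows"`.
#'   `"auto"` detects taxa-in-rows by the presence of a `taxonomy` column or
#'   a first column named `taxon_id`.
#' @return A [taxa_counts] tibble.
#' @export
read_count_table <- function(path, orientation = c("auto", "taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         name_repair = "minimal")
  assert_that(ncol(raw) >= 2, "count table needs an id column plus data columns")
  first <- names(raw)[1]
  if (orientation == "auto") {
    orientation <- if ("taxonomy" %in% names(raw) || first %in% c("taxon_id", "taxon"))
      "taxa_rows" else "samples_rows"
  }
  if (orientation == "samples_rows") {
    names(raw)[1] <- "sample_id"
    return(taxa_counts(raw))
  }
  taxonomy <- NULL
  names(raw)[1] <- "taxon_id"
  raw$taxon_id <- as.character(raw$taxon_id)
  if ("taxonomy" %in% names(raw)) {
    taxonomy <- tibble::tibble(taxon_id = raw$taxon_id,
                               lineage = as.character(raw$taxonomy))
    raw$taxonomy <- NULL
  }
  dup <- raw$taxon_id[duplicated(raw$taxon_id)]
  assert_that(length(dup) == 0,
              paste0("duplicate taxon ids: ", paste(unique(dup), collapse = ", ")))
  m <- t(as.matrix(as.data.frame(raw[, -1, drop = FALSE])))
  colnames(m) <- raw$taxon_id
  rownames(m) <- names(raw)[-1]
  taxa_counts(m, taxonomy = taxonomy)
}

#' Write a taxon count table to TSV (taxa in rows)
#'
#' @param x A [taxa_counts] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  m <- count_matrix(x)
  out <- tibble::as_tibble(t(m), .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(taxon_id = colnames(m)), out)
  tax <- taxonomy_of(x)
  if (!is.null(tax)) {
    out$taxonomy <- tax$lineage[match(out$taxon_id, tax$taxon_id)]
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Remove low-depth samples
#'
#' Drops samples whose total read count falls below a threshold, or the `n`
#' lowest-depth samples (the form used when a cohort removes a handful of
#' samples "with an exceptionally low number of reads" without publishing a
#' cutoff).
#'
#' @param x A [taxa_counts] object.
#' @param min_reads Depth threshold; samples with total counts strictly below
#'   it are removed. Ignored when `n_lowest` is given.
#' @param n_lowest Alternatively, remove exactly this many samples, the ones
#'   with the smallest depths (ties broken by sample id order).
#' @return List with `counts` (filtered [taxa_counts]) and `removed`
#'   (tibble of `sample_id`, `depth`).
#' @export
drop_low_depth_samples <- function(x, min_reads = NULL, n_lowest = NULL) {
  m <- count_matrix(x)
  depth <- rowSums(m)
  if (!is.null(n_lowest)) {
    assert_that(n_lowest >= 0 && n_lowest < nrow(m),
                "n_lowest must be in [0, n_samples)")
    drop <- order(depth)[seq_len(n_lowest)]
  } else {
    assert_that(!is.null(min_reads), "give either min_reads or n_lowest")
    drop <- which(depth < min_reads)
  }
  assert_that(length(drop) < nrow(m), "all samples would be removed")
  removed <- tibble::tibble(sample_id = rownames(m)[drop],
                            depth = unname(depth[drop]))
  keep <- setdiff(seq_len(nrow(m)), drop)
  list(counts = rebuild_counts(m[keep, , drop = FALSE], taxonomy_of(x)),
       removed = removed)
}

#' Prevalence/abundance taxon filter
#'
#' Keeps a taxon when the fraction of samples in which it is detected — i.e.
#' its per-sample relative abundance is at least `rel_abund` — strictly
#' exceeds `prevalence_frac`. Defaults implement the common "detected at
#' 0.1% relative abundance in > 10% of samples" rule.
#'
#' @param x A [taxa_counts] object.
#' @param prevalence_frac Prevalence threshold (strict `>`), default 0.10.
#' @param rel_abund Per-sample detection threshold on relative abundance
#'   (inclusive `>=`), default 0.001.
#' @return Filtered [taxa_counts].
#' @export
filter_prevalent_taxa <- function(x, prevalence_frac = 0.10, rel_abund = 0.001) {
  m <- count_matrix(x)
  depth <- rowSums(m)
  assert_that(all(depth > 0), "zero-depth samples present; remove them first")
  detected <- sweep(m, 1, depth, "/") >= rel_abund
  prev <- colMeans(detected)
  keep <- prev > prevalence_frac
  if (!any(keep)) {
    abort(paste0("no taxa pass prevalence > ", prevalence_frac,
                 " at relative abundance >= ", rel_abund,
                 "; consider lowering the thresholds"))
  }
  rebuild_counts(m[, keep, drop = FALSE], taxonomy_of(x))
}

# pull the genus rank out of one lineage string; NA when absent
extract_genus <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  vapply(parts, function(p) {
    p <- trimws(p)
    g <- grep("^g__", p, value = TRUE)
    if (length(g) >= 1) {
      nm <- sub("^g__", "", g[[1]])
      return(if (nzchar(nm)) nm else NA_character_)
    }
    # plain 7-rank lineage: genus is the 6th field
    if (length(p) >= 6 && nzchar(p[[6]])) return(p[[6]])
    NA_character_
  }, character(1))
}

#' Aggregate a species-level table to genus level
#'
#' Sums counts over taxa sharing a genus (taken from the rank-labelled
#' lineage strings). Per-sample totals are conserved exactly. Taxa without a
#' genus label are pooled into an `"unclassified"` column by default so that
#' sequencing depth — which the multinomial model conditions on — is kept.
#'
#' @param x A [taxa_counts] object with taxonomy.
#' @param keep_unclassified Pool genus-less taxa into `"unclassified"`
#'   (default) instead of dropping them.
#' @return Genus-level [taxa_counts] (no taxonomy attribute).
#' @export
aggregate_to_genus <- function(x, keep_unclassified = TRUE) {
  tax <- taxonomy_of(x)
  assert_that(!is.null(tax), "table has no taxonomy; cannot aggregate to genus")
  m <- count_matrix(x)
  genus <- extract_genus(tax$lineage[match(colnames(m), tax$taxon_id)])
  assert_that(any(!is.na(genus)), "no lineage contains a genus rank")
  genus[is.na(genus)] <- if (keep_unclassified) "unclassified" else NA_character_
  keep <- !is.na(genus)
  m <- m[, keep, drop = FALSE]
  genus <- genus[keep]
  agg <- t(rowsum(t(m), group = genus))
  taxa_counts(agg[, order(colnames(agg)), drop = FALSE])
}

atc_parent <- function(code) {
  # ATC levels by code length: 7 (level 5) -> 5 (level 4) -> 4 (level 3)
  n <- nchar(code)
  dplyr::case_when(n >= 7 ~ substr(code, 1, 5),
                   n >= 5 ~ substr(code, 1, 4),
                   TRUE ~ NA_character_)
}

#' Group EHR diagnoses and drug exposures into analysis factors
#'
#' Disease indicators (3-digit ICD-10 categories) are kept when they have at
#' least `min_cases` carriers. Drug indicators are rolled up the ATC
#' hierarchy (level 5 to 4 to 3) until the rolled-up group reaches
#' `min_cases`; codes that never do are dropped.
#'
#' @param ehr List with tibbles `prevalent` (`sample_id`, `icd10`) and/or
#'   `drugs` (`sample_id`, `atc_code`, `used`).
#' @param sample_ids Character vector of all cohort sample ids (defines the
#'   0 rows of each indicator).
#' @param min_cases Minimum case count, default 20.
#' @return List with `phenotypes` (tibble: `sample_id` + one 0/1 column per
#'   retained factor) and `provenance` (tibble describing each factor's
#'   origin and any ATC roll-up).
#' @export
group_ehr_factors <- function(ehr, sample_ids, min_cases = 20) {
  out <- tibble::tibble(sample_id = as.character(sample_ids))
  prov <- list()

  if (!is.null(ehr$prevalent) && nrow(ehr$prevalent) > 0) {
    prev <- dplyr::distinct(ehr$prevalent, .data$sample_id, .data$icd10)
    bad <- !grepl("^[A-Z][0-9]{2}$", prev$icd10)
    assert_that(!any(bad), paste0("malformed ICD-10 3-digit codes: ",
                                  paste(unique(prev$icd10[bad]), collapse = ", ")))
    counts <- table(prev$icd10)
    for (code in names(counts)[counts >= min_cases]) {
      out[[code]] <- as.integer(out$sample_id %in% prev$sample_id[prev$icd10 == code])
      prov[[length(prov) + 1]] <- tibble::tibble(
        factor_name = code, source = "icd10", n_cases = as.integer(counts[[code]]),
        rolled_from = NA_character_)
    }
    dropped <- names(counts)[counts < min_cases]
    for (code in dropped) {
      prov[[length(prov) + 1]] <- tibble::tibble(
        factor_name = code, source = "icd10_dropped",
        n_cases = as.integer(counts[[code]]), rolled_from = NA_character_)
    }
  }

  if (!is.null(ehr$drugs) && nrow(ehr$drugs) > 0) {
    drugs <- dplyr::filter(ehr$drugs, .data$used == 1)
    bad <- nchar(drugs$atc_code) < 4 | nchar(drugs$atc_code) > 7
    assert_that(!any(bad), paste0("ATC codes must be 4-7 characters: ",
                                  paste(unique(drugs$atc_code[bad]), collapse = ", ")))
    work <- dplyr::distinct(drugs, .data$sample_id, .data$atc_code)
    users_of_prefix <- function(pfx)
      unique(work$sample_id[startsWith(work$atc_code, pfx)])
    codes <- sort(unique(work$atc_code))
    own_n <- vapply(codes, function(cd)
      length(unique(work$sample_id[work$atc_code == cd])), integer(1))

    kept <- codes[own_n >= min_cases]
    # each small code walks up the hierarchy until the prefix group — all
    # users of any code under that prefix — reaches min_cases
    assigned <- character()   # small code -> prefix it lands on ("" = dropped)
    for (cd in codes[own_n < min_cases]) {
      pfx <- atc_parent(cd)
      landed <- ""
      while (!is.na(pfx)) {
        if (length(users_of_prefix(pfx)) >= min_cases) {
          landed <- pfx
          break
        }
        pfx <- if (nchar(pfx) > 4) atc_parent(pfx) else NA_character_
      }
      assigned[[cd]] <- landed
    }
    pooled <- sort(unique(assigned[assigned != ""]))
    for (code in setdiff(kept, pooled)) {
      out[[code]] <- as.integer(out$sample_id %in%
                                  work$sample_id[work$atc_code == code])
      prov[[length(prov) + 1]] <- tibble::tibble(
        factor_name = code, source = "atc",
        n_cases = own_n[[which(codes == code)]], rolled_from = NA_character_)
    }
    for (pfx in pooled) {
      users <- users_of_prefix(pfx)
      out[[pfx]] <- as.integer(out$sample_id %in% users)
      prov[[length(prov) + 1]] <- tibble::tibble(
        factor_name = pfx, source = "atc",
        n_cases = length(users),
        rolled_from = paste(sort(names(assigned)[assigned == pfx]), collapse = ","))
    }
    for (cd in names(assigned)[assigned == ""]) {
      prov[[length(prov) + 1]] <- tibble::tibble(
        factor_name = cd, source = "atc_dropped",
        n_cases = own_n[[which(codes == cd)]], rolled_from = NA_character_)
    }
  }

  if (ncol(out) == 1) warn("no EHR factor reached the minimum case count")
  list(phenotypes = out,
       provenance = if (length(prov)) dplyr::bind_rows(prov) else
         tibble::tibble(factor_name = character(), source = character(),
                        n_cases = integer(), rolled_from = character()))
}

#' Write / read a phenotype table with a factor-kind sidecar
#'
#' The TSV holds `sample_id` plus one column per factor or covariate; the
#' sidecar YAML (`<path>.yml`) records each factor's measurement kind
#' (binary, continuous, categorical, ordinal) so that downstream tests pick
#' the right model without guessing.
#'
#' @param phenotypes Tibble with `sample_id` and factor columns.
#' @param kinds Named character vector mapping factor names to kinds.
#' @param path TSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, kinds, path) {
  unknown <- setdiff(names(kinds), names(phenotypes))
  assert_that(length(unknown) == 0,
              paste0("kinds given for absent factors: ", paste(unknown, collapse = ", ")))
  readr::write_tsv(phenotypes, path)
  yaml::write_yaml(as.list(kinds), paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_phenotypes
#' @return `read_phenotypes()`: list with `phenotypes` tibble and `kinds`
#'   named character vector.
#' @export
read_phenotypes <- function(path) {
  phenotypes <- readr::read_tsv(path, show_col_types = FALSE)
  side <- paste0(path, ".yml")
  kinds <- if (file.exists(side)) unlist(yaml::read_yaml(side)) else character()
  list(phenotypes = tibble::as_tibble(phenotypes), kinds = kinds)
}
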