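#' Taxon-by-sample count tables
#'
#' A `taxa_counts` object is a tibble with a `sample_id` column followed by
#' one non-negative integer column per taxon, optionally carrying a taxonomy
#' table (`taxon_id`, `lineage`) as an attribute. It is the common currency of
#' the preprocessing, community-typing and descriptor functions.
#'
#' @param counts A samples-by-taxa numeric matrix with dimnames, or a data
#'   frame with a `sample_id` column and one numeric column per taxon.
#' @param taxonomy Optional data frame with columns `taxon_id` and `lineage`
#'   (semicolon-separated rank-labelled lineage strings, kingdom to species).
#' @return A `taxa_counts` tibble.
#' @export
taxa_counts <- function(counts, taxonomy = NULL) {
  if (is.matrix(counts)) {
    assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
                "count matrix must have sample (row) and taxon (column) names")
    dup_t <- colnames(counts)[duplicated(colnames(counts))]
    assert_that(length(dup_t) == 0,
                paste0("duplicate taxon ids: ", paste(unique(dup_t), collapse = ", ")))
    tbl <- tibble::as_tibble(counts, .name_repair = "minimal")
    tbl <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(counts)), tbl)
  } else {
    tbl <- tibble::as_tibble(counts)
    assert_that("sample_id" %in% names(tbl),
                "count table must have a 'sample_id' column")
    tbl$sample_id <- as.character(tbl$sample_id)
  }
  validate_taxa_counts(tbl)
  if (!is.null(taxonomy)) {
    taxonomy <- tibble::as_tibble(taxonomy)
    assert_that(all(c("taxon_id", "lineage") %in% names(taxonomy)),
                "taxonomy must have columns 'taxon_id' and 'lineage'")
    missing <- setdiff(setdiff(names(tbl), "sample_id"), taxonomy$taxon_id)
    assert_that(length(missing) == 0,
                paste0("taxa missing from taxonomy: ",
                       paste(utils::head(missing, 5), collapse = ", ")))
    attr(tbl, "taxonomy") <- taxonomy
  }
  class(tbl) <- c("taxa_counts", class(tbl))
  tbl
}

validate_taxa_counts <- function(tbl) {
  taxa <- setdiff(names(tbl), "sample_id")
  assert_that(length(taxa) > 0, "count table has no taxon columns")
  dup_s <- tbl$sample_id[duplicated(tbl$sample_id)]
  assert_that(length(dup_s) == 0,
              paste0("duplicate sample ids: ", paste(unique(dup_s), collapse = ", ")))
  dup_t <- taxa[duplicated(taxa)]
  assert_that(length(dup_t) == 0,
              paste0("duplicate taxon ids: ", paste(unique(dup_t), collapse = ", ")))
  for (tx in taxa) {
    v <- tbl[[tx]]
    if (!is_count_vector(v)) {
      abort(paste0("taxon '", tx, "' has negative, non-finite or non-integer counts"))
    }
  }
  invisible(tbl)
}

#' Extract the numeric count matrix (samples x taxa) from a count table
#' @param x A `taxa_counts` object (or compatible data frame).
#' @return Numeric matrix with sample ids as rownames, taxa as colnames.
#' @export
count_matrix <- function(x) {
  taxa <- setdiff(names(x), "sample_id")
  m <- as.matrix(as.data.frame(x)[, taxa, drop = FALSE])
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

taxonomy_of <- function(x) attr(x, "taxonomy", exact = TRUE)

# rebuild a taxa_counts from a matrix, carrying over taxonomy rows still present
rebuild_counts <- function(m, taxonomy = NULL) {
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[taxonomy$taxon_id %in% colnames(m), , drop = FALSE]
    if (nrow(taxonomy) == 0) taxonomy <- NULL
  }
  taxa_counts(m, taxonomy = taxonomy)
}

#' @export
print.taxa_counts <- function(x, ...) {
  cat(sprintf("<taxa_counts> %d samples x %d taxa%s\n",
              nrow(x), ncol(x) - 1L,
              if (is.null(taxonomy_of(x))) "" else " (with taxonomy)"))
  NextMethod()
}
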