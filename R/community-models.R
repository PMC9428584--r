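#' Fit mixtures across a range of cluster numbers
#'
#' Fits the DM mixture for K = 1..`k_max` and scores each fit by its Laplace
#' evidence, producing the model-fit curve from which the enterotype (K = 3)
#' and optimal community-type models are read off.
#'
#' @param x Genus-level [taxa_counts] or count matrix.
#' @param k_max Largest K to consider, default 10.
#' @param seed Integer seed (each K uses a derived seed).
#' @param ... Passed on to [fit_dmm()] (e.g. `n_starts`).
#' @return A `dmm_fit_curve`: list with `curve` (tibble `k`, `laplace_score`,
#'   `log_likelihood`, `converged`) and `fits` (list of `dmm_fit`).
#' @export
fit_dmm_curve <- function(x, k_max = 10, seed = 1, ...) {
  X <- if (is.matrix(x)) x else count_matrix(x)
  fits <- vector("list", k_max)
  partial <- FALSE
  for (k in seq_len(k_max)) {
    fits[[k]] <- tryCatch({
      f <- fit_dmm(X, K = k, seed = seed + 1000L * k, ...)
      f$laplace_score <- laplace_evidence(f, X)
      f
    }, error = function(e) {
      warn(sprintf("fit for K=%d failed: %s", k, conditionMessage(e)))
      partial <<- TRUE
      NULL
    })
  }
  ok <- !vapply(fits, is.null, logical(1))
  curve <- tibble::tibble(
    k = which(ok),
    laplace_score = vapply(fits[ok], function(f) f$laplace_score, numeric(1)),
    log_likelihood = vapply(fits[ok], function(f) f$log_likelihood, numeric(1)),
    converged = vapply(fits[ok], function(f) f$converged, logical(1)))
  structure(list(curve = curve, fits = fits, partial = partial,
                 seed = as.integer(seed)),
            class = "dmm_fit_curve")
}

#' @export
print.dmm_fit_curve <- function(x, ...) {
  cat(sprintf("<dmm_fit_curve> K = %s%s\n",
              paste(range(x$curve$k), collapse = ".."),
              if (x$partial) " (partial)" else ""))
  print(x$curve)
  invisible(x)
}

#' @param x A `dmm_fit_curve`.
#' @param ... Unused.
#' @rdname fit_dmm_curve
#' @export
tidy.dmm_fit_curve <- function(x, ...) x$curve

#' Scree plot of the model-fit curve
#' @param object A `dmm_fit_curve`.
#' @param ... Unused.
#' @export
autoplot.dmm_fit_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$k, y = .data$laplace_score)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters K",
                  y = "Laplace score (lower = better)") +
    ggplot2::theme_minimal()
}

#' Select the number of clusters from a fit curve
#'
#' The default `"elbow"` rule formalises "no significant improvement in the
#' model fit": it returns the smallest K whose improvement to K+1 falls
#' below a fraction `tau` of the first improvement, i.e. the smallest k with
#' `score(k) - score(k+1) < tau * (score(1) - score(2))`. The `"min"` rule
#' returns the global minimiser of the score.
#'
#' @param curve A `dmm_fit_curve` or a tibble with columns `k` and
#'   `laplace_score`.
#' @param rule `"elbow"` (default) or `"min"`.
#' @param tau Elbow threshold fraction, default 0.05.
#' @return Selected K (integer).
#' @export
select_k <- function(curve, rule = c("elbow", "min"), tau = 0.05) {
  rule <- match.arg(rule)
  tbl <- if (inherits(curve, "dmm_fit_curve")) curve$curve else curve
  assert_that(nrow(tbl) >= 2, "need at least two fitted K values")
  tbl <- tbl[order(tbl$k), ]
  s <- tbl$laplace_score
  k <- tbl$k
  if (rule == "min") return(as.integer(k[which.min(s)]))
  gains <- s[-length(s)] - s[-1]
  if (gains[1] <= 0) {
    warn("score(2) >= score(1): no initial improvement, falling back to the global minimum")
    return(as.integer(k[which.min(s)]))
  }
  thr <- tau * gains[1]
  below <- which(gains < thr)
  if (length(below) == 0) return(as.integer(k[length(k)]))
  as.integer(k[min(below)])
}

#' Cross-tabulate two cluster models
#'
#' @param labels_a,labels_b Equal-length label vectors (e.g. enterotype and
#'   community-type assignments of the same samples).
#' @return Integer contingency matrix (A clusters in rows, B in columns).
#' @export
crosstab_models <- function(labels_a, labels_b) {
  assert_that(length(labels_a) == length(labels_b),
              "label vectors must have the same length")
  as.matrix(unclass(table(A = labels_a, B = labels_b)))
}

#' Driving genera of each cluster
#'
#' Ranks genera within each cluster by how far their expected proportion
#' `alpha_kj / A_k` deviates (absolutely) from the across-cluster mean
#' expected proportion; the strongest deviators are the genera that drive
#' the cluster's identity. Ties are broken alphabetically.
#'
#' @param fit A `dmm_fit`.
#' @param top_m Genera reported per cluster, default 10.
#' @return Tibble: `cluster`, `rank`, `genus`, `expected_prop`, `deviation`.
#' @export
driving_genera <- function(fit, top_m = 10) {
  m <- fit$alpha / rowSums(fit$alpha)       # K x G expected proportions
  dev <- abs(sweep(m, 2, colMeans(m), "-"))
  purrr::map_dfr(seq_len(fit$K), function(k) {
    ord <- order(-dev[k, ], colnames(m))
    idx <- ord[seq_len(min(top_m, ncol(m)))]
    tibble::tibble(cluster = k, rank = seq_along(idx),
                   genus = colnames(m)[idx],
                   expected_prop = unname(m[k, idx]),
                   deviation = unname(dev[k, idx]))
  })
}

#' Log Prevotella/Bacteroides gradient score
#'
#' The continuous "gradient model" representation of a sample:
#' `g_i = log((Prevotella_i + c) / (Bacteroides_i + c))` on genus counts,
#' natural log, with pseudocount `c` guarding zeros.
#'
#' @param x Genus-level [taxa_counts] or count matrix.
#' @param pseudocount Pseudocount `c`, default 0.5.
#' @param prevotella,bacteroides Genus column names, defaults `"Prevotella"`
#'   and `"Bacteroides"`.
#' @return Tibble: `sample_id`, `gradient`.
#' @export
gradient_score <- function(x, pseudocount = 0.5,
                           prevotella = "Prevotella", bacteroides = "Bacteroides") {
  X <- if (is.matrix(x)) x else count_matrix(x)
  for (g in c(prevotella, bacteroides)) {
    assert_that(g %in% colnames(X), paste0("genus column not found: ", g))
  }
  g <- log((X[, prevotella] + pseudocount) / (X[, bacteroides] + pseudocount))
  tibble::tibble(sample_id = rownames(X) %||% as.character(seq_len(nrow(X))),
                 gradient = unname(g))
}

#' Per-sample alpha diversity
#'
#' Observed richness (taxa with non-zero counts) and the Shannon index
#' (natural log) per sample.
#'
#' @param x A [taxa_counts] or count matrix.
#' @return Tibble: `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(x) {
  X <- if (is.matrix(x)) x else count_matrix(x)
  assert_that(all(rowSums(X) > 0), "zero-depth samples present; remove them first")
  tibble::tibble(sample_id = rownames(X) %||% as.character(seq_len(nrow(X))),
                 richness = as.integer(rowSums(X > 0)),
                 shannon = unname(vegan::diversity(X, index = "shannon")))
}

#' Bray-Curtis principal coordinates analysis
#'
#' Computes Bray-Curtis dissimilarities on per-sample proportions and embeds
#' the samples by classical metric scaling (double-centred eigendecomposition).
#' Negative eigenvalues are reported as-is, not corrected.
#'
#' @param x A [taxa_counts] or count matrix (typically species-level).
#' @param n_axes Number of coordinate axes returned, default 2.
#' @return List: `coordinates` (tibble `sample_id`, `axis1`, ...),
#'   `eigenvalues` (full vector), `dist` (the `dist` object),
#'   `degenerate` (TRUE when all pairwise dissimilarities are zero).
#' @export
bray_curtis_pcoa <- function(x, n_axes = 2) {
  X <- if (is.matrix(x)) x else count_matrix(x)
  assert_that(nrow(X) >= 3, "need at least 3 samples")
  P <- X / rowSums(X)
  d <- vegan::vegdist(P, method = "bray")
  degenerate <- all(d < .Machine$double.eps^0.5)
  if (degenerate) {
    warn("all pairwise Bray-Curtis dissimilarities are zero; coordinates are all zero")
    coords <- matrix(0, nrow(X), n_axes)
    eig <- rep(0, nrow(X) - 1)
  } else {
    mds <- stats::cmdscale(d, k = n_axes, eig = TRUE)
    coords <- mds$points
    # cmdscale may return fewer axes than asked when the spectrum collapses
    if (ncol(coords) < n_axes)
      coords <- cbind(coords, matrix(0, nrow(coords), n_axes - ncol(coords)))
    eig <- mds$eig
  }
  ct <- tibble::as_tibble(coords, .name_repair = ~ paste0("axis", seq_along(.x)))
  ct <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(X) %||% as.character(seq_len(nrow(X)))), ct)
  list(coordinates = ct, eigenvalues = eig, dist = d, degenerate = degenerate)
}

#' Ordination plot coloured by cluster
#'
#' @param pcoa Result of [bray_curtis_pcoa()].
#' @param clusters Optional label vector aligned with the samples.
#' @return A ggplot.
#' @export
plot_pcoa <- function(pcoa, clusters = NULL) {
  df <- pcoa$coordinates
  if (!is.null(clusters)) df$cluster <- factor(clusters)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::labs(x = "PCoA 1", y = "PCoA 2") + ggplot2::theme_minimal()
  if (is.null(clusters)) p + ggplot2::geom_point(alpha = 0.6)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), alpha = 0.6)
}
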