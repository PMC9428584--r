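#' Dirichlet-multinomial log probability mass
#'
#' Log density of a count vector under the Dirichlet-multinomial (DM)
#' compound distribution with concentration parameters `alpha`:
#' \deqn{\log\left[\frac{n!}{\prod_j x_j!}\,
#'   \frac{\Gamma(A)}{\Gamma(n+A)}\,
#'   \prod_j \frac{\Gamma(x_j+\alpha_j)}{\Gamma(\alpha_j)}\right],\quad
#'   A=\sum_j \alpha_j,}
#' evaluated entirely through `lgamma` so large counts never overflow.
#'
#' @param x Non-negative integer count vector.
#' @param alpha Positive concentration vector of the same length.
#' @return The log probability (a scalar).
#' @export
dm_log_pmf <- function(x, alpha) {
  assert_that(length(x) == length(alpha),
              "x and alpha must have the same length")
  assert_that(is_count_vector(x), "x must be non-negative integers")
  assert_that(is.numeric(alpha) && all(is.finite(alpha)) && all(alpha > 0),
              "alpha must be strictly positive and finite")
  n <- sum(x)
  A <- sum(alpha)
  lgamma(n + 1) - sum(lgamma(x + 1)) +
    lgamma(A) - lgamma(n + A) +
    sum(lgamma(x + alpha) - lgamma(alpha))
}

# Vectorised DM log-likelihood of every row of X under one alpha,
# excluding the multinomial coefficient (constant across components).
# X: N x G matrix; returns length-N vector.
dm_loglik_rows <- function(X, alpha, n = rowSums(X)) {
  A <- sum(alpha)
  lgamma(A) - lgamma(n + A) +
    rowSums(lgamma(X + rep(alpha, each = nrow(X)))) - sum(lgamma(alpha))
}

# multinomial coefficient term per sample (constant in alpha)
dm_const_rows <- function(X, n = rowSums(X)) {
  lgamma(n + 1) - rowSums(lgamma(X + 1))
}

# Weighted DM negative log-likelihood and gradient in theta = log(alpha).
# w: responsibilities for one component. Optional exponential(prior_rate)
# prior on alpha (plus the log-alpha Jacobian) for MAP polishing.
dm_negll_theta <- function(theta, X, w, n, prior_rate = 0) {
  alpha <- exp(theta)
  A <- sum(alpha)
  W <- sum(w)
  ll <- W * (lgamma(A) - sum(lgamma(alpha))) -
    sum(w * lgamma(n + A)) +
    sum(w * rowSums(lgamma(X + rep(alpha, each = nrow(X)))))
  if (prior_rate > 0) {
    ll <- ll + sum(log(prior_rate) - prior_rate * alpha + theta)
  }
  -ll
}

dm_neggrad_theta <- function(theta, X, w, n, prior_rate = 0) {
  alpha <- exp(theta)
  A <- sum(alpha)
  W <- sum(w)
  g_alpha <- W * (digamma(A) - digamma(alpha)) -
    sum(w * digamma(n + A)) +
    colSums(w * digamma(X + rep(alpha, each = nrow(X))))
  g_theta <- alpha * g_alpha
  if (prior_rate > 0) g_theta <- g_theta + (1 - prior_rate * alpha)
  -g_theta
}

# One weighted DM maximum-likelihood (or MAP) update from a starting alpha.
# Box constraints on log(alpha) keep a dying component (near-zero weights,
# flat objective) from driving the concentrations to numerical infinity.
fit_dm_component <- function(X, w, alpha0, n = rowSums(X), maxit = 25,
                             prior_rate = 0) {
  theta0 <- pmin(pmax(log(alpha0), log(1e-6)), log(1e6))
  opt <- stats::optim(theta0, fn = dm_negll_theta, gr = dm_neggrad_theta,
                      X = X, w = w, n = n, prior_rate = prior_rate,
                      method = "L-BFGS-B",
                      lower = log(1e-6), upper = log(1e6),
                      control = list(maxit = maxit))
  exp(opt$par)
}

# moment-style initial alpha from weighted mean proportions
init_alpha <- function(P, w, scale = 50) {
  p_bar <- colSums(P * w) / sum(w)
  pmax(p_bar * scale, 1e-3)
}

#' Fit a Dirichlet multinomial mixture by EM
#'
#' Fits a K-component DM mixture to a genus-level count table. The E-step
#' computes responsibilities from the component DM densities and mixing
#' weights; the M-step re-estimates the mixing weights in closed form and
#' improves each component's concentration vector by quasi-Newton steps on
#' the weighted DM log-likelihood in log-parameter space (a generalised EM,
#' so the observed-data log-likelihood is non-decreasing). Components are
#' initialised from a seeded k-means on the proportion vectors; further
#' starts perturb the assignment, and the best start by final log-likelihood
#' is returned.
#'
#' @param x A [taxa_counts] object or samples-by-taxa count matrix.
#' @param K Number of mixture components (>= 1).
#' @param seed Integer seed controlling initialisation; same seed, same fit.
#' @param n_starts Number of EM starts, default 5.
#' @param tol Relative log-likelihood convergence tolerance, default 1e-6.
#' @param max_iter Maximum EM iterations per start, default 1000.
#' @param m_step_maxit BFGS iterations per component per M-step, default 8
#'   (partial M-steps: cheaper, still monotone).
#' @param verbose Print per-start progress.
#' @return A `dmm_fit` object: `K`, `alpha` (K x G), `pi`, `responsibilities`
#'   (N x K), `log_likelihood`, `n_iter`, `converged`, `seed`, diagnostics.
#' @export
fit_dmm <- function(x, K, seed = 1, n_starts = 5, tol = 1e-6, max_iter = 1000,
                    m_step_maxit = 8, verbose = FALSE) {
  X <- if (is.matrix(x)) x else count_matrix(x)
  N <- nrow(X)
  G <- ncol(X)
  assert_that(K >= 1, "K must be >= 1")
  assert_that(N > K, "need more samples than components")
  n <- rowSums(X)
  assert_that(all(n > 0), "zero-depth samples present; remove them first")
  const <- dm_const_rows(X, n)
  P <- X / n
  pi_floor <- 1 / (10 * N)

  run_start <- function(start_seed, jitter) {
    # initial hard assignment
    z <- with_seed(start_seed, {
      if (K == 1) rep(1L, N)
      else {
        km <- tryCatch(stats::kmeans(P, centers = K, nstart = 3, iter.max = 30),
                       error = function(e) NULL)
        z0 <- if (is.null(km)) sample.int(K, N, replace = TRUE) else km$cluster
        if (jitter) {
          flip <- sample.int(N, max(1L, round(0.25 * N)))
          z0[flip] <- sample.int(K, length(flip), replace = TRUE)
        }
        z0
      }
    })
    R <- matrix(1e-6, N, K)
    R[cbind(seq_len(N), z)] <- 1
    R <- R / rowSums(R)

    alpha <- matrix(0, K, G, dimnames = list(NULL, colnames(X)))
    for (k in seq_len(K)) alpha[k, ] <- init_alpha(P, R[, k])
    pi_k <- colMeans(R)
    ll_old <- -Inf
    ll <- -Inf
    ll_trace <- numeric()
    converged <- FALSE
    flagged <- character()
    iter <- 0L
    for (iter in seq_len(max_iter)) {
      # M-step
      pi_k <- pmax(colMeans(R), pi_floor)
      pi_k <- pi_k / sum(pi_k)
      for (k in seq_len(K)) {
        alpha[k, ] <- fit_dm_component(X, R[, k], alpha[k, ], n,
                                       maxit = m_step_maxit)
      }
      # E-step
      LL <- vapply(seq_len(K), function(k) dm_loglik_rows(X, alpha[k, ], n),
                   numeric(N))
      LL <- matrix(LL, N, K)
      lw <- sweep(LL, 2, log(pi_k), "+")
      lse <- row_logsumexp(lw)
      R <- exp(lw - lse)
      ll <- sum(lse) + sum(const)
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    if (any(colMeans(R) < pi_floor)) flagged <- c(flagged, "small_component")
    if (!is.finite(ll) || ll > 0) {    # a log-probability must be negative
      flagged <- c(flagged, "degenerate")
      ll <- -Inf
    }
    list(alpha = alpha, pi = pi_k, R = R, ll = ll, iter = iter,
         converged = converged, flagged = flagged, ll_trace = ll_trace)
  }

  seeds <- seed + seq_len(n_starts) - 1L
  best <- NULL
  for (s in seq_along(seeds)) {
    cand <- run_start(seeds[s], jitter = s > 1)
    if (verbose) inform(sprintf("start %d: loglik %.3f (%d iter)",
                                s, cand$ll, cand$iter))
    if (is.null(best) || cand$ll > best$ll) best <- cand
  }
  if (!best$converged) warn("EM did not converge within max_iter; fit flagged")

  structure(list(K = as.integer(K), alpha = best$alpha, pi = best$pi,
                 responsibilities = best$R, log_likelihood = best$ll,
                 n_iter = best$iter, converged = best$converged,
                 ll_trace = best$ll_trace,
                 flags = best$flagged, seed = as.integer(seed),
                 genus = colnames(X), sample_ids = rownames(X),
                 laplace_score = NA_real_),
            class = "dmm_fit")
}

#' @export
print.dmm_fit <- function(x, ...) {
  cat(sprintf("<dmm_fit> K=%d, %d samples x %d genera\n", x$K,
              nrow(x$responsibilities), ncol(x$alpha)))
  cat(sprintf("  log-likelihood %.2f, %s in %d iterations\n", x$log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  if (is.finite(x$laplace_score))
    cat(sprintf("  Laplace score %.2f (lower is better)\n", x$laplace_score))
  cat(sprintf("  mixing weights: %s\n", paste(sprintf("%.3f", x$pi), collapse = " ")))
  invisible(x)
}

# Analytic Hessian of the negative log posterior of one component in
# log-alpha space, with responsibilities fixed:
#   l''(alpha)[j,l] = c + [j==l] d_j,  c = sum_i w_i (psi'(A) - psi'(n_i+A)),
#   d_j = sum_i w_i (psi'(x_ij+alpha_j) - psi'(alpha_j));
# chain rule to theta=log(alpha) adds a diagonal gradient term, and the
# exponential prior (with Jacobian) contributes rate*alpha on the diagonal.
component_hessian_theta <- function(X, w, alpha, n, prior_rate) {
  A <- sum(alpha)
  W <- sum(w)
  cc <- W * trigamma(A) - sum(w * trigamma(n + A))
  dj <- colSums(w * trigamma(X + rep(alpha, each = nrow(X)))) -
    W * trigamma(alpha)
  grad_alpha <- W * (digamma(A) - digamma(alpha)) -
    sum(w * digamma(n + A)) +
    colSums(w * digamma(X + rep(alpha, each = nrow(X))))
  H <- -(outer(alpha, alpha) * cc)
  diag(H) <- diag(H) - alpha^2 * dj - alpha * grad_alpha +
    prior_rate * alpha  # prior: -d2/dtheta2 [ -rate*alpha + theta ] = rate*alpha
  H
}

#' Laplace approximation of the DMM model evidence
#'
#' Scores a fitted mixture by the negative log marginal likelihood under a
#' Laplace (Gaussian) approximation of the parameter posterior taken in
#' log-concentration space:
#' \deqn{-\left[\log p(D\mid\hat\theta) + \log p(\hat\theta)
#'   + \tfrac{d}{2}\log 2\pi - \tfrac12 \log\det H\right],}
#' with `d = K*G` free concentration parameters, an independent
#' Exponential(`prior_rate`) prior on each concentration, and `H` the
#' block-diagonal (per-component, responsibilities fixed) Hessian of the
#' negative log posterior at its mode. Each component is first polished to
#' the posterior mode by a few quasi-Newton steps so the expansion point is
#' genuine. Lower scores mean better-supported models. Mixing weights are
#' held at their maximum-likelihood values and not counted as integrated
#' parameters.
#'
#' @param fit A `dmm_fit`.
#' @param x The count table the fit was produced from.
#' @param prior_rate Rate of the exponential prior on each concentration,
#'   default 0.1 (weak shrinkage).
#' @return The Laplace score (negative log evidence, scalar). Degenerate
#'   Hessians are handled by clipping eigenvalues at 1e-8; when that happens
#'   the value is computed from the clipped spectrum and a warning is issued.
#' @export
laplace_evidence <- function(fit, x, prior_rate = 0.1) {
  X <- if (is.matrix(x)) x else count_matrix(x)
  n <- rowSums(X)
  const <- dm_const_rows(X, n)
  K <- fit$K
  G <- ncol(X)
  R <- fit$responsibilities
  alpha <- fit$alpha
  # MAP polish per component with responsibilities fixed
  for (k in seq_len(K)) {
    alpha[k, ] <- fit_dm_component(X, R[, k], alpha[k, ], n, maxit = 40,
                                   prior_rate = prior_rate)
  }
  LL <- vapply(seq_len(K), function(k) dm_loglik_rows(X, alpha[k, ], n),
               numeric(nrow(X)))
  LL <- matrix(LL, nrow(X), K)
  lw <- sweep(LL, 2, log(fit$pi), "+")
  loglik <- sum(row_logsumexp(lw)) + sum(const)
  theta <- log(alpha)
  logprior <- sum(log(prior_rate) - prior_rate * alpha + theta)

  logdet <- 0
  clipped <- FALSE
  for (k in seq_len(K)) {
    H <- component_hessian_theta(X, R[, k], alpha[k, ], n, prior_rate)
    ev <- eigen(0.5 * (H + t(H)), symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < 1e-8)) {
      clipped <- TRUE
      ev <- pmax(ev, 1e-8)
    }
    logdet <- logdet + sum(log(ev))
  }
  if (clipped) warn("Laplace Hessian not positive definite; eigenvalues clipped at 1e-8")
  d <- K * G
  -(loglik + logprior + d / 2 * log(2 * pi) - 0.5 * logdet)
}

#' Posterior cluster assignment
#'
#' Computes posterior responsibilities of (possibly new) samples under a
#' fitted mixture and assigns each sample to the maximum-posterior
#' component, ties broken to the lowest component index.
#'
#' @param fit A `dmm_fit`.
#' @param x Count table over the same genus set the model was fitted on.
#' @return Tibble: `sample_id`, `cluster` (integer 1..K), `max_posterior`.
#' @export
assign_clusters <- function(fit, x) {
  X <- if (is.matrix(x)) x else count_matrix(x)
  missing <- setdiff(fit$genus, colnames(X))
  assert_that(length(missing) == 0,
              paste0("genera missing from the table: ",
                     paste(utils::head(missing, 10), collapse = ", ")))
  X <- X[, fit$genus, drop = FALSE]
  n <- rowSums(X)
  LL <- vapply(seq_len(fit$K), function(k) dm_loglik_rows(X, fit$alpha[k, ], n),
               numeric(nrow(X)))
  LL <- matrix(LL, nrow(X), fit$K)
  lw <- sweep(LL, 2, log(fit$pi), "+")
  R <- exp(lw - row_logsumexp(lw))
  labels <- max.col(R, ties.method = "first")
  tibble::tibble(sample_id = rownames(X) %||% as.character(seq_len(nrow(X))),
                 cluster = as.integer(labels),
                 max_posterior = R[cbind(seq_len(nrow(R)), labels)])
}

#' Serialise / restore a fitted mixture
#'
#' Writes the fit as a YAML parameter file plus a TSV of responsibilities so
#' samples can be re-assigned later without refitting.
#'
#' @param fit A `dmm_fit`.
#' @param path Basename; `<path>.yml` and `<path>_responsibilities.tsv` are
#'   written.
#' @return `path` invisibly; `read_dmm_fit(path)` returns the `dmm_fit`.
#' @export
write_dmm_fit <- function(fit, path) {
  yaml::write_yaml(list(
    K = fit$K, pi = as.numeric(fit$pi),
    alpha = apply(fit$alpha, 1, as.numeric, simplify = FALSE),
    genus = fit$genus, log_likelihood = fit$log_likelihood,
    laplace_score = fit$laplace_score, n_iter = fit$n_iter,
    converged = fit$converged, seed = fit$seed
  ), paste0(path, ".yml"), precision = 15)
  resp <- tibble::as_tibble(fit$responsibilities, .name_repair = ~ paste0("k", seq_along(.x)))
  resp <- dplyr::bind_cols(tibble::tibble(
    sample_id = fit$sample_ids %||% as.character(seq_len(nrow(fit$responsibilities)))), resp)
  readr::write_tsv(resp, paste0(path, "_responsibilities.tsv"))
  invisible(path)
}

#' @rdname write_dmm_fit
#' @export
read_dmm_fit <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  resp <- readr::read_tsv(paste0(path, "_responsibilities.tsv"),
                          show_col_types = FALSE)
  R <- as.matrix(resp[, -1, drop = FALSE])
  alpha <- do.call(rbind, meta$alpha)
  colnames(alpha) <- meta$genus
  structure(list(K = meta$K, alpha = alpha, pi = unlist(meta$pi),
                 responsibilities = unname(R),
                 log_likelihood = meta$log_likelihood,
                 laplace_score = meta$laplace_score %||% NA_real_,
                 n_iter = meta$n_iter, converged = meta$converged,
                 flags = character(), seed = meta$seed,
                 genus = meta$genus, sample_ids = resp$sample_id),
            class = "dmm_fit")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted mixture into per-cluster genus proportions
#' @param x A `dmm_fit`.
#' @param ... Unused.
#' @return Tibble: `cluster`, `genus`, `alpha`, `expected_prop`.
#' @export
tidy.dmm_fit <- function(x, ...) {
  A <- rowSums(x$alpha)
  tibble::tibble(
    cluster = rep(seq_len(x$K), each = ncol(x$alpha)),
    genus = rep(colnames(x$alpha), times = x$K),
    alpha = as.numeric(t(x$alpha)),
    expected_prop = as.numeric(t(x$alpha / A)))
}

#' One-row fit summary
#' @param x A `dmm_fit`.
#' @param ... Unused.
#' @export
glance.dmm_fit <- function(x, ...) {
  tibble::tibble(K = x$K, log_likelihood = x$log_likelihood,
                 laplace_score = x$laplace_score, n_iter = x$n_iter,
                 converged = x$converged,
                 min_pi = min(x$pi), max_pi = max(x$pi))
}

#' Heatmap of per-cluster expected genus proportions
#' @param object A `dmm_fit`.
#' @param top_m Show the `top_m` most variable genera, default 15.
#' @param ... Unused.
#' @export
autoplot.dmm_fit <- function(object, top_m = 15, ...) {
  td <- tidy.dmm_fit(object)
  spread <- tapply(td$expected_prop, td$genus, function(v) diff(range(v)))
  keep <- names(sort(spread, decreasing = TRUE))[seq_len(min(top_m, length(spread)))]
  td <- td[td$genus %in% keep, ]
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$cluster),
                                   y = .data$genus,
                                   fill = .data$expected_prop)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "expected\nproportion") +
    ggplot2::labs(x = "cluster", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
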