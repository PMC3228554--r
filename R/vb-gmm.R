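#' Variational-Bayes one-dimensional Gaussian mixture
#'
#' Fits a univariate Gaussian mixture by variational Bayes with conjugate
#' priors (Dirichlet on the weights, Normal-Gamma on each component's mean and
#' precision). The weight-concentration prior automatically switches off
#' superfluous components, giving an objective estimate of the number of
#' activity levels in a one-dimensional activity profile without BIC/AIC-style
#' model scans. The fit is restarted `n_restarts` times from random
#' initialisations and the run with the best variational lower bound (ELBO) is
#' kept; given a seed the result is deterministic.
#'
#' @param scores Activity profile: numeric vector or tibble with `sample`,
#'   `score` columns.
#' @param max_components Maximum number of mixture components (default 5).
#' @param seed Optional integer seed.
#' @param max_iter Maximum VB iterations per restart (default 500).
#' @param tol Absolute ELBO convergence tolerance (default 1e-4).
#' @param n_restarts Random restarts, best ELBO kept (default 3).
#' @param alpha0 Dirichlet weight-concentration prior (default
#'   `1/max_components`; smaller values prune components more aggressively).
#' @return A `dart_vb` object: `assignments` (component id per sample, by
#'   maximum responsibility), `component_means` (posterior means, all
#'   components), `occupied` (ids of components holding at least one sample),
#'   `ground_state` (occupied component with the lowest mean),
#'   `n_effective_components`, `weights`, `elbo`.
#' @export
vb_cluster_1d <- function(scores, max_components = 5, seed = NULL,
                          max_iter = 500, tol = 1e-4, n_restarts = 3,
                          alpha0 = 1 / max_components) {
  x <- as_score_vector(scores)
  n <- length(x)
  if (n < 2) abort("Need at least 2 samples to cluster.")
  if (max_components < 2) abort("`max_components` must be >= 2.")

  if (sd(x) == 0) {
    # degenerate: a single point mass
    return(new_dart_vb(
      assignments = rep(1L, n), means = mean(x)[1], weights = 1,
      elbo = NA_real_, sample_ids = names(x)
    ))
  }

  fit <- with_seed_if(seed, {
    # multi-resolution restarts: initialise from k-means partitions at
    # decreasing k (all fitted within the same K-component model, so ELBOs
    # are comparable). Coarser initialisations avoid the symmetric local
    # optimum where two components lock onto one tight cluster and never die.
    k_inits <- unique(round(seq(max_components, 2, length.out = n_restarts)))
    best <- NULL
    for (k0 in k_inits) {
      cand <- vb_gmm_fit(x, K = max_components, alpha0 = alpha0,
                         max_iter = max_iter, tol = tol, k_init = k0)
      if (is.null(best) || cand$elbo > best$elbo) best <- cand
    }
    best
  })

  assign <- max.col(fit$resp, ties.method = "first")
  new_dart_vb(
    assignments = assign, means = fit$m, weights = fit$alpha / sum(fit$alpha),
    elbo = fit$elbo, sample_ids = names(x)
  )
}

new_dart_vb <- function(assignments, means, weights, elbo, sample_ids = NULL) {
  occupied <- sort(unique(assignments))
  ground <- occupied[which.min(means[occupied])]
  structure(
    list(
      assignments = assignments,
      component_means = means,
      weights = weights,
      occupied = occupied,
      ground_state = ground,
      n_effective_components = length(occupied),
      elbo = elbo,
      sample_ids = sample_ids
    ),
    class = "dart_vb"
  )
}

# One VB run (Bishop-style univariate Normal-Gamma mixture).
# Prior: pi ~ Dir(alpha0); mu_k | lambda_k ~ N(m0, (beta0 lambda_k)^-1);
# lambda_k ~ Gamma(a0, b0). Responsibilities are initialised by k-means
# (randomly seeded centres, so restarts explore different partitions).
vb_gmm_fit <- function(x, K, alpha0, max_iter, tol, k_init = K) {
  n <- length(x)
  m0 <- mean(x)
  v0 <- var(x)
  beta0 <- 1e-3
  # vague, scale-invariant precision prior (mean 1/var(x), huge variance):
  # a stronger prior drags well-separated components toward the pooled
  # variance and merges adjacent activity levels
  a0 <- 1e-3
  b0 <- 1e-3 * v0

  K <- min(K, length(unique(x)))
  k0 <- min(k_init, K)
  assign0 <- suppressWarnings(
    stats::kmeans(x, centers = k0, nstart = 1, iter.max = 50)$cluster
  )
  resp <- matrix(1e-10, n, K)  # components beyond k0 start empty
  resp[cbind(seq_len(n), assign0)] <- 1
  resp <- resp / rowSums(resp)

  # M-step quantities from the initial hard assignment
  nk <- colSums(resp) + 1e-10
  xbar <- colSums(resp * x) / nk
  sk <- colSums(resp * outer(x, xbar, "-")^2) / nk
  alpha <- alpha0 + nk
  beta <- beta0 + nk
  m <- (beta0 * m0 + nk * xbar) / beta
  a <- a0 + nk / 2
  b <- b0 + 0.5 * (nk * sk + beta0 * nk * (xbar - m0)^2 / (beta0 + nk))

  elbo_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # E-step: responsibilities from expected log-densities
    e_log_pi <- digamma(alpha) - digamma(sum(alpha))
    e_log_lambda <- digamma(a) - log(b)
    e_lambda <- a / b
    # n x K matrix of E[lambda_k (x - mu_k)^2]
    quad <- outer(x, m, "-")^2 * rep(e_lambda, each = n) +
      matrix(1 / beta, n, K, byrow = TRUE)
    log_rho <- matrix(e_log_pi + 0.5 * e_log_lambda, n, K, byrow = TRUE) -
      0.5 * log(2 * pi) - 0.5 * quad
    mrho <- apply(log_rho, 1, max)
    lse <- mrho + log(rowSums(exp(log_rho - mrho)))
    resp <- exp(log_rho - lse)

    # ELBO computed with fresh responsibilities:
    # sum_n log sum_k rho_nk  -  KL(q(pi)||p(pi))  -  sum_k KL(q(mu,lambda)||p)
    kl_dir <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
      lgamma(K * alpha0) + K * lgamma(alpha0) +
      sum((alpha - alpha0) * (digamma(alpha) - digamma(sum(alpha))))
    kl_ng <- sum(
      0.5 * log(beta / beta0) - 0.5 +
        0.5 * beta0 * (1 / beta + (a / b) * (m - m0)^2) +
        (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
        a0 * (log(b) - log(b0)) + a * (b0 - b) / b
    )
    elbo <- sum(lse) - kl_dir - kl_ng
    if (abs(elbo - elbo_old) < tol) break
    elbo_old <- elbo

    # M-step: update variational parameters
    nk <- colSums(resp) + 1e-10
    xbar <- colSums(resp * x) / nk
    sk <- colSums(resp * outer(x, xbar, "-")^2) / nk
    alpha <- alpha0 + nk
    beta <- beta0 + nk
    m <- (beta0 * m0 + nk * xbar) / beta
    a <- a0 + nk / 2
    b <- b0 + 0.5 * (nk * sk + beta0 * nk * (xbar - m0)^2 / (beta0 + nk))
  }
  list(resp = resp, m = m, alpha = alpha, elbo = elbo)
}

#' @export
print.dart_vb <- function(x, ...) {
  cat(sprintf(
    "VB mixture: %d effective component(s); ground state mean %.3f\n",
    x$n_effective_components, x$component_means[x$ground_state]
  ))
  invisible(x)
}

#' @describeIn vb_cluster_1d `tidy()` returns per-sample assignments with the
#'   ground-state indicator.
#' @param x A `dart_vb` object.
#' @param ... Unused.
#' @export
tidy.dart_vb <- function(x, ...) {
  tibble(
    sample = x$sample_ids %||% as.character(seq_along(x$assignments)),
    component = x$assignments,
    component_mean = x$component_means[x$assignments],
    ground_state = x$assignments == x$ground_state
  )
}

#' @describeIn vb_cluster_1d `glance()` returns a one-row fit summary.
#' @export
glance.dart_vb <- function(x, ...) {
  tibble(
    n_effective_components = x$n_effective_components,
    ground_state_mean = x$component_means[x$ground_state],
    elbo = x$elbo
  )
}
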