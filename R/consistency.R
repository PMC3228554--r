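#' Edge sign predicted by the prior signature
#'
#' Two genes both annotated up (or both down) upon pathway activation are
#' predicted to be positively correlated (`+1`); genes regulated in opposite
#' directions are predicted anticorrelated (`-1`). The prediction is simply
#' the product of the two prior signs.
#'
#' @param signature Signature tibble (`gene`, `sign`).
#' @param gene_a,gene_b Gene identifier vectors (recycled to common length).
#' @return Integer vector of +1 / -1 predictions.
#' @export
#' @examples
#' sig <- tibble::tibble(gene = c("A", "B"), sign = c(1L, -1L))
#' predicted_edge_sign(sig, "A", "B")
predicted_edge_sign <- function(signature, gene_a, gene_b) {
  sig <- as_signature(signature)
  as.integer(signature_signs(sig, gene_a) * signature_signs(sig, gene_b))
}

#' Consistency of observed correlation signs with the prior
#'
#' An edge of the relevance network is consistent when its observed
#' correlation sign equals the sign predicted from the prior annotation. The
#' consistency score is the fraction of consistent edges.
#'
#' @param net A `relevance_network` (edges must carry `obs_sign`; predicted
#'   signs are recomputed from `signature` if supplied, otherwise the signs
#'   stored at build time are used).
#' @param signature Optional signature tibble to recompute predictions.
#' @return A tibble with `fraction_consistent` and `n_edges`.
#' @export
consistency_score <- function(net, signature = NULL) {
  edges <- net$edges
  if (nrow(edges) == 0) {
    abort("Consistency score undefined: the relevance network has no edges.")
  }
  pred <- if (is.null(signature)) {
    edges$pred_sign
  } else {
    predicted_edge_sign(signature, edges$gene_a, edges$gene_b)
  }
  tibble(
    fraction_consistent = mean(edges$obs_sign == pred),
    n_edges = nrow(edges)
  )
}

#' Randomization significance of the consistency score
#'
#' Tests whether the observed consistency fraction exceeds what the empirical
#' sign imbalance alone would produce. The probability of a positive edge sign
#' is estimated from the data (by default the fraction of positive observed
#' signs among the network's significant edges; `prob_from = "all_pairs"` uses
#' every signature-gene pair instead). Each randomization redraws every edge's
#' observed sign as +1 with that probability and recomputes the consistency
#' fraction; the p-value is the fraction of randomizations scoring strictly
#' higher than the observed network.
#'
#' @param net A `relevance_network`.
#' @param signature Optional signature to recompute predicted signs.
#' @param n_rand Number of randomizations (default 1000).
#' @param seed Optional integer seed.
#' @param prob_from Where to estimate the positive-sign probability:
#'   `"edges"` (significant edges, default) or `"all_pairs"`.
#' @param smooth If `TRUE`, report the add-one-smoothed p `(k + 1)/(n + 1)`
#'   instead of `k/n`, avoiding exact zeros.
#' @return A `dart_consistency` object: `n_edges`, `fraction_consistent`,
#'   `p_value`, `binom_prob_positive`, `n_randomisations`, `null_scores`.
#' @export
consistency_pvalue <- function(net, signature = NULL, n_rand = 1000,
                               seed = NULL, prob_from = c("edges", "all_pairs"),
                               smooth = FALSE) {
  prob_from <- rlang::arg_match(prob_from)
  if (n_rand < 1) abort("`n_rand` must be >= 1.")
  edges <- net$edges
  if (nrow(edges) == 0) {
    abort("Consistency p-value undefined: the relevance network has no edges.")
  }
  pred <- if (is.null(signature)) {
    edges$pred_sign
  } else {
    predicted_edge_sign(signature, edges$gene_a, edges$gene_b)
  }
  observed <- mean(edges$obs_sign == pred)
  q <- switch(prob_from,
    edges = mean(edges$obs_sign == 1L),
    all_pairs = mean(net$all_pairs$obs_sign == 1L)
  )
  n_e <- nrow(edges)
  null_scores <- with_seed_if(seed, {
    draws <- matrix(rbinom(n_rand * n_e, 1L, q) * 2L - 1L, nrow = n_rand)
    rowMeans(draws == matrix(pred, nrow = n_rand, ncol = n_e, byrow = TRUE))
  })
  k <- sum(null_scores > observed)
  p <- if (smooth) (k + 1) / (n_rand + 1) else k / n_rand
  structure(
    list(
      n_edges = n_e,
      fraction_consistent = observed,
      p_value = p,
      binom_prob_positive = q,
      n_randomisations = n_rand,
      null_scores = null_scores,
      prob_from = prob_from,
      smooth = smooth,
      seed = seed
    ),
    class = "dart_consistency"
  )
}

#' @export
print.dart_consistency <- function(x, ...) {
  cat(sprintf(
    "Consistency: %.3f over %d edge(s); randomization p = %.4g (%d draws, Pr[+] = %.3f)\n",
    x$fraction_consistent, x$n_edges, x$p_value, x$n_randomisations,
    x$binom_prob_positive
  ))
  invisible(x)
}

#' @describeIn consistency_pvalue `tidy()` returns the null consistency scores,
#'   one row per randomization.
#' @param x A `dart_consistency` object.
#' @param ... Unused.
#' @export
tidy.dart_consistency <- function(x, ...) {
  tibble(randomisation = seq_along(x$null_scores), null_score = x$null_scores)
}

#' @describeIn consistency_pvalue `glance()` returns a one-row summary.
#' @export
glance.dart_consistency <- function(x, ...) {
  tibble(
    n_edges = x$n_edges,
    fraction_consistent = x$fraction_consistent,
    p_value = x$p_value,
    binom_prob_positive = x$binom_prob_positive,
    n_randomisations = x$n_randomisations
  )
}

#' @describeIn consistency_pvalue Histogram of the randomization null with the
#'   observed consistency fraction marked.
#' @param object A `dart_consistency` object.
#' @export
autoplot.dart_consistency <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$fraction_consistent,
                        colour = "red", linewidth = 0.8) +
    ggplot2::labs(
      x = "null consistency fraction",
      y = "randomizations",
      title = sprintf("Observed consistency %.3f (p = %.3g)",
                      object$fraction_consistent, object$p_value)
    )
}
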