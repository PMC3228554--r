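#' Fisher-transform significance of a Pearson correlation
#'
#' Transforms a correlation `c` to `y = atanh(c) = 0.5 * log((1 + c)/(1 - c))`,
#' which under the null of no correlation between two genes measured on `n_s`
#' samples is approximately Normal with mean zero and standard deviation
#' `1/sqrt(n_s - 3)`. The two-sided tail probability of that null is returned
#' alongside the statistic.
#'
#' @param c Correlation value(s), each with `|c| < 1`.
#' @param n_s Number of samples used to compute the correlation; must be >= 4
#'   so the null standard deviation is defined.
#' @return A tibble with columns `cor`, `y`, `p_value`.
#' @export
#' @examples
#' fisher_statistic(c(0, 0.5, -0.5), n_s = 50)
fisher_statistic <- function(c, n_s) {
  if (length(n_s) != 1 || n_s < 4) abort("`n_s` must be a single value >= 4.")
  if (any(abs(c) >= 1)) {
    abort("Infinite Fisher statistic: |correlation| >= 1 (perfectly collinear genes).")
  }
  y <- atanh(c)
  tibble(cor = c, y = y, p_value = fisher_pvalue(y, n_s))
}

# Two-sided normal tail of the Fisher statistic; tolerates infinite y
# (collinear pairs), which get p = 0.
fisher_pvalue <- function(y, n_s) {
  2 * pnorm(-abs(y) * sqrt(n_s - 3))
}

#' All pairwise correlation edge statistics
#'
#' Computes textbook Pearson correlations between every pair of the requested
#' genes, with the Fisher-transform statistic and two-sided p-value for each
#' pair. Zero-variance genes are dropped with a warning. Perfectly collinear
#' pairs (`|c| = 1`) are retained with `p_value = 0` and flagged `collinear`
#' rather than erroring, so duplicated probes do not break network building.
#'
#' @param expr Expression data: wide tibble (`gene` column + sample columns)
#'   or genes x samples matrix.
#' @param genes Optional character vector restricting to a gene subset;
#'   default all genes in `expr`.
#' @return A tibble with one row per unordered pair (`gene_a < gene_b`
#'   lexicographically): `gene_a`, `gene_b`, `cor`, `y`, `p_value`,
#'   `obs_sign`, `collinear`.
#' @export
pairwise_correlations <- function(expr, genes = NULL) {
  m <- as_expr_matrix(expr, "expr")
  if (!is.null(genes)) {
    keep <- intersect(genes, rownames(m))
    if (length(keep) < 2) abort("Fewer than 2 requested genes present in the expression data.")
    m <- m[keep, , drop = FALSE]
  }
  n_s <- ncol(m)
  if (n_s < 4) abort("Need at least 4 samples (null SD requires n_s - 3 > 0).")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf(
      "Dropping %d zero-variance gene(s): %s",
      sum(sds == 0), paste(head(rownames(m)[sds == 0], 5), collapse = ", ")
    ))
    m <- m[sds > 0, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("Fewer than 2 usable genes after dropping zero-variance rows.")
  m <- m[order(rownames(m)), , drop = FALSE]

  cm <- cor(t(m))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  cvals <- cm[idx]
  collinear <- abs(cvals) >= 1 - 1e-12
  y <- ifelse(collinear, sign(cvals) * Inf, atanh(pmin(pmax(cvals, -1), 1)))
  tibble(
    gene_a = rownames(cm)[idx[, 1]],
    gene_b = rownames(cm)[idx[, 2]],
    cor = cvals,
    y = y,
    p_value = ifelse(collinear, 0, fisher_pvalue(y, n_s)),
    obs_sign = ifelse(cvals > 0, 1L, -1L),
    collinear = collinear
  )
}

#' Monte-Carlo false-positive calibration of the edge p-value threshold
#'
#' Because gene-pair correlations are not independent tests, the expected
#' number of false-positive edges at a given p-value threshold is estimated by
#' permutation: in each Monte-Carlo run every gene's expression profile is
#' independently permuted across samples (destroying all gene-gene correlation
#' while preserving marginals), all pairwise correlations are recomputed, and
#' the pairs passing the threshold are counted. The default threshold `1e-4`
#' yields well under one false positive per run for typical pathway sizes.
#'
#' @param expr Expression data (wide tibble or matrix).
#' @param genes Optional gene subset.
#' @param p_threshold Edge p-value threshold; default `1e-4`.
#' @param n_runs Number of Monte-Carlo runs; default 1000.
#' @param seed Optional integer seed for reproducible permutations.
#' @return A `dart_fdr` object: list with `avg_false_positives`, `per_run`
#'   (integer vector of per-run counts), `p_threshold`, `n_runs`, `n_pairs`.
#' @export
estimate_edge_fdr <- function(expr, genes = NULL, p_threshold = 1e-4,
                              n_runs = 1000, seed = NULL) {
  m <- as_expr_matrix(expr, "expr")
  if (!is.null(genes)) m <- m[intersect(genes, rownames(m)), , drop = FALSE]
  if (nrow(m) < 2) abort("Fewer than 2 genes for FDR estimation.")
  if (n_runs < 1) abort("`n_runs` must be >= 1.")
  n_s <- ncol(m)
  if (n_s < 4) abort("Need at least 4 samples.")
  ut <- upper.tri(diag(nrow(m)))
  per_run <- with_seed_if(seed, {
    vapply(seq_len(n_runs), function(run) {
      perm <- t(apply(m, 1, sample))
      cv <- cor(t(perm))[ut]
      pv <- ifelse(abs(cv) >= 1 - 1e-12, 0, fisher_pvalue(atanh(cv), n_s))
      sum(pv <= p_threshold)
    }, integer(1))
  })
  structure(
    list(
      avg_false_positives = mean(per_run),
      per_run = per_run,
      p_threshold = p_threshold,
      n_runs = n_runs,
      n_pairs = sum(ut),
      seed = seed
    ),
    class = "dart_fdr"
  )
}

#' @export
print.dart_fdr <- function(x, ...) {
  cat(sprintf(
    "Edge FDR calibration: %.4g expected false-positive edge(s)/run\n  (%d pairs, p <= %g, %d Monte-Carlo runs)\n",
    x$avg_false_positives, x$n_pairs, x$p_threshold, x$n_runs
  ))
  invisible(x)
}

#' @export
glance.dart_fdr <- function(x, ...) {
  tibble(
    avg_false_positives = x$avg_false_positives,
    p_threshold = x$p_threshold,
    n_runs = x$n_runs,
    n_pairs = x$n_pairs
  )
}

#' Edge p-value threshold calibrated to an expected false-positive count
#'
#' The edge threshold is chosen so that a network built on data with no true
#' gene-gene correlation contains fewer than `target` edges on average. Under
#' the permutation null each pair's p-value is marginally uniform (the
#' Monte-Carlo scheme of [estimate_edge_fdr()] destroys all correlation), so
#' the expected false-positive count at threshold `t` is exactly
#' `n_pairs * t` regardless of the dependence between pairs, and the
#' calibrated threshold is `target / n_pairs`. For genome-scale signatures
#' (hundreds of genes) this lands near the conventional `1e-4`; for small
#' gene sets it is correspondingly looser. Agreement with the Monte-Carlo
#' estimate can be checked with [estimate_edge_fdr()].
#'
#' @param n_genes Number of signature genes in the expression data.
#' @param target Expected false-positive edge count bound (default 1).
#' @return The p-value threshold `target / (n_genes * (n_genes - 1) / 2)`.
#' @export
fdr_calibrated_threshold <- function(n_genes, target = 1) {
  if (n_genes < 2) abort("`n_genes` must be >= 2.")
  target / (n_genes * (n_genes - 1) / 2)
}

#' Build the expression relevance network of a pathway signature
#'
#' Restricts the expression data to the signature genes, computes all pairwise
#' Pearson correlations, and keeps as edges the pairs whose Fisher-transform
#' p-value is at or below `p_threshold` (default `1e-4`, a threshold at which
#' permutation calibration gives a negligible expected false-positive count;
#' see [estimate_edge_fdr()]). Each edge carries its observed correlation
#' sign and the sign predicted by the prior (the product of the two genes'
#' signature signs), plus a consistency flag.
#'
#' @param expr Expression data (wide tibble or genes x samples matrix) with at
#'   least 4 samples.
#' @param signature Signature tibble (`gene`, `sign`).
#' @param p_threshold Edge p-value threshold in (0, 1]; `0` yields only exact
#'   collinear edges. Default `1e-4`.
#' @return A `relevance_network` object: list with `nodes` (tibble `gene`,
#'   `sign`), `edges` (significant pairs), `all_pairs` (every pair's
#'   statistics), `p_threshold`, `n_samples`, `pruned`.
#' @export
build_network <- function(expr, signature, p_threshold = 1e-4) {
  m <- as_expr_matrix(expr, "expr")
  sig <- as_signature(signature)
  present <- intersect(sig$gene, rownames(m))
  if (length(present) == 0) {
    abort(sprintf(
      "No signature gene found in the expression data (first missing: %s).",
      paste(head(sig$gene, 5), collapse = ", ")
    ))
  }
  if (length(present) < 2) {
    abort("Fewer than 2 signature genes present in the expression data.")
  }
  pairs <- pairwise_correlations(m, genes = present)
  used <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  nodes <- tibble(gene = used, sign = signature_signs(sig, used))
  pairs$pred_sign <- predicted_edge_sign(sig, pairs$gene_a, pairs$gene_b)
  pairs$consistent <- pairs$obs_sign == pairs$pred_sign
  structure(
    list(
      nodes = nodes,
      edges = dplyr::filter(pairs, .data$p_value <= p_threshold),
      all_pairs = pairs,
      p_threshold = p_threshold,
      n_samples = ncol(m),
      pruned = FALSE
    ),
    class = "relevance_network"
  )
}

#' @export
print.relevance_network <- function(x, ...) {
  cat(sprintf(
    "Relevance network: %d nodes, %d edge(s) at p <= %g (%s), n_S = %d\n",
    nrow(x$nodes), nrow(x$edges), x$p_threshold,
    if (x$pruned) "pruned" else "unpruned", x$n_samples
  ))
  invisible(x)
}

#' @describeIn build_network `tidy()` returns the edge table.
#' @param x A `relevance_network`.
#' @param ... Unused.
#' @export
tidy.relevance_network <- function(x, ...) x$edges

#' @describeIn build_network `glance()` returns a one-row network summary
#'   (`fraction_possible_edges` is edges over all unordered node pairs, the
#'   `fE` column of consistency reports).
#' @export
glance.relevance_network <- function(x, ...) {
  n_g <- nrow(x$nodes)
  tibble(
    n_nodes = n_g,
    n_edges = nrow(x$edges),
    fraction_possible_edges = nrow(x$edges) / (n_g * (n_g - 1) / 2),
    p_threshold = x$p_threshold,
    n_samples = x$n_samples,
    pruned = x$pruned
  )
}
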