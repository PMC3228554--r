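# Fixture builders shared across test files. All data is generated in code.

# genes x samples matrix -> wide expression tibble
make_expr <- function(m, genes = NULL, samples = NULL) {
  if (!is.null(genes)) rownames(m) <- genes
  if (!is.null(samples)) colnames(m) <- samples
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene = rownames(m)), tibble::as_tibble(m))
}

make_signature <- function(genes, signs = 1L) {
  tibble::tibble(gene = genes, sign = as.integer(rep_len(signs, length(genes))))
}

# Hand-built relevance network: edges as a data frame with gene_a, gene_b,
# obs_sign (and optional cor); predicted signs come from the signature.
toy_network <- function(edges, signature, n_samples = 50, p_threshold = 1e-4) {
  edges <- tibble::as_tibble(edges)
  if (!"cor" %in% names(edges) && nrow(edges) > 0) {
    edges$cor <- 0.5 * edges$obs_sign
  }
  if (nrow(edges) > 0) {
    edges$y <- atanh(edges$cor)
    edges$p_value <- 2 * stats::pnorm(-abs(edges$y) * sqrt(n_samples - 3))
    edges$collinear <- FALSE
    edges$pred_sign <- predicted_edge_sign(signature, edges$gene_a, edges$gene_b)
    edges$consistent <- edges$obs_sign == edges$pred_sign
  } else {
    edges <- tibble::tibble(
      gene_a = character(), gene_b = character(), cor = double(),
      y = double(), p_value = double(), obs_sign = integer(),
      collinear = logical(), pred_sign = integer(), consistent = logical()
    )
  }
  nodes <- tibble::tibble(
    gene = sort(unique(signature$gene)),
    sign = signature$sign[match(sort(unique(signature$gene)), signature$gene)]
  )
  structure(
    list(nodes = nodes, edges = edges, all_pairs = edges,
         p_threshold = p_threshold, n_samples = n_samples, pruned = FALSE),
    class = "relevance_network"
  )
}

# Exact null tail of the consistency score: the count of consistent edges is
# the sum of two independent binomials, Bin(n_plus, q) over edges predicted
# positive and Bin(n_minus, 1 - q) over edges predicted negative. Returns
# P(count > k_obs) by direct convolution — independent of the Monte-Carlo code.
exact_consistency_tail <- function(n_plus, n_minus, q, k_obs) {
  pmf_plus <- stats::dbinom(0:n_plus, n_plus, q)
  pmf_minus <- stats::dbinom(0:n_minus, n_minus, 1 - q)
  pmf <- as.vector(outer(pmf_plus, pmf_minus, "*"))
  counts <- as.vector(outer(0:n_plus, 0:n_minus, "+"))
  sum(pmf[counts > k_obs])
}

# Minimal dart_vb object with given hard assignments and component means.
new_vb_for_test <- function(assignments, means) {
  occupied <- sort(unique(assignments))
  structure(
    list(
      assignments = as.integer(assignments),
      component_means = means,
      weights = rep(1 / length(means), length(means)),
      occupied = occupied,
      ground_state = occupied[which.min(means[occupied])],
      n_effective_components = length(occupied),
      elbo = NA_real_,
      sample_ids = NULL
    ),
    class = "dart_vb"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
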