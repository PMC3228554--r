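#' Z-score normalise expression profiles
#'
#' Centres and scales each gene's profile to mean zero and unit variance
#' across the samples on which activity is being estimated. The default uses
#' the population standard deviation (denominator `n`); the `1/(n - 1)` sample
#' convention is available and only rescales downstream scores. Constant
#' (zero-SD) genes are dropped with a warning.
#'
#' @param expr Expression data (wide tibble or genes x samples matrix).
#' @param genes Optional gene subset.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A wide tibble (`gene` + sample columns) of z-scored profiles.
#' @export
zscore_expression <- function(expr, genes = NULL,
                              sd_type = c("population", "sample")) {
  sd_type <- rlang::arg_match(sd_type)
  m <- as_expr_matrix(expr, "expr")
  if (!is.null(genes)) {
    keep <- intersect(genes, rownames(m))
    if (length(keep) == 0) abort("None of the requested genes are present.")
    m <- m[keep, , drop = FALSE]
  }
  expr_as_tibble(zscore_matrix(m, sd_type))
}

zscore_matrix <- function(m, sd_type = "population") {
  mu <- rowMeans(m)
  centred <- m - mu
  s <- if (sd_type == "population") {
    sqrt(rowMeans(centred^2))
  } else {
    apply(m, 1, sd)
  }
  if (any(s == 0)) {
    warn(sprintf(
      "Dropping %d constant gene(s) from z-scoring: %s",
      sum(s == 0), paste(head(rownames(m)[s == 0], 5), collapse = ", ")
    ))
    keep <- s > 0
    centred <- centred[keep, , drop = FALSE]
    s <- s[keep]
    if (length(s) == 0) abort("All genes are constant; nothing to z-score.")
  }
  centred / s
}

activity_tibble <- function(scores, method, genes, unreliable = FALSE) {
  out <- tibble(
    sample = names(scores),
    score = unname(scores),
    method = method
  )
  attr(out, "genes_used") <- genes
  attr(out, "unreliable") <- unreliable
  out
}

#' Simple-average pathway activity (unweighted metric)
#'
#' For each sample, the signed average of the z-scored expression of the genes
#' used: `score_s = (1/M) * sum_i sigma_i * z_is`, where `sigma_i` is the
#' prior regulation sign. Applied to the full signature this is the unpruned
#' average estimator (UPR-AV); applied to the genes of a pruned component it
#' is the pruned average (PR-AV).
#'
#' @param expr Expression data on which activity is estimated (z-scoring is
#'   done internally on these samples).
#' @param signature Signature tibble (`gene`, `sign`); only genes present in
#'   `expr` are used.
#' @param genes Optional subset of signature genes (e.g. a component's nodes).
#' @param method Label stored in the output (`"UPR-AV"` default).
#' @param sd_type Z-scoring convention, see [zscore_expression()].
#' @return An activity tibble: `sample`, `score`, `method`.
#' @export
activity_unweighted <- function(expr, signature, genes = NULL,
                                method = "UPR-AV",
                                sd_type = c("population", "sample")) {
  sd_type <- rlang::arg_match(sd_type)
  m <- as_expr_matrix(expr, "expr")
  sig <- as_signature(signature)
  use <- sort(intersect(if (is.null(genes)) sig$gene else genes, rownames(m)))
  if (length(use) == 0) abort("No usable genes for activity estimation.")
  z <- zscore_matrix(m[use, , drop = FALSE], sd_type)
  sigma <- signature_signs(sig, rownames(z))
  scores <- colMeans(sigma * z)
  activity_tibble(scores, method, rownames(z))
}

#' Degree-weighted pathway activity (hub-weighted metric)
#'
#' The topology-aware metric computed over a pruned consistent component:
#' each gene is weighted by its number of neighbours, so correlation hubs --
#' the most reliable pathway markers -- dominate the estimate:
#' `score_s = (1/sqrt(sum_i k_i^2)) * sum_i sigma_i * k_i * z_is`.
#' The `1/sqrt(sum k_i^2)` normalisation makes the score unit-variance when
#' the z-scored profiles are independent unit-variance variables.
#'
#' @param expr Expression data on which activity is estimated.
#' @param comp A `dart_component` giving genes, prior signs and degrees.
#' @param sd_type Z-scoring convention, see [zscore_expression()].
#' @return An activity tibble: `sample`, `score`, `method = "DART"`.
#' @export
activity_weighted <- function(expr, comp,
                              sd_type = c("population", "sample")) {
  sd_type <- rlang::arg_match(sd_type)
  if (!inherits(comp, "dart_component")) abort("`comp` must be a `dart_component`.")
  m <- as_expr_matrix(expr, "expr")
  use <- sort(intersect(comp$nodes$gene, rownames(m)))
  if (length(use) == 0) abort("No component gene present in the expression data.")
  z <- zscore_matrix(m[use, , drop = FALSE], sd_type)
  idx <- match(rownames(z), comp$nodes$gene)
  k <- comp$nodes$degree[idx]
  sigma <- comp$nodes$sign[idx]
  w <- sigma * k / sqrt(sum(k^2))
  scores <- colSums(w * z)
  activity_tibble(scores, "DART", rownames(z))
}
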