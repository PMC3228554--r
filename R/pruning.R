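#' Prune prior-inconsistent edges from a relevance network
#'
#' The denoising step: edges whose observed correlation sign disagrees with the
#' prior prediction are removed. Nodes are kept (genes disconnected by pruning
#' simply become isolated and drop out of the largest component later), and
#' pruning is idempotent.
#'
#' @param net A `relevance_network`.
#' @param signature Optional signature to recompute predicted signs before
#'   pruning.
#' @return A `relevance_network` with only consistent edges and `pruned = TRUE`.
#' @export
prune_inconsistent <- function(net, signature = NULL) {
  edges <- net$edges
  if (!is.null(signature) && nrow(edges) > 0) {
    edges$pred_sign <- predicted_edge_sign(signature, edges$gene_a, edges$gene_b)
    edges$consistent <- edges$obs_sign == edges$pred_sign
  }
  net$edges <- dplyr::filter(edges, .data$consistent)
  net$pruned <- TRUE
  net
}

#' Largest connected component of a (pruned) relevance network
#'
#' Extracts the maximally connected component, over which pathway activity is
#' estimated. Node degrees are counted within the component. Ties on node
#' count are broken deterministically: larger edge count first, then the
#' component containing the lexicographically smallest gene id.
#'
#' @param net A `relevance_network`, normally after [prune_inconsistent()].
#' @return A `dart_component`: list with `nodes` (tibble `gene`, `sign`,
#'   `degree`, sorted by gene), `edges`, `parent_network_size`.
#' @export
max_connected_component <- function(net) {
  edges <- net$edges
  if (nrow(edges) == 0) {
    abort(paste(
      "Empty component: the pruned network has no edges.",
      "Fall back to the unpruned average estimator (see `run_dart(fallback_unpruned=)`)."
    ))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = net$nodes$gene
  )
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie-break: edge count, then smallest member gene id
    counts <- vapply(best, function(k) {
      members <- names(comp$membership)[comp$membership == k]
      sum(edges$gene_a %in% members & edges$gene_b %in% members)
    }, numeric(1))
    best <- best[counts == max(counts)]
    if (length(best) > 1) {
      first_gene <- vapply(best, function(k) {
        min(names(comp$membership)[comp$membership == k])
      }, character(1))
      best <- best[order(first_gene)[1]]
    }
  }
  members <- sort(names(comp$membership)[comp$membership == best[1]])
  comp_edges <- dplyr::filter(edges, .data$gene_a %in% members & .data$gene_b %in% members)
  deg <- table(c(comp_edges$gene_a, comp_edges$gene_b))
  nodes <- tibble(
    gene = members,
    sign = signature_signs(net$nodes, members),
    degree = as.integer(deg[members])
  )
  structure(
    list(
      nodes = nodes,
      edges = comp_edges,
      parent_network_size = nrow(net$nodes),
      n_samples = net$n_samples,
      p_threshold = net$p_threshold
    ),
    class = "dart_component"
  )
}

#' Rank the genes of a pruned component by hubness
#'
#' Hubs (high-degree genes in the consistent relevance network) are the most
#' reliable markers of pathway activity and receive the largest weights in the
#' degree-weighted activity metric. Ties are broken lexicographically by gene
#' id.
#'
#' @param comp A `dart_component`.
#' @return A tibble (`gene`, `degree`, `prior_sign`) in descending degree
#'   order.
#' @export
hub_ranking <- function(comp) {
  if (!inherits(comp, "dart_component")) abort("`comp` must be a `dart_component`.")
  comp$nodes |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene) |>
    dplyr::select(gene = "gene", degree = "degree", prior_sign = "sign")
}

#' @export
print.dart_component <- function(x, ...) {
  cat(sprintf(
    "Pruned component: %d of %d network gene(s), %d consistent edge(s)\n",
    nrow(x$nodes), x$parent_network_size, nrow(x$edges)
  ))
  invisible(x)
}

#' @describeIn max_connected_component `tidy()` returns the hub-ranked node
#'   table.
#' @param x A `dart_component`.
#' @param ... Unused.
#' @export
tidy.dart_component <- function(x, ...) hub_ranking(x)

#' @describeIn max_connected_component `glance()` returns a one-row summary.
#' @export
glance.dart_component <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    parent_network_size = x$parent_network_size,
    max_degree = max(x$nodes$degree)
  )
}

#' @describeIn max_connected_component Network diagram of the component,
#'   node size proportional to degree, colour = prior sign.
#' @param object A `dart_component`.
#' @param seed Seed for the deterministic graph layout.
#' @export
autoplot.dart_component <- function(object, seed = 1L, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[, c("gene_a", "gene_b")],
    directed = FALSE, vertices = object$nodes$gene
  )
  xy <- with_seed_if(seed, igraph::layout_with_fr(g))
  lay <- tibble(
    gene = igraph::V(g)$name, x = xy[, 1], y = xy[, 2]
  ) |>
    dplyr::left_join(object$nodes, by = "gene")
  segs <- object$edges |>
    dplyr::left_join(lay[, c("gene", "x", "y")], by = c(gene_a = "gene")) |>
    dplyr::left_join(lay[, c("gene", "x", "y")], by = c(gene_b = "gene"),
                     suffix = c("", "_b"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_b, yend = .data$y_b),
      colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree,
                   colour = factor(.data$sign))
    ) +
    ggplot2::geom_text(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_colour_manual(values = c(`-1` = "#3366aa", `1` = "#aa3333"),
                                 name = "prior sign") +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Pruned consistent component")
}
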