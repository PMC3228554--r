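#' Denoise a pathway signature and estimate per-sample activity
#'
#' The full pipeline: (1) build the relevance correlation network of the
#' signature genes on the training data; (2) test the consistency of the prior
#' against the binomial randomization null; (3) prune prior-inconsistent
#' edges; (4) extract the largest connected component and estimate per-sample
#' activity over it with the degree-weighted metric (and, optionally, the
#' unweighted comparators). The network topology is learned on `expr`; when
#' `expr_test` is supplied, activity is estimated on the test samples
#' (z-scoring on the test set itself -- only the topology transfers between
#' cohorts).
#'
#' If the consistency p-value exceeds `consistency_cutoff` the prior is not
#' demonstrably relevant in this data set: a prominent warning is emitted and
#' the returned scores are flagged unreliable. If pruning leaves no edges the
#' run errors unless `fallback_unpruned = TRUE`, in which case all requested
#' methods degenerate to the unpruned average (logged in the result).
#'
#' @param expr Training expression data (wide tibble or genes x samples
#'   matrix, >= 4 samples).
#' @param signature Signature tibble (`gene`, `sign`).
#' @param expr_test Optional expression data on which to estimate activity
#'   with the component learned on `expr`.
#' @param p_threshold Edge p-value threshold (default `1e-4`).
#' @param n_rand Randomizations for the consistency p-value (default 1000).
#' @param consistency_cutoff Consistency p-value above which the prior is
#'   flagged unusable (default 0.05).
#' @param methods Estimators to compute: any of `"DART"` (degree-weighted,
#'   default), `"PR-AV"` (pruned average), `"UPR-AV"` (unpruned average).
#' @param split_updown If `TRUE`, the up- and down-regulated gene subsets are
#'   run separately and results are returned per subset (subsets with fewer
#'   than 2 genes are skipped with a message).
#' @param fallback_unpruned Degrade to UPR-AV when the pruned component is
#'   empty instead of erroring.
#' @param sd_type Z-scoring convention (see [zscore_expression()]).
#' @param seed Optional seed (consistency randomizations).
#' @return A `dart_fit` object: list with `network`, `consistency`,
#'   `component` (NULL on fallback), `activity` (tibble `sample`, `score`,
#'   `method`), `unreliable`, `fallback_used`. With `split_updown = TRUE`, a
#'   named list of `dart_fit` objects (`up`, `down`).
#' @export
run_dart <- function(expr, signature, expr_test = NULL,
                     p_threshold = 1e-4, n_rand = 1000,
                     consistency_cutoff = 0.05,
                     methods = "DART",
                     split_updown = FALSE,
                     fallback_unpruned = FALSE,
                     sd_type = c("population", "sample"),
                     seed = NULL) {
  sd_type <- rlang::arg_match(sd_type)
  methods <- match.arg(methods, c("DART", "PR-AV", "UPR-AV"), several.ok = TRUE)
  sig <- as_signature(signature)

  if (split_updown) {
    fits <- list()
    for (dir in c(up = 1L, down = -1L)) {
      sub <- dplyr::filter(sig, .data$sign == dir)
      label <- if (dir == 1L) "up" else "down"
      if (nrow(sub) < 2) {
        inform(sprintf("Skipping '%s' subset: fewer than 2 genes.", label))
        next
      }
      fits[[label]] <- run_dart(
        expr, sub, expr_test = expr_test, p_threshold = p_threshold,
        n_rand = n_rand, consistency_cutoff = consistency_cutoff,
        methods = methods, split_updown = FALSE,
        fallback_unpruned = fallback_unpruned, sd_type = sd_type, seed = seed
      )
    }
    return(fits)
  }

  net <- build_network(expr, sig, p_threshold = p_threshold)
  target <- if (is.null(expr_test)) expr else expr_test

  if (nrow(net$edges) == 0) {
    if (!fallback_unpruned) {
      abort(paste(
        "No significant edges in the relevance network;",
        "set `fallback_unpruned = TRUE` to fall back to the unpruned average."
      ))
    }
    warn("No significant edges: falling back to the unpruned average estimator.")
    act <- activity_unweighted(target, sig, method = "UPR-AV", sd_type = sd_type)
    return(new_dart_fit(net, NULL, NULL, act, unreliable = TRUE, fallback = TRUE))
  }

  cons <- consistency_pvalue(net, n_rand = n_rand, seed = seed)
  unreliable <- cons$p_value > consistency_cutoff
  if (unreliable) {
    warn(sprintf(
      paste(
        "Prior information is NOT significantly consistent with this data set",
        "(consistency p = %.3g > %.3g): returned activity scores are flagged unreliable."
      ),
      cons$p_value, consistency_cutoff
    ))
  }

  pruned <- prune_inconsistent(net)
  comp <- tryCatch(max_connected_component(pruned), error = function(e) NULL)
  if (is.null(comp)) {
    if (!fallback_unpruned) {
      abort(paste(
        "Pruning removed every edge (empty component);",
        "set `fallback_unpruned = TRUE` to fall back to the unpruned average."
      ))
    }
    warn("Empty pruned component: falling back to the unpruned average estimator.")
    act <- activity_unweighted(target, sig, method = "UPR-AV", sd_type = sd_type)
    return(new_dart_fit(net, cons, NULL, act, unreliable = TRUE, fallback = TRUE))
  }

  acts <- purrr::map(methods, function(mth) {
    switch(mth,
      "DART" = activity_weighted(target, comp, sd_type = sd_type),
      "PR-AV" = activity_unweighted(target, sig, genes = comp$nodes$gene,
                                    method = "PR-AV", sd_type = sd_type),
      "UPR-AV" = activity_unweighted(target, sig, method = "UPR-AV",
                                     sd_type = sd_type)
    )
  })
  act <- dplyr::bind_rows(acts)
  act$unreliable <- unreliable
  new_dart_fit(net, cons, comp, act, unreliable = unreliable, fallback = FALSE)
}

new_dart_fit <- function(net, cons, comp, activity, unreliable, fallback) {
  structure(
    list(
      network = net,
      consistency = cons,
      component = comp,
      activity = activity,
      unreliable = unreliable,
      fallback_used = fallback
    ),
    class = "dart_fit"
  )
}

#' @export
print.dart_fit <- function(x, ...) {
  cat("Denoised pathway activity fit\n")
  print(x$network)
  if (!is.null(x$consistency)) print(x$consistency)
  if (!is.null(x$component)) print(x$component)
  if (x$fallback_used) cat("NOTE: fell back to the unpruned average estimator.\n")
  if (x$unreliable) cat("WARNING: prior not consistent with the data; scores unreliable.\n")
  cat(sprintf(
    "Activity: %d sample(s) x %d method(s)\n",
    length(unique(x$activity$sample)), length(unique(x$activity$method))
  ))
  invisible(x)
}

#' @describeIn run_dart `tidy()` returns the per-sample activity tibble.
#' @param x A `dart_fit`.
#' @param ... Unused.
#' @export
tidy.dart_fit <- function(x, ...) x$activity

#' @describeIn run_dart `glance()` returns a one-row fit summary.
#' @export
glance.dart_fit <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$network$nodes),
    n_edges = nrow(x$network$edges),
    n_component = if (is.null(x$component)) 0L else nrow(x$component$nodes),
    fraction_consistent = if (is.null(x$consistency)) NA_real_ else x$consistency$fraction_consistent,
    consistency_p = if (is.null(x$consistency)) NA_real_ else x$consistency$p_value,
    unreliable = x$unreliable,
    fallback_used = x$fallback_used
  )
}

#' @describeIn run_dart Per-sample activity scores, one panel per estimator.
#' @param object A `dart_fit`.
#' @export
autoplot.dart_fit <- function(object, ...) {
  act <- object$activity
  act$index <- match(act$sample, unique(act$sample))
  ggplot2::ggplot(act, ggplot2::aes(x = .data$index, y = .data$score)) +
    ggplot2::geom_point(size = 0.9, colour = "#33557f") +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(x = "sample", y = "pathway activity")
}
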