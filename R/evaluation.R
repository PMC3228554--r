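#' Ground-state classification accuracy
#'
#' Given a one-dimensional mixture clustering of activity scores, the occupied
#' component with the lowest mean is the "ground state" of no pathway
#' activity. Accuracy counts inactive samples assigned to the ground state and
#' active samples assigned to any higher-level component (no level matching is
#' required among the active levels). Invariant to component relabelling.
#'
#' @param cluster A `dart_vb` object from [vb_cluster_1d()].
#' @param active Logical vector (or a `dart_sim` truth tibble with an `active`
#'   column), one entry per sample, `TRUE` when the pathway is truly active.
#' @return Accuracy in `[0, 1]`.
#' @export
ground_state_accuracy <- function(cluster, active) {
  if (is.data.frame(active)) active <- active$active
  active <- as.logical(active)
  if (length(active) != length(cluster$assignments)) {
    abort("`active` length must match the number of clustered samples.")
  }
  in_ground <- cluster$assignments == cluster$ground_state
  mean((!active & in_ground) | (active & !in_ground))
}

#' Benchmark the three estimators on synthetic data
#'
#' Repeatedly simulates a scenario, runs the unpruned average (UPR-AV), pruned
#' average (PR-AV) and degree-weighted (DART) estimators, clusters each
#' activity profile with the variational-Bayes mixture, and scores
#' ground-state accuracy against the simulation truth. Replicates where the
#' pruned component is empty fall back to the unpruned average (counted in the
#' output). Method pairs are compared by two-sided paired Wilcoxon signed-rank
#' tests across replicates.
#'
#' @param scenario `"simset1"` or `"simset2"`.
#' @param n_reps Number of simulation replicates (default 100).
#' @param seed Integer seed; replicate r uses sub-seed `seed + r`.
#' @param p_threshold Edge p-value threshold. The default `NULL` calibrates
#'   the threshold to the simulated pathway's size so that a null network
#'   carries less than one false-positive edge on average (see
#'   [fdr_calibrated_threshold()]), the same rule that yields `1e-4` at
#'   genome scale.
#' @param max_components VB mixture components (default 5).
#' @param config Simulation configuration, see [sim_config()].
#' @return A `dart_benchmark` object: `results` (tibble `rep`, `method`,
#'   `accuracy`), `summary` (per-method mean/sd), `comparisons` (pairwise
#'   Wilcoxon p-values), `n_fallback`, `scenario`.
#' @export
benchmark_simulation <- function(scenario = c("simset2", "simset1"),
                                 n_reps = 100, seed = 1,
                                 p_threshold = NULL, max_components = 5,
                                 config = sim_config()) {
  scenario <- rlang::arg_match(scenario)
  if (n_reps < 2) abort("`n_reps` must be >= 2.")
  if (is.null(p_threshold)) {
    p_threshold <- fdr_calibrated_threshold(config$n_genes)
  }
  gen <- switch(scenario, simset1 = simset1, simset2 = simset2)
  methods <- c("UPR-AV", "PR-AV", "DART")
  n_fallback <- 0L

  rows <- purrr::map(seq_len(n_reps), function(r) {
    rep_seed <- as.integer(seed + r)
    sim <- gen(seed = rep_seed, config = config)
    fit <- suppressWarnings(run_dart(
      sim$expression, sim$signature, p_threshold = p_threshold,
      n_rand = 1L,  # consistency p is not scored in this benchmark; keep it cheap
      methods = methods, fallback_unpruned = TRUE, seed = rep_seed
    ))
    if (fit$fallback_used) n_fallback <<- n_fallback + 1L
    acc <- purrr::map_dbl(methods, function(mth) {
      act <- dplyr::filter(fit$activity, .data$method == mth)
      if (nrow(act) == 0) {  # fallback: only UPR-AV exists
        act <- dplyr::filter(fit$activity, .data$method == "UPR-AV")
      }
      cl <- vb_cluster_1d(act, max_components = max_components,
                          seed = rep_seed)
      ground_state_accuracy(cl, sim$truth)
    })
    tibble(rep = r, method = methods, accuracy = acc)
  })
  results <- dplyr::bind_rows(rows)

  summary <- results |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = sd(.data$accuracy),
      .groups = "drop"
    )
  wide <- tidyr::pivot_wider(results, names_from = "method",
                             values_from = "accuracy")
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  comparisons <- purrr::map_dfr(pairs, function(pr) {
    tibble(
      method_1 = pr[1], method_2 = pr[2],
      p_value = paired_wilcoxon_p(wide[[pr[1]]], wide[[pr[2]]])
    )
  })
  structure(
    list(
      results = results, summary = summary, comparisons = comparisons,
      n_fallback = n_fallback, scenario = scenario, n_reps = n_reps,
      seed = seed
    ),
    class = "dart_benchmark"
  )
}

#' @export
print.dart_benchmark <- function(x, ...) {
  cat(sprintf("Benchmark on %s (%d replicates):\n", x$scenario, x$n_reps))
  print(as.data.frame(x$summary), row.names = FALSE)
  cat("Paired Wilcoxon comparisons:\n")
  print(as.data.frame(x$comparisons), row.names = FALSE)
  if (x$n_fallback > 0) {
    cat(sprintf("(%d replicate(s) fell back to the unpruned average)\n", x$n_fallback))
  }
  invisible(x)
}

#' @describeIn benchmark_simulation `tidy()` returns per-replicate accuracies.
#' @param x A `dart_benchmark`.
#' @param ... Unused.
#' @export
tidy.dart_benchmark <- function(x, ...) x$results

#' @describeIn benchmark_simulation `glance()` returns per-method mean/sd in
#'   one row.
#' @export
glance.dart_benchmark <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(
      names_from = "method",
      values_from = c("mean_accuracy", "sd_accuracy")
    ) |>
    dplyr::mutate(scenario = x$scenario, n_reps = x$n_reps, .before = 1)
}

#' @describeIn benchmark_simulation Boxplot of per-replicate accuracies by
#'   method.
#' @param object A `dart_benchmark`.
#' @export
autoplot.dart_benchmark <- function(object, ...) {
  res <- object$results
  res$method <- factor(res$method, levels = c("UPR-AV", "PR-AV", "DART"))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$method, y = .data$accuracy)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(
      x = NULL, y = "ground-state accuracy",
      title = sprintf("%s, %d replicates", object$scenario, object$n_reps)
    )
}

#' Correlation between two pathways' activity profiles
#'
#' Regresses one pathway's per-sample activity on another's and returns the
#' t-statistic and two-sided p-value of the slope. Overlapping genes between
#' the two pathway modules must have been excluded upstream (run each pathway
#' of a pair on the mutually exclusive gene sets) so a correlation cannot be a
#' trivial consequence of shared genes. Perfectly collinear profiles get a
#' capped t-statistic and `p_value = 0`.
#'
#' @param act_i,act_j Activity tibbles (`sample`, `score`) or numeric vectors
#'   over the same samples (tibbles are aligned by sample id).
#' @return A tibble with `t`, `p_value`, `n`.
#' @export
interpathway_correlation <- function(act_i, act_j) {
  xi <- as_score_vector(act_i, "act_i")
  xj <- as_score_vector(act_j, "act_j")
  if (!is.null(names(xi)) && !is.null(names(xj))) {
    common <- intersect(names(xi), names(xj))
    if (length(common) < length(xi) || length(common) < length(xj)) {
      inform(sprintf("Aligning on %d common sample(s).", length(common)))
    }
    xi <- xi[common]
    xj <- xj[common]
  }
  n <- length(xi)
  if (n < 4) abort("Need at least 4 samples to correlate activity profiles.")
  if (sd(xi) == 0 || sd(xj) == 0) abort("Constant activity profile.")
  tstat <- regression_t(xi, xj)
  tibble(
    t = tstat,
    p_value = if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), df = n - 2),
    n = n
  )
}

# t-statistic of the slope in the simple regression y ~ x, via the
# correlation identity t = r sqrt((n-2)/(1-r^2)); infinite for |r| = 1.
regression_t <- function(x, y) {
  n <- length(x)
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-12) return(sign(r) * Inf)
  r * sqrt((n - 2) / (1 - r^2))
}

#' Cross-cohort consistency score of an inter-pathway correlation
#'
#' A significant inter-pathway correlation found in a training cohort is a
#' hypothesis (declared when its training p-value is below 0.05). Its
#' consistency across validation cohorts is scored as
#' `V = sum_d sigma_d * |t_d| * S(p_d)` where `S(p) = 1` if `p <= 0.05` (else
#' 0) and `sigma_d = +1` when the validation t-statistic has the same sign as
#' the training one, `-1` otherwise: significance, directionality and
#' magnitude all weigh in. `V` is additive over validation sets and 0 when no
#' set passes the threshold.
#'
#' @param t_train Training-set t-statistic of the pair.
#' @param validation Tibble with one row per validation set, columns `t` and
#'   `p_value` (an empty tibble gives `V = 0`).
#' @param p_cutoff Significance threshold of `S` (default 0.05).
#' @return The consistency score `V` (a single number).
#' @export
consistency_score_V <- function(t_train, validation, p_cutoff = 0.05) {
  if (nrow(validation) == 0) return(0)
  if (!all(c("t", "p_value") %in% names(validation))) {
    abort("`validation` needs columns `t` and `p_value`.")
  }
  sigma <- ifelse(sign(validation$t) == sign(t_train), 1, -1)
  sum(sigma * abs(validation$t) * (validation$p_value <= p_cutoff))
}

#' Compare two methods' consistency scores over common hypotheses
#'
#' Two activity-estimation methods are compared by a two-tailed paired
#' Wilcoxon signed-rank test on their `V` scores over the hypothesis pairs
#' both methods declared significant in training. Identical score vectors
#' return `p = 1` by convention.
#'
#' @param v_method1,v_method2 Numeric `V`-score vectors over the same
#'   hypothesis pairs (same order).
#' @return Two-sided paired Wilcoxon p-value.
#' @export
compare_methods_V <- function(v_method1, v_method2) {
  if (length(v_method1) != length(v_method2)) {
    abort("`V` vectors must cover the same hypotheses (equal length).")
  }
  if (length(v_method1) < 2) abort("Need at least 2 common hypotheses.")
  paired_wilcoxon_p(v_method1, v_method2)
}

#' Association between pathway activity and a phenotype
#'
#' Either a one-tailed two-group t-test (binary phenotype with a stated
#' direction) or an empirical permutation test of the regression t-statistic
#' against a (possibly ordinal/continuous) covariate: sample labels of the
#' covariate are permuted `n_perm` times and the p-value is the add-one
#' fraction `(k + 1)/(n_perm + 1)` of permutations whose statistic is at least
#' as extreme as the observed one (signed per `direction`, absolute for
#' `"two_sided"`). The smallest reportable permutation p is therefore
#' `1/(n_perm + 1)`.
#'
#' @param scores Activity tibble (`sample`, `score`) or numeric vector.
#' @param covariate Per-sample phenotype: two-level factor/character for the
#'   t-test, numeric for the permutation regression.
#' @param test `"permutation"` (default) or `"t_one_tailed"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed.
#' @param direction For the permutation test: `"two_sided"` (default),
#'   `"greater"` (activity increases with the covariate) or `"less"`. For the
#'   t-test a direction must be given via `higher_group`.
#' @param higher_group For `test = "t_one_tailed"`: the covariate level
#'   expected to have the higher activity.
#' @return A tibble with `p_value`, `statistic`, `test`.
#' @export
phenotype_association <- function(scores, covariate,
                                  test = c("permutation", "t_one_tailed"),
                                  n_perm = 1000, seed = NULL,
                                  direction = c("two_sided", "greater", "less"),
                                  higher_group = NULL) {
  test <- rlang::arg_match(test)
  direction <- rlang::arg_match(direction)
  x <- as_score_vector(scores)
  if (length(covariate) != length(x)) {
    abort("`covariate` must have one value per sample.")
  }
  if (length(unique(covariate)) < 2) abort("Constant covariate.")

  if (test == "t_one_tailed") {
    g <- as.factor(covariate)
    if (nlevels(g) != 2) abort("One-tailed t-test needs a binary covariate.")
    if (is.null(higher_group) || !higher_group %in% levels(g)) {
      abort("State the expected higher-activity level via `higher_group`.")
    }
    hi <- x[g == higher_group]
    lo <- x[g != higher_group]
    tt <- t.test(hi, lo, alternative = "greater")
    return(tibble(p_value = tt$p.value, statistic = unname(tt$statistic),
                  test = "t_one_tailed"))
  }

  cov_num <- as.numeric(covariate)
  t_obs <- regression_t(cov_num, x)
  t_perm <- with_seed_if(seed, {
    perm <- replicate(n_perm, sample(cov_num))
    r <- as.vector(cor(x, perm))
    n <- length(x)
    ifelse(abs(r) >= 1 - 1e-12, sign(r) * Inf, r * sqrt((n - 2) / (1 - r^2)))
  })
  k <- switch(direction,
    two_sided = sum(abs(t_perm) >= abs(t_obs)),
    greater = sum(t_perm >= t_obs),
    less = sum(t_perm <= t_obs)
  )
  tibble(
    p_value = (k + 1) / (n_perm + 1),
    statistic = t_obs,
    test = paste0("permutation_", direction)
  )
}
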