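#' Configuration for the synthetic pathway benchmarks
#'
#' Defaults reproduce the study conditions of the two synthetic scenarios: a
#' 24-gene x 100-sample matrix in which 40 samples carry no pathway activity
#' and the remaining 60 carry three activity levels in 20-sample blocks.
#' Each "on" block shifts a gene's mean from 0 to `mu_active`; faithful
#' pathway genes have small residual noise `sigma1`, unfaithful ones `sigma2`,
#' and the non-discriminatory genes of scenario 2 are pure `N(0, noise_sd)`.
#'
#' @param n_genes Number of genes (default 24).
#' @param n_samples Number of samples (default 100).
#' @param n_inactive Leading samples with no pathway activity (default 40).
#' @param mu_active Mean shift of an "on" block (default 2).
#' @param sigma1 Residual SD of the faithful genes (default 0.25).
#' @param sigma2 Residual SD of the noisy pattern-carrying genes (default 3).
#' @param noise_sd SD of the non-discriminatory pure-noise genes in scenario 2
#'   (default 2).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 24, n_samples = 100, n_inactive = 40,
                       mu_active = 2, sigma1 = 0.25, sigma2 = 3,
                       noise_sd = 2) {
  stopifnot(
    n_genes >= 6, n_samples > n_inactive, n_inactive >= 1,
    (n_samples - n_inactive) %% 3 == 0,
    sigma1 >= 0, sigma2 >= 0, noise_sd > 0
  )
  structure(
    list(
      n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
      n_inactive = as.integer(n_inactive), mu_active = mu_active,
      sigma1 = sigma1, sigma2 = sigma2, noise_sd = noise_sd
    ),
    class = "sim_config"
  )
}

# The three on/off block patterns over samples. With the default 40 inactive
# samples and 20-sample activity blocks b1 = 41-60, b2 = 61-80, b3 = 81-100:
#   pattern 1 is on in b1, b2, b3; pattern 2 in b1 and b3; pattern 3 in b3.
# The per-sample true activity level is the number of patterns that are on:
# 0 for inactive samples, then 2, 1, 3 across the three blocks (three distinct
# non-zero levels).
block_patterns <- function(cfg) {
  s <- seq_len(cfg$n_samples)
  width <- (cfg$n_samples - cfg$n_inactive) / 3
  b <- pmax(0, ceiling((s - cfg$n_inactive) / width))  # 0 = inactive, 1..3
  rbind(
    p1 = as.numeric(b >= 1),
    p2 = as.numeric(b == 1 | b == 3),
    p3 = as.numeric(b == 3)
  )
}

# Pattern index of each gene: cycled 1,2,3,1,2,3,... so genes 1-3 and 4-6
# carry patterns 1-3 pairwise.
gene_patterns <- function(n_genes) ((seq_len(n_genes) - 1L) %% 3L) + 1L

new_dart_sim <- function(m, cfg, scenario, seed) {
  patt <- block_patterns(cfg)
  level <- as.integer(colSums(patt))
  truth <- tibble(
    sample = colnames(m),
    level = level,
    active = level > 0L
  )
  structure(
    list(
      expression = expr_as_tibble(m),
      truth = truth,
      signature = tibble(gene = rownames(m), sign = 1L),
      scenario = scenario,
      config = cfg,
      seed = seed
    ),
    class = "dart_sim"
  )
}

sim_dimnames <- function(cfg) {
  list(
    sprintf("g%02d", seq_len(cfg$n_genes)),
    sprintf("s%03d", seq_len(cfg$n_samples))
  )
}

#' Synthetic scenario 1: every gene carries the activation pattern
#'
#' All `n_genes` genes follow the block activation patterns (cycled over the
#' three patterns), but only genes 1-3 do so faithfully (residual SD
#' `sigma1 = 0.25`); genes 4 onwards carry the same block means buried in
#' large residual noise (`sigma2 = 3`). All genes are annotated up-regulated
#' in the accompanying signature.
#'
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @param config A [sim_config()].
#' @return A `dart_sim`: list with `expression` (wide tibble), `truth`
#'   (`sample`, `level` in 0..3, `active`), `signature`, `scenario`,
#'   `config`, `seed`.
#' @export
simset1 <- function(seed = NULL, config = sim_config()) {
  cfg <- config
  patt <- block_patterns(cfg)
  gp <- gene_patterns(cfg$n_genes)
  means <- cfg$mu_active * patt[gp, , drop = FALSE]
  sds <- c(rep(cfg$sigma1, 3), rep(cfg$sigma2, cfg$n_genes - 3))
  m <- with_seed_if(seed, {
    t(vapply(seq_len(cfg$n_genes), function(g) {
      means[g, ] + rnorm(cfg$n_samples, 0, sds[g])
    }, numeric(cfg$n_samples)))
  })
  dimnames(m) <- sim_dimnames(cfg)
  new_dart_sim(m, cfg, "SimSet1", seed)
}

#' Synthetic scenario 2: only six genes carry the activation pattern
#'
#' Genes 1-3 follow the block patterns faithfully (SD `sigma1`), genes 4-6
#' carry the same patterns with SD `sigma2`, and the remaining genes are
#' i.i.d. `N(0, noise_sd)` -- not discriminatory at all. This is the harder
#' scenario in which pruning irrelevant prior information matters most.
#'
#' @inheritParams simset1
#' @return A `dart_sim`, as for [simset1()].
#' @export
simset2 <- function(seed = NULL, config = sim_config()) {
  cfg <- config
  patt <- block_patterns(cfg)
  gp <- gene_patterns(cfg$n_genes)
  m <- with_seed_if(seed, {
    t(vapply(seq_len(cfg$n_genes), function(g) {
      if (g <= 3) {
        cfg$mu_active * patt[gp[g], ] + rnorm(cfg$n_samples, 0, cfg$sigma1)
      } else if (g <= 6) {
        cfg$mu_active * patt[gp[g], ] + rnorm(cfg$n_samples, 0, cfg$sigma2)
      } else {
        rnorm(cfg$n_samples, 0, cfg$noise_sd)
      }
    }, numeric(cfg$n_samples)))
  })
  dimnames(m) <- sim_dimnames(cfg)
  new_dart_sim(m, cfg, "SimSet2", seed)
}

#' @export
print.dart_sim <- function(x, ...) {
  cat(sprintf(
    "%s: %d genes x %d samples (%d inactive, %d active; seed %s)\n",
    x$scenario, x$config$n_genes, x$config$n_samples,
    sum(!x$truth$active), sum(x$truth$active),
    if (is.null(x$seed)) "none" else x$seed
  ))
  invisible(x)
}

#' @describeIn simset1 `tidy()` on a `dart_sim` returns expression in long
#'   form joined with the per-sample truth.
#' @param x A `dart_sim`.
#' @param ... Unused.
#' @export
tidy.dart_sim <- function(x, ...) {
  x$expression |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "expression") |>
    dplyr::left_join(x$truth, by = "sample")
}
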