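test_that("Fisher statistic matches the closed form and a high-precision oracle", {
  # null centre
  r0 <- fisher_statistic(0, n_s = 10)
  expect_equal(r0$y, 0)
  expect_equal(r0$p_value, 1)

  # c = 0.9, n_s = 103: y = log(19)/2, p = erfc(10 y / sqrt(2)); frozen from a
  # 30-digit arbitrary-precision evaluation
  r <- fisher_statistic(0.9, n_s = 103)
  expect_equal(r$y, 1.472219489583220, tolerance = 1e-12)
  expect_equal(r$p_value, 4.643409962358222e-49, tolerance = 1e-10)

  # antisymmetry: opposite y, equal p
  rp <- fisher_statistic(0.5, n_s = 20)
  rm <- fisher_statistic(-0.5, n_s = 20)
  expect_equal(rm$y, -rp$y)
  expect_equal(rm$p_value, rp$p_value)

  expect_error(fisher_statistic(1, n_s = 10), "collinear")
  expect_error(fisher_statistic(0.5, n_s = 3), "n_s")
})

test_that("pairwise correlations equal textbook Pearson and flag collinearity", {
  a <- c(1, 2, 3, 4)
  m <- rbind(A = a, B = c(1, 3, 2, 4), C = 2 * a + 5, D = -a)
  colnames(m) <- paste0("s", 1:4)
  expect_warning(pw <- pairwise_correlations(rbind(m, E = rep(7, 4))),
                 "zero-variance")
  expect_equal(nrow(pw), choose(4, 2))
  get <- function(x, y) pw[pw$gene_a == x & pw$gene_b == y, ]
  expect_equal(get("A", "B")$cor, 0.8)          # hand Pearson
  expect_equal(get("A", "C")$cor, 1)            # exact linear
  expect_true(get("A", "C")$collinear)
  expect_equal(get("A", "C")$p_value, 0)
  expect_equal(get("A", "D")$cor, -1)
  expect_equal(get("A", "D")$obs_sign, -1L)

  expect_error(pairwise_correlations(make_expr(m[1, , drop = FALSE])), "2")
})

test_that("edge significance is invariant under sample reordering", {
  withr::local_seed(11)
  m <- matrix(rnorm(6 * 30), 6, 30,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:30)))
  pw1 <- pairwise_correlations(m)
  pw2 <- pairwise_correlations(m[, sample(30)])
  expect_equal(pw1, pw2)
})

test_that("permutation FDR counts are deterministic and behave at the extremes", {
  withr::local_seed(3)
  m <- matrix(rnorm(8 * 20), 8, 20,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:20)))
  # threshold 1: every pair passes in every run
  all_pass <- estimate_edge_fdr(m, p_threshold = 1, n_runs = 1, seed = 5)
  expect_equal(all_pass$per_run, choose(8, 2))
  # same seed -> identical per-run counts
  f1 <- estimate_edge_fdr(m, p_threshold = 0.05, n_runs = 25, seed = 42)
  f2 <- estimate_edge_fdr(m, p_threshold = 0.05, n_runs = 25, seed = 42)
  expect_identical(f1$per_run, f2$per_run)
  expect_equal(f1$avg_false_positives, mean(f1$per_run))
})

test_that("null edge counts track pairs x threshold and the calibrated threshold", {
  withr::local_seed(7)
  m <- matrix(rnorm(25 * 60), 25, 60,
              dimnames = list(paste0("g", 1:25), paste0("s", 1:60)))
  thr <- fdr_calibrated_threshold(25, target = 1)   # = 1/300
  expect_equal(thr, 1 / choose(25, 2))
  fdr <- estimate_edge_fdr(m, p_threshold = thr, n_runs = 300, seed = 9)
  # expectation is pairs x P(p <= thr) ~ 1; allow generous Monte-Carlo slack
  expect_lt(fdr$avg_false_positives, 3)
  expect_gt(fdr$avg_false_positives, 0.1)
})

test_that("network building keeps only significant pairs and is threshold-monotone", {
  withr::local_seed(21)
  n_s <- 50
  base <- rnorm(n_s)
  m <- rbind(
    A = base,
    B = base + rnorm(n_s, 0, 0.01),  # near-duplicate of A
    C = rnorm(n_s)
  )
  colnames(m) <- paste0("s", seq_len(n_s))
  sig <- make_signature(c("A", "B", "C"))
  net <- build_network(m, sig, p_threshold = 1e-4)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(c(net$edges$gene_a, net$edges$gene_b), c("A", "B"))

  # threshold 0 keeps nothing here; loosening never removes edges
  expect_equal(nrow(build_network(m, sig, p_threshold = 0)$edges), 0)
  loose <- build_network(m, sig, p_threshold = 0.5)
  expect_true(all(net$edges$gene_a %in% loose$edges$gene_a))
  expect_gte(nrow(loose$edges), nrow(net$edges))

  # missing signature genes are named
  expect_error(build_network(m, make_signature(c("X", "Y"))), "X")
})

test_that("network is invariant to gene and signature input order", {
  withr::local_seed(33)
  m <- matrix(rnorm(5 * 40), 5, 40,
              dimnames = list(c("E", "B", "D", "A", "C"), paste0("s", 1:40)))
  sig <- make_signature(c("A", "B", "C", "D", "E"), c(1, -1, 1, -1, 1))
  n1 <- build_network(m, sig, p_threshold = 0.3)
  n2 <- build_network(m[sample(5), ], sig[sample(5), ], p_threshold = 0.3)
  expect_equal(n1$edges, n2$edges)
  expect_equal(n1$nodes, n2$nodes)
})

test_that("low-noise SimSet1 genes form a triangle and edges match a brute-force oracle", {
  sim <- simset1(seed = 101)
  thr <- fdr_calibrated_threshold(24)
  net <- build_network(sim$expression, sim$signature, p_threshold = thr)
  m <- as.matrix(sim$expression[-1])
  rownames(m) <- sim$expression$gene
  # the three faithful genes are pairwise connected
  for (pair in list(c("g01", "g02"), c("g01", "g03"), c("g02", "g03"))) {
    expect_true(any(net$edges$gene_a == pair[1] & net$edges$gene_b == pair[2]))
  }
  # every retained edge, and no omitted pair, agrees with a brute-force
  # all-pairs Pearson + Fisher oracle (checked at the conventional 1e-4 too)
  for (p_chk in c(thr, 1e-4)) {
    net_chk <- build_network(sim$expression, sim$signature, p_threshold = p_chk)
    oracle <- which(upper.tri(diag(24)), arr.ind = TRUE)
    oracle_edges <- apply(oracle, 1, function(ij) {
      cc <- cor(m[ij[1], ], m[ij[2], ])
      p <- 2 * pnorm(-abs(atanh(cc)) * sqrt(100 - 3))
      if (p <= p_chk) paste(sort(rownames(m)[ij]), collapse = "|") else NA
    })
    expect_setequal(
      paste(net_chk$edges$gene_a, net_chk$edges$gene_b, sep = "|"),
      oracle_edges[!is.na(oracle_edges)]
    )
  }
})
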