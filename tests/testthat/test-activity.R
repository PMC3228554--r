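test_that("z-scoring uses the population-SD convention and drops constant genes", {
  m <- rbind(A = c(1, 2, 3), B = c(-1.224744871391589, 0, 1.224744871391589))
  colnames(m) <- paste0("s", 1:3)
  z <- zscore_expression(m)
  expect_equal(as.numeric(z[z$gene == "A", -1]),
               c(-1.224744871391589, 0, 1.224744871391589))  # hand z-score, SD = sqrt(2/3)
  # an already-standardised row is unchanged
  expect_equal(as.numeric(z[z$gene == "B", -1]), as.numeric(m["B", ]))
  # sample-SD convention rescales by sqrt(n/(n-1))
  zs <- zscore_expression(m, sd_type = "sample")
  expect_equal(as.numeric(zs[zs$gene == "A", -1]), c(-1, 0, 1))

  expect_warning(zc <- zscore_expression(rbind(m, C = c(5, 5, 5))), "constant")
  expect_false("C" %in% zc$gene)
})

test_that("the unweighted metric averages signed z-scores", {
  withr::local_seed(2)
  n <- 20
  up <- rnorm(n)
  m <- rbind(U = up, D = -up + rnorm(n, 0, 1e-9))
  colnames(m) <- paste0("s", 1:n)
  sig <- make_signature(c("U", "D"), c(1, -1))

  # single up gene: the score is that gene's z profile
  a1 <- activity_unweighted(m, sig, genes = "U")
  zu <- as.numeric(zscore_expression(m, genes = "U")[1, -1])
  expect_equal(a1$score, zu)

  # one up and one down gene with z_down = -z_up: score equals z_up
  a2 <- activity_unweighted(m, sig)
  expect_equal(a2$score, zu, tolerance = 1e-6)

  # flipping all prior signs negates the scores
  flipped <- sig
  flipped$sign <- -flipped$sign
  a3 <- activity_unweighted(m, flipped)
  expect_equal(a3$score, -a2$score)
})

test_that("the degree-weighted metric follows the 1/sqrt(sum k^2) algebra", {
  withr::local_seed(4)
  n <- 30
  m <- matrix(rnorm(4 * n), 4, n,
              dimnames = list(c("H", "a", "b", "c"), paste0("s", 1:n)))
  sig <- make_signature(c("H", "a", "b", "c"))
  star <- toy_network(
    data.frame(gene_a = c("H", "H", "H"), gene_b = c("a", "b", "c"),
               obs_sign = 1L),
    sig
  )
  comp <- max_connected_component(star)
  aw <- activity_weighted(m, comp)
  z <- as.matrix(zscore_expression(m)[-1])
  # norm = sqrt(9 + 1 + 1 + 1) = sqrt(12); hub weight 3/sqrt(12)
  zi <- match(c("H", "a", "b", "c"), zscore_expression(m)$gene)
  manual <- (3 * z[zi[1], ] + z[zi[2], ] + z[zi[3], ] + z[zi[4], ]) / sqrt(12)
  expect_equal(aw$score, unname(manual))

  # equal degrees: weighted score = sqrt(M) x unweighted score, same ranking
  tri <- toy_network(
    data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
               obs_sign = 1L),
    sig
  )
  ctri <- max_connected_component(tri)
  aw2 <- activity_weighted(m, ctri)
  au2 <- activity_unweighted(m, sig, genes = c("a", "b", "c"), method = "PR-AV")
  expect_equal(aw2$score, sqrt(3) * au2$score)
  expect_equal(order(aw2$score), order(au2$score))

  # flipping prior signs negates the weighted scores too
  comp_f <- comp
  comp_f$nodes$sign <- -comp_f$nodes$sign
  expect_equal(activity_weighted(m, comp_f)$score, -aw$score)
})

test_that("the weighted score has unit variance for independent unit-variance genes", {
  withr::local_seed(99)
  n <- 1e4
  m <- matrix(rnorm(4 * n), 4, n,
              dimnames = list(c("H", "a", "b", "c"), paste0("s", 1:n)))
  sig <- make_signature(c("H", "a", "b", "c"))
  star <- toy_network(
    data.frame(gene_a = c("H", "H", "H"), gene_b = c("a", "b", "c"),
               obs_sign = 1L),
    sig
  )
  aw <- activity_weighted(m, max_connected_component(star))
  expect_gt(var(aw$score), 0.8)
  expect_lt(var(aw$score), 1.2)
})

test_that("scores are invariant to gene and sample input order", {
  withr::local_seed(14)
  m <- matrix(rnorm(5 * 25), 5, 25,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:25)))
  sig <- make_signature(paste0("g", 1:5), c(1, -1, 1, 1, -1))
  a1 <- activity_unweighted(m, sig)
  a2 <- activity_unweighted(m[sample(5), ], sig[sample(5), ])
  expect_equal(a1, a2)
  perm <- sample(25)
  a3 <- activity_unweighted(m[, perm], sig)
  expect_equal(a3$score[match(a1$sample, a3$sample)], a1$score)
})

test_that("the full pipeline recovers the faithful genes and transfers to test data", {
  sim <- simset2(seed = 1)
  fit <- run_dart(sim$expression, sim$signature,
                  methods = c("DART", "PR-AV", "UPR-AV"), seed = 1)
  expect_true(all(c("g01", "g02", "g03") %in% fit$component$nodes$gene))
  expect_false(fit$unreliable)

  # DART scores separate truly active from inactive samples
  dart <- dplyr::filter(fit$activity, method == "DART")
  expect_gt(
    mean(dart$score[sim$truth$active]) - mean(dart$score[!sim$truth$active]),
    1
  )

  # X_test = X_train reproduces the train-only scores
  fit2 <- run_dart(sim$expression, sim$signature, expr_test = sim$expression,
                   methods = "DART", seed = 1)
  expect_equal(dplyr::filter(fit2$activity, method == "DART")$score, dart$score)

  # a held-out draw from the same generative process gets sensible scores
  sim_test <- simset2(seed = 2)
  fit3 <- run_dart(sim$expression, sim$signature, expr_test = sim_test$expression,
                   methods = "DART", seed = 1)
  d3 <- dplyr::filter(fit3$activity, method == "DART")
  expect_gt(mean(d3$score[sim_test$truth$active]),
            mean(d3$score[!sim_test$truth$active]))
})

test_that("degenerate signatures fall back to the unpruned average when allowed", {
  withr::local_seed(6)
  m <- matrix(rnorm(3 * 30), 3, 30,
              dimnames = list(c("A", "B", "C"), paste0("s", 1:30)))
  sig <- make_signature(c("A", "B", "C"))
  # independent noise: no significant edges at the strict threshold
  expect_error(run_dart(m, sig, p_threshold = 1e-8), "fallback_unpruned")
  expect_warning(
    fit <- run_dart(m, sig, p_threshold = 1e-8, fallback_unpruned = TRUE),
    "unpruned"
  )
  expect_true(fit$fallback_used)
  expect_equal(unique(fit$activity$method), "UPR-AV")
  expect_equal(fit$activity$score,
               activity_unweighted(m, sig)$score)
})

test_that("an inconsistent prior is flagged unreliable but still scored", {
  withr::local_seed(61)
  n <- 40
  base <- rnorm(n)
  m <- rbind(A = base + rnorm(n, 0, 0.2), B = base + rnorm(n, 0, 0.2),
             C = -base + rnorm(n, 0, 0.2))
  colnames(m) <- paste0("s", 1:n)
  # prior says all up, but C anticorrelates: half the edges are inconsistent
  sig <- make_signature(c("A", "B", "C"))
  expect_warning(
    fit <- run_dart(m, sig, p_threshold = 1e-3, n_rand = 500, seed = 3),
    "NOT significantly consistent"
  )
  expect_true(fit$unreliable)
  expect_true(all(fit$activity$unreliable))
  expect_equal(nrow(fit$activity), n)
})

test_that("up/down subsets can be denoised separately", {
  sim <- simset2(seed = 9)
  sig <- sim$signature
  sig$sign[7:24] <- -1L  # pretend the noise genes are a down-module
  fits <- suppressWarnings(
    run_dart(sim$expression, sig, split_updown = TRUE,
             fallback_unpruned = TRUE, n_rand = 100, seed = 9)
  )
  expect_named(fits, c("up", "down"))
  expect_true(all(c("g01", "g02", "g03") %in% fits$up$component$nodes$gene))
})
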