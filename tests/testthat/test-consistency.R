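test_that("predicted edge signs are the product of prior signs", {
  sig <- make_signature(c("u1", "u2", "d1", "d2"), c(1, 1, -1, -1))
  expect_equal(predicted_edge_sign(sig, "u1", "u2"), 1L)
  expect_equal(predicted_edge_sign(sig, "u1", "d1"), -1L)
  expect_equal(predicted_edge_sign(sig, "d1", "d2"), 1L)
  expect_equal(predicted_edge_sign(sig, c("u1", "u2"), c("d1", "u1")), c(-1L, 1L))
  expect_error(predicted_edge_sign(sig, "u1", "zz"), "absent")
})

test_that("consistency fraction counts sign agreements", {
  sig <- make_signature(c("u1", "u2", "d1"), c(1, 1, -1))
  # observed (+, +) vs predicted (+, -): half consistent
  net <- toy_network(
    data.frame(gene_a = c("u1", "u1"), gene_b = c("u2", "d1"),
               obs_sign = c(1L, 1L)),
    sig
  )
  expect_equal(consistency_score(net)$fraction_consistent, 0.5)

  all_ok <- toy_network(
    data.frame(gene_a = c("u1", "u1"), gene_b = c("u2", "d1"),
               obs_sign = c(1L, -1L)),
    sig
  )
  expect_equal(consistency_score(all_ok)$fraction_consistent, 1)

  all_bad <- toy_network(
    data.frame(gene_a = c("u1", "u1"), gene_b = c("u2", "d1"),
               obs_sign = c(-1L, 1L)),
    sig
  )
  expect_equal(consistency_score(all_bad)$fraction_consistent, 0)

  expect_error(consistency_score(toy_network(data.frame(), sig)), "no edges")
})

test_that("negating predicted edge signs mirrors the consistency fraction", {
  sig <- make_signature(paste0("g", 1:6), c(1, 1, 1, -1, -1, 1))
  withr::local_seed(8)
  edges <- data.frame(
    gene_a = c("g1", "g1", "g2", "g3", "g4", "g5"),
    gene_b = c("g2", "g3", "g4", "g5", "g6", "g6"),
    obs_sign = sample(c(-1L, 1L), 6, replace = TRUE)
  )
  net <- toy_network(edges, sig)
  f <- consistency_score(net)$fraction_consistent
  flipped <- net
  flipped$edges$pred_sign <- -flipped$edges$pred_sign
  flipped$edges$consistent <- flipped$edges$obs_sign == flipped$edges$pred_sign
  expect_equal(consistency_score(flipped)$fraction_consistent, 1 - f)
})

test_that("Monte-Carlo consistency p agrees with the exact binomial-mixture tail", {
  # 12 edges: 8 predicted positive, 4 predicted negative; binomial prob from
  # the observed sign imbalance
  sig <- make_signature(c(paste0("u", 1:5), paste0("d", 1:3)),
                        c(rep(1, 5), rep(-1, 3)))
  edges <- data.frame(
    gene_a = c("u1", "u1", "u1", "u2", "u2", "u3", "u3", "u4",
               "u1", "u2", "u3", "u4"),
    gene_b = c("u2", "u3", "u4", "u3", "u5", "u4", "u5", "u5",
               "d1", "d1", "d2", "d3"),
    obs_sign = c(1L, 1L, 1L, 1L, -1L, 1L, 1L, -1L, -1L, -1L, 1L, -1L)
  )
  net <- toy_network(edges, sig)
  q <- mean(net$edges$obs_sign == 1L)
  k_obs <- sum(net$edges$consistent)
  n_plus <- sum(net$edges$pred_sign == 1L)
  n_minus <- sum(net$edges$pred_sign == -1L)
  p_exact <- exact_consistency_tail(n_plus, n_minus, q, k_obs)

  n_rand <- 4000
  rep <- consistency_pvalue(net, n_rand = n_rand, seed = 77)
  expect_equal(rep$binom_prob_positive, q)
  se <- sqrt(p_exact * (1 - p_exact) / n_rand)
  expect_lt(abs(rep$p_value - p_exact), 3 * se)

  # determinism and granularity
  rep2 <- consistency_pvalue(net, n_rand = n_rand, seed = 77)
  expect_identical(rep$null_scores, rep2$null_scores)
  expect_equal(rep$p_value * n_rand, round(rep$p_value * n_rand))
})

test_that("a perfectly consistent network gets a (near-)zero randomization p", {
  # 50 edges all predicted + and observed +, but null prob forced to 0.5 via
  # a half-positive sign imbalance is impossible here; instead use all_pairs
  sig <- make_signature(paste0("u", 1:51))
  edges <- data.frame(
    gene_a = paste0("u", 1:50), gene_b = paste0("u", 2:51),
    obs_sign = rep(1L, 50)
  )
  net <- toy_network(edges, sig)
  net$all_pairs <- net$edges
  net$all_pairs$obs_sign <- rep(c(1L, -1L), 25)  # q estimated as 0.5
  rep <- consistency_pvalue(net, n_rand = 1000, seed = 5, prob_from = "all_pairs")
  expect_equal(rep$binom_prob_positive, 0.5)
  expect_equal(rep$fraction_consistent, 1)
  expect_equal(rep$p_value, 0)  # true tail 2^-50, below the 1/1000 resolution
  # add-one smoothing avoids exact zero
  rep_s <- consistency_pvalue(net, n_rand = 1000, seed = 5,
                              prob_from = "all_pairs", smooth = TRUE)
  expect_equal(rep_s$p_value, 1 / 1001)
})

test_that("an exactly null-level consistency score sits near the middle of the null", {
  # 10 edges predicted +, q = 0.5: null count ~ Bin(10, 0.5); observed 5
  sig <- make_signature(paste0("u", 1:11))
  edges <- data.frame(
    gene_a = paste0("u", 1:10), gene_b = paste0("u", 2:11),
    obs_sign = rep(c(1L, -1L), 5)
  )
  net <- toy_network(edges, sig)
  p_exact <- exact_consistency_tail(10, 0, 0.5, 5)   # P(Bin(10,.5) > 5)
  expect_equal(p_exact, pbinom(5, 10, 0.5, lower.tail = FALSE))
  rep <- consistency_pvalue(net, n_rand = 4000, seed = 13)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(rep$p_value - p_exact), 3 * se)
})
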