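test_that("adjusted alpha pins the true class to 1", {
  expect_equal(adjusted_alpha(c(5, 3), c(1, 0))$alpha, c(1, 3))
  expect_equal(adjusted_alpha(c(5, 3), c(0, 1))$alpha, c(5, 1))
  expect_equal(adjusted_alpha(c(1, 1), c(1, 0))$alpha, c(1, 1))
  expect_error(adjusted_alpha(c(2, 2), c(1, 1)), "one-hot")
})

test_that("waCE matches the digamma closed form on worked cases", {
  expect_equal(wace_loss(c(1, 1), c(1, 0), c(1, 1)), 1.0)
  expect_equal(wace_loss(c(9, 1), c(1, 0), c(1, 1)), 1 / 9)
  expect_equal(wace_loss(c(1, 1), c(1, 0), c(2, 1)), 2.0)
  # strictly decreasing in true-class evidence, wrong class fixed
  vals <- vapply(c(1, 2, 4, 8), function(e)
    wace_loss(c(e + 1, 3), c(1, 0), 1), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("waCE equals the Dirichlet Monte-Carlo expectation", {
  set.seed(42)
  for (rep in 1:8) {
    K <- sample(2:4, 1)
    alpha <- stats::runif(K, 1, 8)
    y <- numeric(K); y[sample(K, 1)] <- 1
    w <- stats::runif(K, 0.5, 3)
    mc <- mc_wace(alpha, y, w, 100000L)
    expect_lt(abs(wace_loss(alpha, y, w) - mc["mean"]), 3 * mc["se"])
  }
})

test_that("KL to the uniform Dirichlet is exact and well behaved", {
  expect_equal(kl_to_uniform(rep(1, 4)), 0)
  expect_equal(kl_to_uniform(c(2, 1)), log(2) - 0.5, tolerance = 1e-9)
  vals <- vapply(c(1, 2, 4, 8), function(t) kl_to_uniform(c(t, 1)), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(kl_to_uniform(c(0.5, 1)), ">= 1")

  set.seed(9)
  for (rep in 1:8) {
    a <- stats::runif(2, 1, 10)
    expect_equal(kl_to_uniform(a), numeric_kl_beta(a), tolerance = 1e-6)
  }
})

test_that("head loss composes waCE and the KL regularizer", {
  a <- c(3, 2); y <- c(0, 1); w <- c(1, 2)
  expect_equal(head_loss(a, y, w, kl_weight = 0), wace_loss(a, y, w))
  expect_equal(head_loss(c(1, 1), c(1, 0), c(1, 1), kl_weight = 1), 1.0)
  # decreasing in true-class evidence
  vals <- vapply(c(0, 1, 3, 7), function(e)
    head_loss(c(2, e + 1), y, w, 1), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("analytic loss gradients match finite differences", {
  set.seed(5)
  for (rep in 1:20) {
    K <- sample(2:4, 1)
    alpha <- stats::runif(K, 1.05, 8)
    y <- numeric(K); y[sample(K, 1)] <- 1
    w <- stats::runif(K, 0.5, 3)
    g <- mmfe:::head_loss_grad(alpha, y, w, 1)
    for (j in seq_len(K)) {
      e <- numeric(K); e[j] <- 1e-6
      fd <- (head_loss(alpha + e, y, w, 1) - head_loss(alpha - e, y, w, 1)) /
        2e-6
      expect_equal(g[j], fd, tolerance = 1e-4)
    }
    # d wace / d e_true < 0; d KL / d alpha_wrong > 0 (binary case — with
    # several wrong classes the KL is not coordinatewise monotone)
    expect_lt(mmfe:::wace_grad(alpha, y, w)[which(y == 1)], 0)
    if (K == 2L) {
      at <- y + alpha * (1 - y)
      wrong <- which(y == 0 & at > 1)
      expect_true(all(mmfe:::kl_grad(at)[wrong] > 0))
    }
  }
})

test_that("stage-1 loss sums the N + 2 heads and masks missing ones", {
  a <- c(2, 3); y <- c(1, 0); w <- c(1, 1)
  alphas <- list(mod1 = a, mod2 = a, FI = a, DI = a)
  lb <- stage1_loss(alphas, y, w, kl_weight = 1)
  expect_length(lb$per_head, 4)
  expect_equal(lb$total, 4 * head_loss(a, y, w, 1))
  expect_equal(lb$total, sum(lb$per_head))

  masked <- stage1_loss(alphas, y, w, 1, missing = "mod2")
  expect_equal(masked$per_head[["mod2"]], 0)
  expect_equal(masked$total, 3 * head_loss(a, y, w, 1))
  expect_error(stage1_loss(list(mod1 = a), y, w), "FI")
})

test_that("match loss is zero at equality and penalizes misalignment", {
  set.seed(3)
  f <- array(rnorm(2 * 2 * 2 * 4), c(2, 2, 2, 4))
  expect_equal(match_loss(f, f), 0)
  # cosine term is scale invariant; MSE picks up the difference
  expect_equal(match_loss(2 * f, f, lambda_cs = 5), mean(f^2))
  # orthogonal vectors: cosine contribution is exactly lambda_cs
  v1 <- c(1, 0, 0, 0); v2 <- c(0, 1, 0, 0)
  expect_equal(match_loss(v1, v2, lambda_cs = 5), mean((v1 - v2)^2) + 5)
  expect_error(match_loss(matrix(1, 2, 2), matrix(1, 3, 3)), "differ")
  expect_message(match_loss(c(0, 0), c(1, 0)), "zero-norm")
})

test_that("match-loss gradients match finite differences", {
  set.seed(13)
  f_ref <- array(rnorm(16), c(2, 2, 2, 2))
  f_syn <- array(rnorm(16), c(2, 2, 2, 2))
  g <- mmfe:::match_loss_impl(f_syn, f_ref, 5, grad = TRUE)$grad
  for (j in sample(16, 5)) {
    e <- array(0, dim(f_syn)); e[j] <- 1e-6
    fd <- (match_loss(f_syn + e, f_ref, 5) - match_loss(f_syn - e, f_ref, 5)) /
      2e-6
    expect_equal(as.numeric(g)[j], fd, tolerance = 1e-5)
  }
})

test_that("stage-2 loss adds weighted mean match terms to stage 1", {
  a <- c(2, 3); y <- c(1, 0)
  s1 <- stage1_loss(list(mod1 = a, mod2 = a, FI = a, DI = a), y, c(1, 1), 1)
  set.seed(8)
  f1 <- array(rnorm(16), c(2, 2, 2, 2)); f2 <- array(rnorm(16), c(2, 2, 2, 2))
  pairs_eq <- list(list(syn = f1, ref = f1))
  pairs_ne <- list(list(syn = f1, ref = f2))

  zero_w <- match_weights(lambda_b = 0, lambda_h = 0)
  expect_equal(stage2_loss(s1, list(), list(), zero_w)$total, s1$total)
  expect_equal(stage2_loss(s1, pairs_eq, pairs_eq)$total, s1$total)

  w1 <- match_weights(lambda_b = 0.5, lambda_h = 0)
  w2 <- match_weights(lambda_b = 1.0, lambda_h = 0)
  d1 <- stage2_loss(s1, pairs_ne, list(), w1)$total - s1$total
  d2 <- stage2_loss(s1, pairs_ne, list(), w2)$total - s1$total
  expect_equal(d2, 2 * d1)
  expect_error(stage2_loss(s1, list(), pairs_ne,
                           match_weights(lambda_b = 1)), "backbone")
})

test_that("class weights follow the negative/positive ratio", {
  expect_equal(class_weights_from_labels(c(rep(0, 60), rep(1, 40))), c(1, 1.5))
  expect_equal(class_weights_from_labels(c(rep(0, 10), rep(1, 10))), c(1, 1))
  expect_equal(class_weights_from_labels(c(rep(0, 90), rep(1, 10))), c(1, 9))
  expect_error(class_weights_from_labels(rep(1, 5)), "both classes")
})
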