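test_that("metrics match hand-computed values", {
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$acc, 1)
  expect_equal(m$f1, 1)

  m <- compute_metrics(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 0.75)   # 3 of 4 concordant pairs

  m <- compute_metrics(rep(0.3, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(m$auc, 0.5)    # all pairs tied

  expect_warning(m1 <- compute_metrics(c(0.2, 0.8), c(1, 1)), "one class")
  expect_true(is.na(m1$auc))
  expect_false(is.na(m1$acc))
})

test_that("AUC equals the normalized Mann-Whitney statistic", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n, mean = labels), 1)  # induce ties
    w <- suppressWarnings(stats::wilcox.test(
      scores[labels == 1], scores[labels == 0]))
    u_norm <- w$statistic / (sum(labels == 1) * sum(labels == 0))
    expect_equal(mmfe:::auc_stat(scores, labels), unname(u_norm),
                 tolerance = 1e-12)
  }
})

test_that("uncertainty report reproduces the hand case", {
  # correct: u = 0.1, 0.2; incorrect: u = 0.9, 0.8
  preds <- c(1, 0, 1, 0); labels <- c(1, 0, 0, 1)
  u <- c(0.1, 0.2, 0.9, 0.8)
  rep_ <- uncertainty_report(preds, labels, u)
  bc <- rep_$by_category
  expect_equal(bc$n[bc$category == "TP"], 1)
  expect_equal(bc$mean_u[bc$category == "TP"], 0.1)
  expect_equal(bc$mean_u[bc$category == "FP"], 0.9)
  expect_equal(sum(bc$coverage), 1)

  # normalized u = (0, 0.125, 1, 0.875); at threshold 0.125: ACC 1, cov 0.5
  row <- rep_$curve[abs(rep_$curve$threshold - 0.125) < 1e-12, ]
  expect_equal(row$acc, 1)
  expect_equal(row$coverage, 0.5)
  # coverage reaches 1 at the top threshold; ACC there is the overall ACC
  last <- rep_$curve[nrow(rep_$curve), ]
  expect_equal(last$coverage, 1)
  expect_equal(last$acc, 0.5)
  expect_true(all(diff(rep_$curve$coverage) >= 0))

  # all-correct: empty FP/FN, p-value absent
  rep2 <- uncertainty_report(c(1, 0), c(1, 0), c(0.2, 0.3))
  expect_true(is.na(rep2$by_category$mean_u[3]))
  expect_true(is.na(rep2$p_correct_vs_incorrect))
})

test_that("feature similarity matches hand computations", {
  set.seed(31)
  f <- list(backbone = array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3)),
            fc1 = rnorm(5), fc2 = rnorm(2))
  sim <- feature_similarity(f, f)
  expect_equal(sim$channels$cs, rep(1, 3))
  expect_equal(sim$channels$kld, rep(0, 3), tolerance = 1e-12)
  expect_equal(sim$fc$cs, c(1, 1))

  f_neg <- list(backbone = -f$backbone, fc1 = -f$fc1, fc2 = -f$fc2)
  sim <- feature_similarity(f_neg, f)
  expect_equal(sim$channels$cs, rep(-1, 3))

  # hand KLD on a 2-element distribution pair (natural log)
  expect_equal(mmfe:::feature_kld(syn = c(0.8, 0.2), ref = c(0.5, 0.5)),
               0.5 * log(0.5 / 0.8) + 0.5 * log(0.5 / 0.2),
               tolerance = 1e-4)
})

test_that("saliency is the head gradient: proportional to linear weights", {
  set.seed(41)
  model <- build_model("a", rep(16, 3), spec = tiny_backbone(),
                       hidden = 2, seed = 41)
  # make the head linear-positive: fc1_pre > 0 ensured by a large bias, W2
  # identity -> d evidence_k / d flat = sigmoid(fc2_k) * W1[k, ]
  nfeat <- model$heads$a$in_features
  model$heads$a$W1 <- matrix(abs(rnorm(2 * nfeat, sd = 0.01)), 2, nfeat)
  model$heads$a$b1 <- c(10, 10)
  model$heads$a$W2 <- diag(2)
  vols <- list(a = array(abs(rnorm(16^3)), rep(16, 3)))
  sm <- saliency_map(model, vols, stage = "S1", target = "true", label = 0)
  sal <- as.numeric(sm$a$channels)
  expect_equal(sal / max(sal),
               as.numeric(model$heads$a$W1[1, ]) /
                 max(model$heads$a$W1[1, ]),
               tolerance = 1e-9)

  # zero output head -> all-zero saliency; identical calls identical output
  model$heads$a$W1[] <- 0
  sm0 <- saliency_map(model, vols, stage = "S1", target = "true", label = 0)
  expect_true(all(sm0$a$channels == 0))
  sm0b <- saliency_map(model, vols, stage = "S1", target = "true", label = 0)
  expect_identical(sm0$a$channels, sm0b$a$channels)
})

test_that("saliency correlation recovers identity and permutations", {
  set.seed(51)
  sms <- lapply(1:4, function(i) array(rnorm(3 * 3 * 3 * 5), c(3, 3, 3, 5)))
  sc <- saliency_correlation(sms, sms)
  expect_equal(diag(sc$matrix), rep(1, 5))
  expect_equal(sc$diagonal$mean, rep(1, 5))

  perm <- c(3, 1, 2, 5, 4)
  sms_p <- lapply(sms, function(a) a[, , , perm])
  sc <- saliency_correlation(sms, sms_p)
  for (i in 1:5) {
    expect_equal(sc$matrix[perm[i], i], 1, tolerance = 1e-12)
  }

  # independent maps: diagonal mean near zero (3 SE over subjects x channels)
  sms_a <- lapply(1:30, function(i) array(rnorm(4^3 * 4), c(4, 4, 4, 4)))
  sms_b <- lapply(1:30, function(i) array(rnorm(4^3 * 4), c(4, 4, 4, 4)))
  sc <- saliency_correlation(sms_a, sms_b)
  d <- sc$diagonal$mean
  expect_lt(abs(mean(d)), 3 / sqrt(30 * 4 * (4^3 - 1)))
})
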