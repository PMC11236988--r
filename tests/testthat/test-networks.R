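test_that("backbone shape algebra follows the stride product", {
  spec <- backbone_spec()   # cnn5 defaults: strides 1,2,2,2,2
  expect_equal(mmfe:::backbone_out_shape(spec, c(112, 128, 112)), c(7, 8, 7))
  expect_equal(mmfe:::backbone_out_shape(spec, c(32, 32, 32)), c(2, 2, 2))
  # odd dims: padding-1 stride-2 convs use floor division
  expect_equal(mmfe:::backbone_out_shape(spec, c(33, 33, 33)), c(3, 3, 3))

  # actual forward agrees with the algebra
  set.seed(1)
  bb <- build_backbone(tiny_backbone())          # strides 1,2,2 -> /4
  x <- array(rnorm(16^3), rep(16, 3))
  out <- mmfe:::backbone_fwd(bb, x)$feat
  expect_equal(dim(out), c(4, 4, 4, 4))
})

test_that("the convolution kernel matches a brute-force oracle", {
  set.seed(99)
  for (stride in c(1L, 2L)) {
    D <- 5L; H <- 6L; W <- 4L; Cin <- 2L; Cout <- 3L
    x <- array(rnorm(D * H * W * Cin), c(D, H, W, Cin))
    Wm <- matrix(rnorm(Cout * Cin * 27), Cout, Cin * 27)
    b <- rnorm(Cout)
    y <- mmfe:::conv3d_forward(x, Wm, b, stride)$y
    od <- function(n) (n - 1L) %/% stride + 1L
    ref <- array(0, c(od(D), od(H), od(W), Cout))
    for (co in 1:Cout) for (ow in 1:od(W)) for (oh in 1:od(H))
      for (odd in 1:od(D)) {
        acc <- b[co]
        for (ci in 1:Cin) for (kw in 0:2) for (kh in 0:2) for (kd in 0:2) {
          id <- (odd - 1L) * stride + kd  # pad 1: input index offset -1
          ih <- (oh - 1L) * stride + kh
          iw <- (ow - 1L) * stride + kw
          if (id >= 1 && id <= D && ih >= 1 && ih <= H &&
              iw >= 1 && iw <= W) {
            r <- (ci - 1L) * 27L + kd + 3L * (kh + 3L * kw) + 1L
            acc <- acc + Wm[co, r] * x[id, ih, iw, ci]
          }
        }
        ref[odd, oh, ow, co] <- acc
      }
    expect_equal(y, ref, tolerance = 1e-12)
  }
})

test_that("heads emit non-negative evidence of length K", {
  set.seed(2)
  h <- build_head(in_features = 128, hidden = 64, K = 2)
  x <- rnorm(128)
  fc1 <- mmfe:::lrelu_fwd(mmfe:::fc_fwd(x, h$W1, h$b1))
  expect_length(fc1, 64)
  ev <- mmfe:::softplus(mmfe:::fc_fwd(fc1, h$W2, h$b2))
  expect_length(ev, 2)
  expect_true(all(ev >= 0))
  # zero input: evidence = softplus(bias), finite and non-negative
  ev0 <- mmfe:::softplus(mmfe:::fc_fwd(
    mmfe:::lrelu_fwd(mmfe:::fc_fwd(numeric(128), h$W1, h$b1)), h$W2, h$b2))
  expect_true(all(is.finite(ev0) & ev0 >= 0))
})

test_that("FI branch concatenates FC1 outputs in modality order", {
  set.seed(3)
  fi <- build_fi_branch(N = 3, hidden = 64, K = 2)
  expect_equal(ncol(fi$W), 192)
  fi1 <- build_fi_branch(N = 1, hidden = 16, K = 2)
  expect_equal(ncol(fi1$W), 16)
})

test_that("cascaded convolutions add parameters, evidence stays non-negative", {
  set.seed(4)
  plain <- build_backbone(tiny_backbone(FALSE))
  casc <- build_backbone(tiny_backbone(TRUE))
  n_par <- function(bb) sum(vapply(rapply(bb$layers, length, how = "unlist"),
                                   sum, numeric(1))) + length(bb$squeeze$W)
  expect_gt(n_par(casc), n_par(plain))

  # evidence non-negativity for arbitrary (even wild) weights
  model <- build_model(c("a", "b"), rep(16, 3), spec = tiny_backbone(),
                       hidden = 4, seed = 5)
  model$heads$a$W2 <- model$heads$a$W2 * 50
  vols <- list(a = array(rnorm(16^3), rep(16, 3)),
               b = array(rnorm(16^3), rep(16, 3)))
  outs <- model_forward(model, vols, stage = "S1")
  expect_true(all(unlist(outs$evidence) >= 0))
  expect_true(all(outs$fi_evidence >= 0))
})

test_that("forward pass honors stage and missing-modality contracts", {
  set.seed(6)
  model <- build_model(c("a", "b", "c"), rep(16, 3), spec = tiny_backbone(),
                       hidden = 4, acquired = "a", seed = 6)
  vols <- lapply(stats::setNames(1:3, c("a", "b", "c")), function(i)
    array(rnorm(16^3), rep(16, 3)))

  # S2 needs only the acquired volume and still produces all branches
  o2 <- model_forward(model, vols["a"], stage = "S2")
  expect_setequal(names(o2$evidence), c("a", "b", "c"))
  expect_true("FI" %in% names(o2$alphas) && "DI" %in% names(o2$alphas))
  expect_error(model_forward(model, vols["b"], stage = "S2"), "acquired")

  # S1 with a missing modality: that branch is absent and excluded from fusion
  o1 <- model_forward(model, vols, stage = "S1", missing = "b")
  expect_false("b" %in% names(o1$evidence))
  expect_setequal(o1$fuse_names, c("a", "c", "FI"))
  expect_error(model_forward(model, vols["a"], stage = "S1"),
               "missing required volume")

  # determinism: identical weights + inputs give identical outputs
  o1b <- model_forward(model, vols, stage = "S1", missing = "b")
  expect_identical(o1$alphas, o1b$alphas)

  # the fused opinion satisfies the simplex constraint and labels argmax
  fused <- o1$fused
  expect_lt(abs(sum(fused$combined$beliefs) + fused$combined$uncertainty - 1),
            1e-9)
  expect_identical(fused$label,
                   which.max(fused$combined$beliefs) - 1L)
})

test_that("a one-voxel perturbation stays within the receptive field", {
  set.seed(7)
  bb <- build_backbone(backbone_spec(channels = 4L, strides = 1L,
                                     squeeze_channels = 2L))
  x <- array(rnorm(8^3), rep(8, 3))
  y0 <- mmfe:::backbone_fwd(bb, x)$feat
  x2 <- x
  x2[1, 1, 1] <- x2[1, 1, 1] + 10
  y1 <- mmfe:::backbone_fwd(bb, x2)$feat
  changed <- which(apply(abs(y1 - y0) > 1e-9, 1:3, any), arr.ind = TRUE)
  # single 3x3x3 layer + instance norm: the norm couples all voxels of a
  # channel through its statistics, but the dominant change is local
  expect_true(all(abs(y1 - y0)[3:8, 3:8, 3:8, ] <
                    max(abs(y1 - y0)[1:2, 1:2, 1:2, ])))
})

test_that("model construction rejects impossible geometry", {
  expect_error(build_model("a", c(0, 16, 16)), "non-positive")
  expect_error(build_model("a", c(4, 4, 4), spec = backbone_spec()),
               NA)  # 4^3 still yields a positive map under floor division
})
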