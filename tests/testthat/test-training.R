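test_that("fold assignment is balanced, reproducible and reused", {
  f <- assign_folds(100, k = 5, seed = 1)
  expect_equal(unname(table(f)), rep(20L, 5), ignore_attr = TRUE)
  expect_identical(f, assign_folds(100, k = 5, seed = 1))
  expect_false(identical(f, assign_folds(100, k = 5, seed = 2)))

  f2 <- assign_folds(101, k = 5, seed = 3)
  expect_lte(diff(range(table(f2))), 1)
  expect_error(assign_folds(4, k = 5), "folds")

  coh <- tiny_cohort(n = 8)
  expect_true(all(vapply(coh, `[[`, integer(1), "fold") %in% 0:3))
})

test_that("stage-1 training is seeded, structured, and masks missing branches", {
  coh <- tiny_cohort(n = 16, noise_sd = 2)
  cfg <- tiny_train_config("S1", epochs = 2, seed = 3)
  ck <- train_stage1(coh, cfg)
  expect_s3_class(ck, "mmfe_checkpoint")
  expect_setequal(names(ck$model$branches), c("mod1", "mod2"))
  expect_setequal(names(ck$model$heads), c("mod1", "mod2"))
  expect_equal(nrow(ck$history), 2)

  # identical seeds -> identical selected weights (full determinism)
  ck2 <- train_stage1(coh, cfg)
  expect_identical(hash_weight_groups(ck$model), hash_weight_groups(ck2$model))

  # modality 2 missing for every subject -> its branch is never updated
  coh_miss <- coh
  for (i in seq_along(coh_miss)) {
    coh_miss[[i]]$missing <- "mod2"
    coh_miss[[i]]$volumes$mod2 <- NULL
  }
  ck3 <- train_stage1(coh_miss, cfg)
  init <- with(list(), {
    # rebuild the seed-identical initial model
    shp <- dim(coh[[1]]$volumes$mod1)
    mmfe:::with_seed(cfg$seed, build_model(
      c("mod1", "mod2"), shp, spec = cfg$backbone, hidden = cfg$hidden,
      acquired = "mod1", seed = cfg$seed))
  })
  expect_identical(hash_weight_groups(ck3$final_model)[["backbone:mod2"]],
                   hash_weight_groups(init)[["backbone:mod2"]])
  expect_false(identical(hash_weight_groups(ck3$final_model)[["backbone:mod1"]],
                         hash_weight_groups(init)[["backbone:mod1"]]))

  # a single-class training fold is a domain error
  coh_one <- coh
  for (i in seq_along(coh_one)) coh_one[[i]]$label <- 1
  expect_error(train_stage1(coh_one, cfg), "single class")
})

test_that("the stage-2 freeze plan covers exactly the synthesized backbones", {
  coh <- tiny_cohort(n = 16, n_modalities = 3, effects = c(0.5, 1, 1))
  cfg <- tiny_train_config("S1", epochs = 2)
  ck1 <- train_stage1(coh, cfg)
  cfg2 <- tiny_train_config("S2", epochs = 2)
  plan <- plan_stage2_freeze(ck1, cfg2)
  expect_setequal(plan$trainable, c("backbone:mod2", "backbone:mod3"))
  expect_setequal(plan$frozen,
                  c("backbone:mod1", "head:mod1", "head:mod2", "head:mod3",
                    "fi"))
  expect_length(intersect(plan$trainable, plan$frozen), 0)

  bad <- tiny_train_config("S2", epochs = 2, modalities = c("mod1", "modX"))
  expect_error(plan_stage2_freeze(ck1, bad), "do not match")
})

test_that("stage 2 trains only the plan's groups and schedules head losses", {
  coh <- tiny_cohort(n = 16, noise_sd = 2)
  ck1 <- train_stage1(coh, tiny_train_config("S1", epochs = 2))
  cfg2 <- tiny_train_config("S2", epochs = 4, seed = 9)
  ck2 <- train_stage2(coh, cfg2, ck1)
  plan <- ck2$freeze_plan

  h1 <- hash_weight_groups(ck1$model)
  h2 <- hash_weight_groups(ck2$final_model)
  for (g in plan$frozen) expect_identical(h2[[g]], h1[[g]])
  for (g in plan$trainable) expect_false(identical(h2[[g]], h1[[g]]))

  # first half epochs: synthesized heads only; then all heads incl. FI/DI
  expect_identical(ck2$history$heads[1:2], rep("mod2", 2))
  expect_identical(ck2$history$heads[3:4],
                   rep("mod1,mod2,FI,DI", 2))

  # the alignment trace includes a pre-training entry
  expect_length(ck2$backbone_cs, 5)

  # inference needs only the acquired modality
  r <- infer(ck2, coh[[1]]$volumes$mod1)
  expect_true(r$label %in% c(0L, 1L))
  expect_true(r$uncertainty > 0 && r$uncertainty <= 1)
  r2 <- infer(ck2, coh[[1]]$volumes$mod1)
  expect_identical(r$score, r2$score)

  # teachers need the real auxiliary volumes
  coh_miss <- coh
  coh_miss[[3]]$missing <- "mod2"
  expect_error(train_stage2(coh_miss, cfg2, ck1), "missing")
})

test_that("with a single modality stage 2 has no trainable groups", {
  coh <- tiny_cohort(n = 16, n_modalities = 1, effects = 1)
  cfg1 <- tiny_train_config("S1", epochs = 2, modalities = "mod1")
  ck1 <- train_stage1(coh, cfg1)
  cfg2 <- tiny_train_config("S2", epochs = 4, modalities = "mod1",
                            match_weights = match_weights(0, 0, 0))
  ck2 <- train_stage2(coh, cfg2, ck1)
  expect_length(ck2$freeze_plan$trainable, 0)
  expect_identical(hash_weight_groups(ck2$final_model),
                   hash_weight_groups(ck1$model))
  # loss is constant once the schedule stabilizes (no trainable parameters)
  expect_equal(ck2$history$train_loss[3], ck2$history$train_loss[4],
               tolerance = 1e-9)
})

test_that("checkpoints round trip through disk", {
  coh <- tiny_cohort(n = 16)
  ck <- train_stage1(coh, tiny_train_config("S1", epochs = 2))
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, p)
  ck2 <- load_checkpoint(p)
  expect_identical(hash_weight_groups(ck$model), hash_weight_groups(ck2$model))
  expect_identical(ck$config_hash, ck2$config_hash)
  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), junk)
  expect_error(load_checkpoint(junk), "not an mmfe checkpoint")
})

test_that("vacuous evidence yields maximal symmetric uncertainty", {
  set.seed(8)
  model <- build_model("mod1", rep(16, 3), spec = tiny_backbone(),
                       hidden = 4, seed = 8)
  # zero final FC weights: evidence = softplus(0) = log 2 for both classes
  model$heads$mod1$W2[] <- 0
  model$heads$mod1$b2[] <- 0
  model$fi$W[] <- 0
  model$fi$b[] <- 0
  r <- infer(model, array(rnorm(16^3), rep(16, 3)))
  a <- log(2) + 1
  op <- evidence_to_opinion(dirichlet_evidence(rep(log(2), 2)))
  expected_u <- mmfe:::ds_pair_num(op$beliefs, op$uncertainty,
                                   op$beliefs, op$uncertainty)$u
  expect_equal(r$uncertainty, expected_u, tolerance = 1e-9)
  expect_identical(r$label, 0L)   # symmetric beliefs tie-break to class 0
})
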