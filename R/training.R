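# ---- parameter-tree utilities ----------------------------------------------
# Gradient trees produced by model_backward mirror the parameter tree but
# contain only numeric leaves; these helpers walk the two in lockstep.

layer_param_template <- function(layer) {
  switch(layer$type,
    conv3 = ,
    conv1 = list(W = zero_like(layer$W), b = zero_like(layer$b)),
    "in" = list(gamma = zero_like(layer$gamma), beta = zero_like(layer$beta)),
    lrelu = NULL,
    res = list(conv1 = layer_param_template(layer$conv1),
               in1 = layer_param_template(layer$in1),
               conv2 = layer_param_template(layer$conv2),
               in2 = layer_param_template(layer$in2),
               proj = if (is.null(layer$proj)) NULL
                      else layer_param_template(layer$proj)),
    stop("unknown layer type")
  )
}

backbone_param_template <- function(bb) {
  list(squeeze = list(W = zero_like(bb$squeeze$W), b = zero_like(bb$squeeze$b)),
       layers = lapply(bb$layers, layer_param_template))
}

grads_template <- function(model) {
  list(
    branches = lapply(model$branches, backbone_param_template),
    heads = lapply(model$heads, function(h)
      list(W1 = zero_like(h$W1), b1 = zero_like(h$b1),
           W2 = zero_like(h$W2), b2 = zero_like(h$b2))),
    fi = list(W = zero_like(model$fi$W), b = zero_like(model$fi$b))
  )
}

tree_add <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.numeric(b)) return(a + b)
  nms <- names(b)
  if (is.null(nms)) {
    for (i in seq_along(b)) {
      if (!is.null(b[[i]])) a[i] <- list(tree_add(a[[i]], b[[i]]))
    }
  } else {
    for (nm in nms) {
      if (!is.null(b[[nm]])) a[nm] <- list(tree_add(a[[nm]], b[[nm]]))
    }
  }
  a
}

tree_scale <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(a * s)
  lapply(a, tree_scale, s = s)
}

# One Adam step on the numeric leaves named in `grads`; `state` holds (m, v)
# trees of the same shape.  Returns list(params, state).
adam_step <- function(params, grads, state, lr, t, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(grads)) return(list(params = params, state = state))
  if (is.numeric(grads)) {
    m <- beta1 * state$m + (1 - beta1) * grads
    v <- beta2 * state$v + (1 - beta2) * grads^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    # decoupled weight decay (AdamW-style)
    return(list(params = params - lr * (mhat / (sqrt(vhat) + eps) +
                                          weight_decay * params),
                state = list(m = m, v = v)))
  }
  nms <- names(grads)
  idx <- if (is.null(nms)) seq_along(grads) else nms
  for (i in idx) {
    if (is.null(grads[[i]])) next
    r <- adam_step(params[[i]], grads[[i]], state[[i]], lr, t, weight_decay,
                   beta1, beta2, eps)
    params[[i]] <- r$params
    state[[i]] <- r$state
  }
  list(params = params, state = state)
}

adam_state_init <- function(template) {
  if (is.null(template)) return(NULL)
  if (is.numeric(template)) {
    return(list(m = zero_like(template), v = zero_like(template)))
  }
  lapply(template, adam_state_init)
}

# Named weight groups: the freezing contract operates on these.
weight_group_names <- function(model) {
  c(paste0("backbone:", model$modalities),
    paste0("head:", model$modalities), "fi")
}

group_ref <- function(tree, group) {
  parts <- strsplit(group, ":", fixed = TRUE)[[1]]
  if (parts[1] == "fi") tree$fi
  else if (parts[1] == "backbone") tree$branches[[parts[2]]]
  else tree$heads[[parts[2]]]
}

group_assign <- function(tree, group, value) {
  parts <- strsplit(group, ":", fixed = TRUE)[[1]]
  if (parts[1] == "fi") tree$fi <- value
  else if (parts[1] == "backbone") tree$branches[[parts[2]]] <- value
  else tree$heads[[parts[2]]] <- value
  tree
}

#' Hash the model's weight groups
#'
#' MD5 of the serialized parameters of every weight group (per-modality
#' backbone, per-modality head, feature-integration branch).  Used to assert
#' the stage-2 freezing contract.
#'
#' @param model An `mmfe_model` (or checkpoint, whose model is used).
#' @return Named character vector of hashes.
#' @export
hash_weight_groups <- function(model) {
  if (inherits(model, "mmfe_checkpoint")) model <- model$model
  groups <- weight_group_names(model)
  vapply(groups, function(g) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(group_ref(model, g), f, version = 2)
    unname(tools::md5sum(f))
  }, character(1))
}

# ---- configuration ---------------------------------------------------------

default_lr_schedule <- function(stage, epochs) {
  half <- max(1L, epochs %/% 2L)
  hi <- if (stage == "S1") 1e-4 else 1e-3
  list(list(lr = hi, from = 1L, to = half),
       list(lr = hi / 10, from = half + 1L, to = epochs))
}

lr_at <- function(schedule, epoch) {
  for (seg in schedule) {
    if (epoch >= seg$from && epoch <= seg$to) return(seg$lr)
  }
  schedule[[length(schedule)]]$lr
}

#' Training configuration
#'
#' Collects every tunable of the two-stage scheme.  Defaults follow the
#' reference hyperparameters: Adam, 30 epochs per stage, mini-batch 10,
#' stage-1 learning rate 1e-4 decayed to 1e-5 at half epochs, stage-2 1e-3
#' decayed to 1e-4, KL weight 1, matching weights from [match_weights()].
#'
#' @param stage `"S1"` or `"S2"`.
#' @param epochs Number of epochs (>= 2).
#' @param batch_size Mini-batch size.
#' @param lr_schedule Piecewise-constant schedule: list of
#'   `list(lr, from, to)` segments (default per stage as above).
#' @param match_weights A [match_weights()] (stage 2 only).
#' @param kl_weight KL regularizer weight.
#' @param kl_warmup Linearly ramp the KL weight from 0 to `kl_weight` over
#'   the first half of stage-1 epochs.
#' @param seed Integer seed governing initialization and batching.
#' @param modalities Modalities to train on (default: all in the cohort).
#' @param acquired Acquired modality name (default: first modality).
#' @param backbone A [backbone_spec()].
#' @param hidden FC1 width.
#' @param fuse_fi Include the FI opinion in the decision fusion.
#' @param di_gradient Differentiate the decision-integration loss through
#'   the Dempster fold (`TRUE`, default); with `FALSE` the DI term is
#'   reported but sends no gradient (evaluation-only fusion).
#' @param fi_detach Stop the feature-integration loss from backpropagating
#'   into the per-modality trunks (the FI layer itself still learns).
#'   Useful on small cohorts, where the concatenated features make the FI
#'   loss a strong subject-memorization channel; default `FALSE` (full
#'   joint backpropagation).
#' @param global_pool Pool the backbone map before the head.
#' @param k Number of cross-validation folds.
#' @param test_fold,val_fold Fold ids held out for testing / validation;
#'   the remaining folds train.
#' @param select_best Keep the epoch with the best validation AUC
#'   (ties to the later epoch); otherwise keep the final epoch.
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to the
#'   trainable groups; 0 disables.
#' @param augment_noise_sd Training-time augmentation: sd of fresh Gaussian
#'   noise added to every input volume each time it is visited (teachers
#'   always see clean volumes).  0 disables.
#' @param augment_shift Training-time augmentation: maximum integer-voxel
#'   circular shift, drawn per visit and shared across a subject's
#'   modalities (preserving co-registration).  0 disables.
#' @return A `train_config` list.
#' @export
train_config <- function(stage = c("S1", "S2"), epochs = 30L, batch_size = 10L,
                         lr_schedule = NULL, match_weights = mmfe::match_weights(),
                         kl_weight = 1, kl_warmup = FALSE, seed = 1L,
                         modalities = NULL, acquired = NULL,
                         backbone = backbone_spec(), hidden = 64L,
                         fuse_fi = TRUE, di_gradient = TRUE,
                         fi_detach = FALSE, global_pool = FALSE,
                         k = 5L, test_fold = 0L, val_fold = 1L,
                         select_best = TRUE, weight_decay = 0,
                         augment_noise_sd = 0, augment_shift = 0L) {
  stage <- match.arg(stage)
  epochs <- as.integer(epochs)
  if (epochs < 2L) stop("epochs must be >= 2", call. = FALSE)
  if (is.null(lr_schedule)) lr_schedule <- default_lr_schedule(stage, epochs)
  for (seg in lr_schedule) {
    if (seg$lr <= 0) stop("learning rates must be positive", call. = FALSE)
  }
  structure(
    list(stage = stage, epochs = epochs, batch_size = as.integer(batch_size),
         lr_schedule = lr_schedule, optimizer = "adam",
         match_weights = match_weights, kl_weight = kl_weight,
         kl_warmup = isTRUE(kl_warmup), seed = as.integer(seed),
         modalities = modalities, acquired = acquired,
         backbone = backbone, hidden = as.integer(hidden),
         fuse_fi = isTRUE(fuse_fi), di_gradient = isTRUE(di_gradient),
         fi_detach = isTRUE(fi_detach), global_pool = isTRUE(global_pool),
         k = as.integer(k), test_fold = as.integer(test_fold),
         val_fold = as.integer(val_fold), select_best = isTRUE(select_best),
         weight_decay = weight_decay,
         augment_noise_sd = augment_noise_sd,
         augment_shift = as.integer(augment_shift)),
    class = "train_config"
  )
}

#' Assign cross-validation folds
#'
#' Randomly partitions subjects into `k` folds of near-equal size (sizes
#' differ by at most one).  One rotation uses `k - 2` folds for training and
#' one each for validation and testing; the same assignment is reused across
#' both training stages to avoid leakage.
#'
#' @param cohort An `mmfe_cohort`, or an integer number of subjects.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the same seed reproduces the assignment.
#' @return If given a cohort, the cohort with per-sample `fold` set;
#'   otherwise an integer vector of fold ids in `[0, k)`.
#' @export
assign_folds <- function(cohort, k = 5L, seed = 1L) {
  n <- if (inherits(cohort, "mmfe_cohort")) length(cohort) else as.integer(cohort)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop(sprintf("cannot split %d subjects into %d folds", n, k),
                  call. = FALSE)
  folds <- with_seed(seed, {
    ids <- rep(seq_len(k) - 1L, length.out = n)
    sample(ids)
  })
  if (inherits(cohort, "mmfe_cohort")) {
    for (i in seq_len(n)) cohort[[i]]$fold <- folds[i]
    cohort
  } else folds
}

cohort_modalities <- function(cohort) {
  attr(cohort, "spec")$modality_names %||% names(cohort[[1]]$volumes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

one_hot <- function(label, K) {
  y <- numeric(K)
  y[label + 1L] <- 1
  y
}

split_cohort <- function(cohort, config) {
  folds <- vapply(cohort, `[[`, integer(1), "fold")
  if (anyNA(folds)) {
    stop("cohort folds are unassigned; run assign_folds() first",
         call. = FALSE)
  }
  list(train = which(!folds %in% c(config$test_fold, config$val_fold)),
       val = which(folds == config$val_fold),
       test = which(folds == config$test_fold))
}

# DI positive-class probability used as the ranking score.
di_score <- function(outs) {
  a <- outs$alphas$DI
  a[2] / sum(a)
}

#' Score a set of subjects with a trained model
#'
#' Runs the forward pass on each subject and collects the fused decision,
#' its uncertainty mass and the decision-integration positive-class
#' probability used as ranking score.
#'
#' @param checkpoint An `mmfe_checkpoint` (or bare `mmfe_model`).
#' @param cohort An `mmfe_cohort`.
#' @param subjects Integer indices into the cohort (default: all).
#' @param stage `"S1"` (all available modalities) or `"S2"` (acquired
#'   modality only); defaults to the checkpoint's stage.
#' @return A data.frame with `subject_id`, `label`, `score`, `pred`,
#'   `uncertainty`.
#' @export
predict_cohort <- function(checkpoint, cohort, subjects = seq_along(cohort),
                           stage = NULL) {
  model <- if (inherits(checkpoint, "mmfe_checkpoint")) checkpoint$model
           else checkpoint
  if (is.null(stage)) {
    stage <- if (inherits(checkpoint, "mmfe_checkpoint")) checkpoint$stage
             else "S1"
  }
  rows <- lapply(subjects, function(i) {
    s <- cohort[[i]]
    outs <- model_forward(model, s$volumes, stage = stage,
                          missing = if (stage == "S1") s$missing else character())
    data.frame(subject_id = s$subject_id, label = s$label,
               score = di_score(outs), pred = outs$fused$label,
               uncertainty = outs$fused$final_uncertainty,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- stage 1 ---------------------------------------------------------------

kl_weight_at <- function(config, epoch) {
  if (!config$kl_warmup) return(config$kl_weight)
  half <- max(1L, config$epochs %/% 2L)
  config$kl_weight * min(1, epoch / half)
}

# Per-sample loss + gradients for a forward pass.  loss_heads: names of heads
# whose classification loss is active (schedule + missing masking applied by
# the caller).
sample_loss_grads <- function(outs, y, w, kl_w, loss_heads) {
  dalphas <- list()
  per_head <- numeric(0)
  for (nm in loss_heads) {
    a <- outs$alphas[[nm]]
    per_head[nm] <- head_loss(a, y, w, kl_w)
    dalphas[[nm]] <- head_loss_grad(a, y, w, kl_w)
  }
  list(loss = sum(per_head), per_head = per_head, dalphas = dalphas)
}

#' Train stage 1 (joint multi-modal representation learning)
#'
#' All modality branches, heads and the feature-integration branch are
#' trained jointly with the evidential loss summed over the N + 2 heads
#' (modalities + FI + decision integration).  Subjects missing a modality
#' contribute no gradient to that branch.  Model selection keeps the epoch
#' with the best validation AUC.
#'
#' @param cohort An `mmfe_cohort` with folds assigned.
#' @param config A [train_config()] with `stage = "S1"`.
#' @return An `mmfe_checkpoint`: the selected model, config, seed and an
#'   epoch-level history.
#' @export
train_stage1 <- function(cohort, config) {
  stopifnot(inherits(config, "train_config"))
  mods <- config$modalities %||% cohort_modalities(cohort)
  acquired <- config$acquired %||% mods[1]
  idx <- split_cohort(cohort, config)
  labels_tr <- vapply(cohort[idx$train], `[[`, numeric(1), "label")
  if (length(unique(labels_tr)) < 2L) {
    stop("training folds contain a single class", call. = FALSE)
  }
  w <- class_weights_from_labels(labels_tr)
  shp <- dim(cohort[[1]]$volumes[[
    which(!vapply(cohort[[1]]$volumes, is.null, logical(1)))[1]]])

  with_seed(config$seed, {
    model <- build_model(mods, shp, K = 2L, spec = config$backbone,
                         hidden = config$hidden, fuse_fi = config$fuse_fi,
                         global_pool = config$global_pool,
                         acquired = acquired,
                         seed = config$seed)
    run_training(model, cohort, config, idx, w, s1_teacher = NULL)
  })
}

# ---- stage 2 ---------------------------------------------------------------

#' Plan the stage-2 freezing
#'
#' Stage 2 re-initializes and trains only the classification backbones
#' (encoder + 1x1x1 squeeze) of the synthesized modalities; the acquired
#' modality's backbone, every classification head and the
#' feature-integration branch are loaded from stage 1 and frozen.
#'
#' @param s1_checkpoint An `mmfe_checkpoint` from [train_stage1()].
#' @param config A [train_config()] with `stage = "S2"`.
#' @return A `freeze_plan` with character sets `trainable` and `frozen`.
#' @export
plan_stage2_freeze <- function(s1_checkpoint, config) {
  model <- s1_checkpoint$model
  mods <- config$modalities %||% model$modalities
  if (!setequal(mods, model$modalities)) {
    stop("config modalities do not match the stage-1 checkpoint",
         call. = FALSE)
  }
  acquired <- config$acquired %||% model$acquired
  if (!acquired %in% mods) {
    stop(sprintf("acquired modality '%s' not in checkpoint", acquired),
         call. = FALSE)
  }
  synth <- setdiff(model$modalities, acquired)
  trainable <- paste0("backbone:", synth, recycle0 = TRUE)
  all_groups <- weight_group_names(model)
  structure(list(trainable = trainable,
                 frozen = setdiff(all_groups, trainable)),
            class = "freeze_plan")
}

#' Train stage 2 (single-input feature-representation transfer)
#'
#' The synthesized-modality backbones (freshly initialized, with cascaded
#' convolutions) learn to produce each auxiliary modality's features from
#' the acquired volume.  The frozen stage-1 branches run on the real
#' auxiliary volumes as teachers; hierarchical similarity matching (backbone
#' map, FC1, FC2) aligns student and teacher.  During the first half of the
#' epochs the classification loss covers only the synthesized-modality
#' heads; afterwards the acquired-modality, FI and decision-integration
#' heads join.  Only the weight groups in the [plan_stage2_freeze()] plan
#' are updated.
#'
#' @param cohort An `mmfe_cohort` with folds assigned; training subjects
#'   must have complete modalities (teachers need the real volumes).
#' @param config A [train_config()] with `stage = "S2"`.
#' @param s1_checkpoint The stage-1 `mmfe_checkpoint`.
#' @return An `mmfe_checkpoint` whose history records per-epoch losses,
#'   validation AUC and the mean synthesized-vs-reference backbone cosine
#'   similarity (entry 1 = before training).
#' @export
train_stage2 <- function(cohort, config, s1_checkpoint) {
  stopifnot(inherits(config, "train_config"),
            inherits(s1_checkpoint, "mmfe_checkpoint"))
  teacher <- s1_checkpoint$model
  mods <- teacher$modalities
  acquired <- config$acquired %||% teacher$acquired
  plan <- plan_stage2_freeze(s1_checkpoint, config)
  idx <- split_cohort(cohort, config)
  miss <- unlist(lapply(cohort[c(idx$train, idx$val)], `[[`, "missing"))
  if (length(miss) > 0L) {
    stop("stage 2 requires complete auxiliary volumes for teachers; missing: ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  }
  labels_tr <- vapply(cohort[idx$train], `[[`, numeric(1), "label")
  if (length(unique(labels_tr)) < 2L) {
    stop("training folds contain a single class", call. = FALSE)
  }
  w <- class_weights_from_labels(labels_tr)

  with_seed(config$seed, {
    model <- teacher
    model$acquired <- acquired
    synth <- setdiff(mods, acquired)
    s2spec <- config$backbone
    s2spec$cascaded_convs <- TRUE
    for (m in synth) model$branches[[m]] <- build_backbone(s2spec)
    run_training(model, cohort, config, idx, w,
                 s1_teacher = teacher, plan = plan)
  })
}

# Training-time augmentation: fresh voxel noise per visit, plus one circular
# shift shared across the sample's modalities (co-registration preserved).
augment_volumes <- function(vols, noise_sd, max_shift) {
  if (noise_sd <= 0 && max_shift <= 0) return(vols)
  shift <- if (max_shift > 0) {
    sample(seq(-max_shift, max_shift), 3L, replace = TRUE)
  } else c(0L, 0L, 0L)
  lapply(vols, function(v) {
    if (is.null(v)) return(NULL)
    if (any(shift != 0L)) v <- circ_shift3(v, shift)
    if (noise_sd > 0) {
      v <- v + array(stats::rnorm(length(v), sd = noise_sd), dim = dim(v))
    }
    v
  })
}

# Shared epoch/batch loop for both stages.
run_training <- function(model, cohort, config, idx, w,
                         s1_teacher = NULL, plan = NULL) {
  stage <- config$stage
  is_s2 <- stage == "S2"
  synth <- setdiff(model$modalities, model$acquired)
  template <- grads_template(model)
  trainable <- if (is.null(plan)) weight_group_names(model) else plan$trainable
  adam <- list()
  for (g in trainable) {
    adam[[g]] <- adam_state_init(group_ref(template, g))
  }
  half <- max(1L, config$epochs %/% 2L)
  mw <- config$match_weights
  history <- list()
  best <- list(val_auc = -Inf, model = model, epoch = 0L)
  step_t <- 0L

  # Reference features are produced by the *frozen* stage-1 branches, so
  # they are constant across stage 2: compute them once per training subject.
  refs_cache <- NULL
  if (is_s2) {
    refs_cache <- lapply(idx$train, function(i) {
      s <- cohort[[i]]
      model_forward(s1_teacher, s$volumes, stage = "S1",
                    missing = s$missing)$features
    })
    names(refs_cache) <- as.character(idx$train)
  }

  mean_backbone_cs <- function() {
    # synthesized-vs-reference alignment over the training subjects
    if (!is_s2 || length(synth) == 0L) return(NA_real_)
    cs <- vapply(idx$train, function(i) {
      s <- cohort[[i]]
      refs <- refs_cache[[as.character(i)]]
      st <- model_forward(model, s$volumes[model$acquired], stage = "S2")
      mean(vapply(synth, function(m) {
        match_loss_impl(st$features[[m]]$backbone,
                        refs[[m]]$backbone, 0)$mean_cs
      }, numeric(1)))
    }, numeric(1))
    mean(cs)
  }

  backbone_cs <- if (is_s2) mean_backbone_cs() else NULL

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at(config$lr_schedule, epoch)
    kl_w <- kl_weight_at(config, epoch)
    loss_heads_all <- c(model$modalities, "FI", "DI")
    sched_heads <- if (is_s2 && epoch <= half) synth else loss_heads_all
    order_tr <- sample(idx$train)
    nb <- ceiling(length(order_tr) / config$batch_size)
    epoch_loss <- 0
    cs_accum <- numeric(0)
    for (b in seq_len(nb)) {
      ids <- order_tr[((b - 1) * config$batch_size + 1):
                        min(b * config$batch_size, length(order_tr))]
      acc <- template
      batch_loss <- 0
      for (i in ids) {
        s <- cohort[[i]]
        y <- one_hot(s$label, model$K)
        vols_in <- augment_volumes(
          if (is_s2) s$volumes[model$acquired]
          else s$volumes[setdiff(model$modalities, s$missing)],
          config$augment_noise_sd, config$augment_shift)
        if (is_s2) {
          refs <- refs_cache[[as.character(i)]]
          outs <- model_forward(model, vols_in,
                                stage = "S2", keep_cache = TRUE)
          heads_i <- sched_heads
        } else {
          outs <- model_forward(model, vols_in, stage = "S1",
                                missing = s$missing, keep_cache = TRUE)
          heads_i <- setdiff(sched_heads, s$missing)
        }
        lg <- sample_loss_grads(outs, y, w, kl_w, heads_i)
        if (!isTRUE(config$di_gradient)) lg$dalphas$DI <- NULL
        loss_i <- lg$loss
        match_grads <- list()
        if (is_s2 && length(synth) > 0L &&
            (mw$lambda_b > 0 || mw$lambda_h > 0)) {
          n_b <- length(synth)
          n_h <- 2L * length(synth)
          for (m in synth) {
            fb <- match_loss_impl(outs$features[[m]]$backbone,
                                  refs[[m]]$backbone, mw$lambda_cs,
                                  grad = TRUE)
            f1 <- match_loss_impl(outs$features[[m]]$fc1,
                                  refs[[m]]$fc1, mw$lambda_cs, grad = TRUE)
            f2 <- match_loss_impl(outs$features[[m]]$fc2,
                                  refs[[m]]$fc2, mw$lambda_cs, grad = TRUE)
            match_grads[[m]] <- list(
              backbone = tree_scale(fb$grad, mw$lambda_b / n_b),
              fc1 = tree_scale(f1$grad, mw$lambda_h / n_h),
              fc2 = tree_scale(f2$grad, mw$lambda_h / n_h))
            loss_i <- loss_i + mw$lambda_b * fb$loss / n_b +
              mw$lambda_h * (f1$loss + f2$loss) / n_h
            cs_accum <- c(cs_accum, fb$mean_cs)
          }
        }
        g <- model_backward(model, outs, lg$dalphas, match_grads,
                            fi_detach = isTRUE(config$fi_detach))
        acc <- tree_add(acc, g)
        batch_loss <- batch_loss + loss_i
      }
      acc <- tree_scale(acc, 1 / length(ids))
      step_t <- step_t + 1L
      for (gname in trainable) {
        r <- adam_step(group_ref(model, gname), group_ref(acc, gname),
                       adam[[gname]], lr, step_t, config$weight_decay %||% 0)
        model <- group_assign(model, gname, r$params)
        adam[[gname]] <- r$state
      }
      epoch_loss <- epoch_loss + batch_loss
    }
    epoch_loss <- epoch_loss / length(idx$train)

    val <- predict_cohort(model, cohort, idx$val, stage = stage)
    val_auc <- auc_stat(val$score, val$label)
    cs_ep <- if (is_s2 && length(cs_accum) > 0) mean(cs_accum) else NA_real_
    if (is_s2) backbone_cs <- c(backbone_cs, cs_ep)
    history[[epoch]] <- data.frame(
      epoch = epoch, lr = lr, kl_weight = kl_w, train_loss = epoch_loss,
      val_auc = val_auc, backbone_cs = cs_ep,
      heads = paste(sched_heads, collapse = ","))
    if (config$select_best && !is.na(val_auc) && val_auc >= best$val_auc) {
      best <- list(val_auc = val_auc, model = model, epoch = epoch)
    }
  }
  final <- if (config$select_best && best$epoch > 0L) best$model else model
  structure(
    list(model = final, final_model = model, stage = stage, config = config,
         seed = config$seed,
         best_epoch = if (config$select_best) best$epoch else config$epochs,
         freeze_plan = plan,
         history = do.call(rbind, history),
         backbone_cs = backbone_cs,
         config_hash = {
       f <- tempfile(); on.exit(unlink(f))
       saveRDS(config, f, version = 2); unname(tools::md5sum(f))
     }),
    class = "mmfe_checkpoint"
  )
}

#' @export
print.mmfe_checkpoint <- function(x, ...) {
  cat("<mmfe_checkpoint>", x$stage, "| best epoch", x$best_epoch, "\n")
  if (!is.null(x$history)) {
    utils::tail(x$history[, c("epoch", "train_loss", "val_auc")], 3)
  }
  invisible(x)
}

#' Save / load a checkpoint
#'
#' A checkpoint is a single archive holding the per-branch weight groups,
#' the backbone spec, the training config (with hash) and the seed —
#' sufficient to reconstruct the stage-1 model and to initialize stage 2.
#'
#' @param checkpoint An `mmfe_checkpoint`.
#' @param path File path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "mmfe_checkpoint"))
  saveRDS(checkpoint, path, version = 2)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "mmfe_checkpoint")) {
    stop("not an mmfe checkpoint: ", path, call. = FALSE)
  }
  ck
}

#' Single-modality inference
#'
#' Runs the full forward pass of a stage-2 model from the single acquired
#' volume: the synthesized branches impute the auxiliary modalities'
#' features, all evidential heads fire, and Dempster fusion yields the
#' label and the final uncertainty mass.
#'
#' @param checkpoint An `mmfe_checkpoint` (stage 2) or `mmfe_model`.
#' @param acquired_volume A 3-D array (the acquired modality's volume).
#' @return A list with `label` (0/1), `uncertainty`, `score` (DI
#'   positive-class probability), per-modality `beliefs`, and the full
#'   `model_outputs`.
#' @export
infer <- function(checkpoint, acquired_volume) {
  model <- if (inherits(checkpoint, "mmfe_checkpoint")) checkpoint$model
           else checkpoint
  if (!identical(dim(acquired_volume), NULL) &&
      length(dim(acquired_volume)) != 3L) {
    stop("acquired_volume must be a 3-D array", call. = FALSE)
  }
  vols <- stats::setNames(list(acquired_volume), model$acquired)
  outs <- model_forward(model, vols, stage = "S2")
  list(label = outs$fused$label,
       uncertainty = outs$fused$final_uncertainty,
       score = di_score(outs),
       beliefs = lapply(outs$opinions, `[[`, "beliefs"),
       outputs = outs)
}
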