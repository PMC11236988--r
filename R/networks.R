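#' Backbone specification
#'
#' Describes a per-modality classification backbone.  `cnn5` is a 5-layer 3D
#' CNN (kernel 3x3x3, instance norm + leaky ReLU per layer, first stride 1
#' then 2) with a trailing 1x1x1 convolution squeezing to
#' `squeeze_channels`; `resnet` is a ResNet-style variant with basic blocks
#' and channels 32-64-128-256.  `cascaded_convs` doubles the convolutions per
#' layer and is only used for the unfrozen (synthesizing) branches in
#' stage 2.
#'
#' @param kind `"cnn5"` or `"resnet"`.
#' @param channels Integer sequence of layer channels.
#' @param strides Integer sequence of layer strides (same length).
#' @param squeeze_channels Channels after the final 1x1x1 squeeze.
#' @param cascaded_convs Logical; two cascaded convolutions per layer
#'   (stage-2 synthesized branches only).
#' @return A `backbone_spec` list.
#' @export
backbone_spec <- function(kind = c("cnn5", "resnet"),
                          channels = NULL, strides = NULL,
                          squeeze_channels = 16L, cascaded_convs = FALSE) {
  kind <- match.arg(kind)
  if (is.null(channels)) {
    channels <- if (kind == "cnn5") c(16L, 32L, 64L, 128L, 256L)
                else c(32L, 64L, 128L, 256L)
  }
  if (is.null(strides)) {
    strides <- if (kind == "cnn5") c(1L, 2L, 2L, 2L, 2L) else c(1L, 2L, 2L, 2L)
  }
  if (length(channels) != length(strides)) {
    stop("channels and strides must have equal length", call. = FALSE)
  }
  if (any(channels <= 0) || any(!strides %in% c(1L, 2L))) {
    stop("channels must be positive, strides in {1, 2}", call. = FALSE)
  }
  structure(
    list(kind = kind, channels = as.integer(channels),
         strides = as.integer(strides),
         squeeze_channels = as.integer(squeeze_channels),
         cascaded_convs = isTRUE(cascaded_convs)),
    class = "backbone_spec"
  )
}

conv_out_len <- function(n, s) (n - 1L) %/% s + 1L

# Spatial dims of the backbone output for a given input shape.
backbone_out_shape <- function(spec, input_shape) {
  shp <- as.integer(input_shape)
  strides <- spec$strides
  if (spec$kind == "resnet") strides <- c(2L, spec$strides)  # stem stride 2
  for (s in strides) shp <- conv_out_len(shp, s)
  shp
}

kaiming_mat <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
}

new_conv3 <- function(cin, cout, stride) {
  list(type = "conv3", W = kaiming_mat(cout, cin * 27L),
       b = numeric(cout), stride = as.integer(stride))
}

new_in <- function(c) list(type = "in", gamma = rep(1, c), beta = numeric(c))

new_conv1 <- function(cin, cout) {
  list(type = "conv1", W = kaiming_mat(cout, cin), b = numeric(cout))
}

new_res <- function(cin, cout, stride) {
  list(type = "res",
       conv1 = new_conv3(cin, cout, stride), in1 = new_in(cout),
       conv2 = new_conv3(cout, cout, 1L), in2 = new_in(cout),
       proj = if (stride != 1L || cin != cout) new_conv1(cin, cout) else NULL,
       stride = as.integer(stride))
}

#' Build a classification backbone
#'
#' Constructs the parameter tree of one modality branch: the convolutional
#' encoder plus the trailing 1x1x1 channel squeeze.  Weights are initialized
#' Kaiming-style from the current RNG state.
#'
#' @param spec A [backbone_spec()].
#' @param in_channels Input channels (1 for a single volume).
#' @return A `backbone` parameter list usable by the forward pass.
#' @export
build_backbone <- function(spec, in_channels = 1L) {
  stopifnot(inherits(spec, "backbone_spec"))
  layers <- list()
  cin <- as.integer(in_channels)
  if (spec$kind == "cnn5") {
    for (i in seq_along(spec$channels)) {
      cout <- spec$channels[i]
      layers <- c(layers, list(new_conv3(cin, cout, spec$strides[i])))
      if (spec$cascaded_convs) {
        layers <- c(layers, list(new_conv3(cout, cout, 1L)))
      }
      layers <- c(layers, list(new_in(cout)), list(list(type = "lrelu")))
      cin <- cout
    }
  } else {
    stem <- spec$channels[1]
    layers <- c(layers, list(new_conv3(cin, stem, 2L)),
                list(new_in(stem)), list(list(type = "lrelu")))
    cin <- stem
    for (i in seq_along(spec$channels)) {
      cout <- spec$channels[i]
      layers <- c(layers, list(new_res(cin, cout, spec$strides[i])))
      cin <- cout
    }
  }
  structure(list(spec = spec, layers = layers,
                 squeeze = new_conv1(cin, spec$squeeze_channels)),
            class = "backbone")
}

#' Build an evidential classification head
#'
#' Flatten -> FC1 (`hidden` units, leaky-ReLU) -> FC2 (`K` units) ->
#' Softplus evidence.  The activated FC1 output is exposed for the
#' feature-integration branch and for head-level similarity matching; the
#' FC2 output is the pre-Softplus evidence logit.
#'
#' @param in_features Flattened backbone feature length.
#' @param hidden FC1 width.
#' @param K Number of classes.
#' @return A `head` parameter list.
#' @export
build_head <- function(in_features, hidden, K) {
  stopifnot(in_features > 0, hidden > 0, K >= 2)
  structure(list(W1 = kaiming_mat(hidden, in_features), b1 = numeric(hidden),
                 W2 = kaiming_mat(K, hidden), b2 = numeric(K),
                 hidden = as.integer(hidden), in_features = as.integer(in_features)),
            class = "head")
}

#' Build the feature-integration branch
#'
#' A fully connected layer over the concatenation of the N FC1 outputs
#' (length `N * hidden`), followed by Softplus, yielding the FI evidence.
#'
#' @param N Number of modalities.
#' @param hidden FC1 width of each head.
#' @param K Number of classes.
#' @return An `fi_branch` parameter list.
#' @export
build_fi_branch <- function(N, hidden, K) {
  stopifnot(N >= 1, hidden > 0, K >= 2)
  structure(list(W = kaiming_mat(K, N * hidden), b = numeric(K),
                 N = as.integer(N), hidden = as.integer(hidden)),
            class = "fi_branch")
}

#' Assemble the multi-branch evidential model
#'
#' One backbone + evidential head per modality, a feature-integration branch
#' over the concatenated FC1 outputs, and Dempster fusion of the resulting
#' opinions into the decision-integration output.
#'
#' @param modalities Character vector of modality names (branch order).
#' @param input_shape Integer triple, the spatial shape of input volumes.
#' @param K Number of classes (binary by default).
#' @param spec A [backbone_spec()] shared by all branches.
#' @param hidden FC1 width (default 64).
#' @param fuse_fi Should the FI opinion enter the Dempster fusion that forms
#'   the decision-integration output? (default `TRUE`).
#' @param global_pool Average the squeezed backbone map over space before the
#'   head (for large volumes; default `FALSE`, the head consumes the
#'   flattened map).
#' @param acquired Name of the acquired modality (default: the first); the
#'   remaining branches are the synthesized ones in stage 2.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `mmfe_model`.
#' @export
build_model <- function(modalities, input_shape, K = 2L,
                        spec = backbone_spec(), hidden = 64L,
                        fuse_fi = TRUE, global_pool = FALSE,
                        acquired = modalities[1L], seed = 1L) {
  stopifnot(length(modalities) >= 1L, acquired %in% modalities)
  input_shape <- as.integer(input_shape)
  if (any(input_shape <= 0)) stop("non-positive input dims", call. = FALSE)
  out_shape <- backbone_out_shape(spec, input_shape)
  if (any(out_shape <= 0)) {
    stop("input volume too small for this backbone", call. = FALSE)
  }
  in_features <- if (global_pool) spec$squeeze_channels
                 else spec$squeeze_channels * prod(out_shape)
  with_seed(seed, {
    branches <- lapply(modalities, function(m) build_backbone(spec))
    heads <- lapply(modalities, function(m) build_head(in_features, hidden, K))
    names(branches) <- names(heads) <- modalities
    fi <- build_fi_branch(length(modalities), hidden, K)
    structure(
      list(modalities = modalities, acquired = acquired, K = as.integer(K),
           spec = spec, hidden = as.integer(hidden), fuse_fi = fuse_fi,
           global_pool = isTRUE(global_pool),
           input_shape = input_shape, out_shape = out_shape,
           branches = branches, heads = heads, fi = fi),
      class = "mmfe_model"
    )
  })
}

#' @export
print.mmfe_model <- function(x, ...) {
  cat("<mmfe_model>", length(x$modalities), "branches (",
      paste(x$modalities, collapse = ", "), "), K =", x$K, "\n")
  cat("  backbone:", x$spec$kind, "channels",
      paste(x$spec$channels, collapse = "-"),
      "squeeze", x$spec$squeeze_channels, "\n")
  cat("  acquired modality:", x$acquired,
      " fuse_fi:", x$fuse_fi, "\n")
  invisible(x)
}

# ---- forward ---------------------------------------------------------------

layer_fwd <- function(layer, x, keep_cache) {
  switch(layer$type,
    conv3 = {
      r <- conv3d_forward(x, layer$W, layer$b, layer$stride, keep_cache)
      list(y = r$y, cache = if (keep_cache)
        list(xdim = dim(x), cols = r$cols) else NULL)
    },
    conv1 = {
      y <- conv1x1_fwd(x, layer$W, layer$b)
      list(y = y, cache = if (keep_cache) list(x = x) else NULL)
    },
    "in" = {
      r <- instnorm_fwd(x, layer$gamma, layer$beta)
      list(y = r$y, cache = if (keep_cache) r[c("xhat", "istd", "dims")] else NULL)
    },
    lrelu = {
      list(y = lrelu_fwd(x), cache = if (keep_cache) list(x = x) else NULL)
    },
    res = {
      c1 <- layer_fwd(layer$conv1, x, keep_cache)
      i1 <- layer_fwd(layer$in1, c1$y, keep_cache)
      a1 <- layer_fwd(list(type = "lrelu"), i1$y, keep_cache)
      c2 <- layer_fwd(layer$conv2, a1$y, keep_cache)
      i2 <- layer_fwd(layer$in2, c2$y, keep_cache)
      if (is.null(layer$proj)) {
        short <- x
        pc <- NULL
      } else {
        xs <- if (layer$stride == 2L) {
          ds <- dim(x)
          x[seq(1, ds[1], 2), seq(1, ds[2], 2), seq(1, ds[3], 2), ,
            drop = FALSE]
        } else x
        short <- conv1x1_fwd(xs, layer$proj$W, layer$proj$b)
        pc <- if (keep_cache) list(xs = xs, xdim = dim(x)) else NULL
      }
      pre <- i2$y + short
      list(y = lrelu_fwd(pre),
           cache = if (keep_cache)
             list(c1 = c1$cache, i1 = i1$cache, a1 = a1$cache,
                  c2 = c2$cache, i2 = i2$cache, proj = pc, pre = pre)
           else NULL)
    },
    stop("unknown layer type: ", layer$type)
  )
}

backbone_fwd <- function(bb, x, keep_cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  caches <- if (keep_cache) vector("list", length(bb$layers)) else NULL
  for (i in seq_along(bb$layers)) {
    r <- layer_fwd(bb$layers[[i]], x, keep_cache)
    if (keep_cache) caches[[i]] <- r$cache
    x <- r$y
  }
  feat <- conv1x1_fwd(x, bb$squeeze$W, bb$squeeze$b)
  list(feat = feat,
       cache = if (keep_cache) list(layers = caches, pre_squeeze = x) else NULL)
}

branch_fwd <- function(model, m, vol, keep_cache = FALSE) {
  bb <- backbone_fwd(model$branches[[m]], vol, keep_cache)
  feat <- bb$feat
  flat <- if (model$global_pool) {
    colMeans(matrix(feat, ncol = dim(feat)[4]))
  } else as.numeric(feat)
  h <- model$heads[[m]]
  fc1_pre <- fc_fwd(flat, h$W1, h$b1)
  fc1 <- lrelu_fwd(fc1_pre)
  fc2 <- fc_fwd(fc1, h$W2, h$b2)
  list(feat = feat, flat = flat, fc1_pre = fc1_pre, fc1 = fc1, fc2 = fc2,
       evidence = softplus(fc2),
       cache = if (keep_cache) bb$cache else NULL)
}

#' Multi-branch forward pass
#'
#' Runs every branch and head, the feature-integration branch, and the
#' Dempster fusion.  In stage `"S1"` branch `m` consumes modality `m`'s
#' volume (missing modalities are skipped and excluded from fusion; their
#' FC1 slot in the FI input is zero).  In stage `"S2"` *all* branches consume
#' the single acquired modality's volume: the non-acquired branches
#' synthesize the features of their modality from it.
#'
#' @param model An [build_model()] object.
#' @param volumes Named list of 3-D arrays.  For `"S1"`, one per available
#'   modality; for `"S2"`, the acquired modality's volume suffices.
#' @param stage `"S1"` or `"S2"`.
#' @param missing Character vector of modalities absent for this sample
#'   (`"S1"` only).
#' @param keep_cache Keep the intermediates needed for a backward pass.
#' @return A `model_outputs` list: per-modality `features` (backbone map,
#'   fc1, fc2), `evidence`, `alphas` (including `"FI"` and `"DI"`),
#'   `opinions`, and the fused `fusion_result`.
#' @export
model_forward <- function(model, volumes, stage = c("S1", "S2"),
                          missing = character(), keep_cache = FALSE) {
  stage <- match.arg(stage)
  mods <- model$modalities
  if (stage == "S2") {
    if (!model$acquired %in% names(volumes)) {
      stop(sprintf("stage S2 requires the acquired modality '%s'",
                   model$acquired), call. = FALSE)
    }
    vol_for <- function(m) volumes[[model$acquired]]
    missing <- character()
  } else {
    absent <- setdiff(setdiff(mods, missing), names(volumes))
    if (length(absent) > 0L) {
      stop(sprintf("missing required volume for modality: %s",
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
    vol_for <- function(m) volumes[[m]]
  }

  present <- setdiff(mods, missing)
  br <- lapply(present, function(m)
    branch_fwd(model, m, vol_for(m), keep_cache))
  names(br) <- present

  # FI input: FC1 outputs in branch order, zeros for missing modalities
  fc1s <- lapply(mods, function(m) {
    if (m %in% present) br[[m]]$fc1 else numeric(model$hidden)
  })
  cat_fc1 <- unlist(fc1s, use.names = FALSE)
  fi_pre <- fc_fwd(cat_fc1, model$fi$W, model$fi$b)
  fi_evidence <- softplus(fi_pre)

  alphas <- lapply(br, function(x) x$evidence + 1)
  alphas$FI <- fi_evidence + 1
  opinions <- lapply(alphas, function(a)
    evidence_to_opinion(dirichlet_evidence(a - 1)))
  fuse_names <- if (model$fuse_fi) c(present, "FI") else present
  fused <- dempster_combine_all(opinions[fuse_names])
  alphas$DI <- opinion_to_alpha(fused$combined)$alpha

  structure(
    list(features = lapply(br, function(x)
           list(backbone = x$feat, fc1 = x$fc1, fc2 = x$fc2)),
         evidence = lapply(br, function(x) x$evidence),
         fi_evidence = fi_evidence,
         alphas = alphas, opinions = opinions,
         fuse_names = fuse_names, fused = fused,
         stage = stage, missing = missing,
         cache = if (keep_cache)
           list(branches = br, cat_fc1 = cat_fc1, fi_pre = fi_pre) else NULL),
    class = "model_outputs"
  )
}

# ---- backward --------------------------------------------------------------

zero_like <- function(x) {
  if (is.list(x)) return(lapply(x, zero_like))
  y <- x
  y[] <- 0
  y
}

layer_bwd <- function(layer, cache, dy) {
  switch(layer$type,
    conv3 = {
      r <- conv3d_backward(dy, cache$xdim, layer$W, cache$cols, layer$stride)
      list(dx = r$dx, grads = list(W = r$dW, b = r$db))
    },
    conv1 = {
      r <- conv1x1_bwd(cache$x, layer$W, dy)
      list(dx = r$dx, grads = list(W = r$dW, b = r$db))
    },
    "in" = {
      r <- instnorm_bwd(cache, layer$gamma, dy)
      list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    lrelu = list(dx = lrelu_bwd(cache$x, dy), grads = NULL),
    res = {
      dpre <- lrelu_bwd(cache$pre, dy)
      g <- list()
      r2 <- layer_bwd(layer$in2, cache$i2, dpre);  g$in2 <- r2$grads
      r2c <- layer_bwd(layer$conv2, cache$c2, r2$dx); g$conv2 <- r2c$grads
      ra <- layer_bwd(list(type = "lrelu"), cache$a1, r2c$dx)
      r1 <- layer_bwd(layer$in1, cache$i1, ra$dx); g$in1 <- r1$grads
      r1c <- layer_bwd(layer$conv1, cache$c1, r1$dx); g$conv1 <- r1c$grads
      dx <- r1c$dx
      if (is.null(layer$proj)) {
        dx <- dx + dpre
      } else {
        rp <- conv1x1_bwd(cache$proj$xs, layer$proj$W, dpre)
        g$proj <- list(W = rp$dW, b = rp$db)
        if (layer$stride == 2L) {
          dfull <- array(0, dim = cache$proj$xdim)
          ds <- cache$proj$xdim
          dfull[seq(1, ds[1], 2), seq(1, ds[2], 2), seq(1, ds[3], 2), ] <-
            rp$dx
          dx <- dx + dfull
        } else {
          dx <- dx + rp$dx
        }
      }
      list(dx = dx, grads = g)
    },
    stop("unknown layer type")
  )
}

backbone_bwd <- function(bb, cache, dfeat, need_dx = FALSE) {
  sq <- conv1x1_bwd(cache$pre_squeeze, bb$squeeze$W, dfeat)
  grads <- list(squeeze = list(W = sq$dW, b = sq$db),
                layers = vector("list", length(bb$layers)))
  dy <- sq$dx
  for (i in rev(seq_along(bb$layers))) {
    r <- layer_bwd(bb$layers[[i]], cache$layers[[i]], dy)
    grads$layers[i] <- list(r$grads)  # keep NULL slots (lrelu) in place
    dy <- r$dx
  }
  list(grads = grads, dx = if (need_dx) dy else NULL)
}

# Backward pass through the whole model for one sample.
#
# dalphas: named list of upstream gradients w.r.t. the head alphas,
#   including "FI" and "DI" (any may be NULL).
# match_grads: named per-modality list(backbone =, fc1 =, fc2 =) gradients
#   from the similarity-matching losses (or NULL).
# Returns a gradient tree mirroring model$branches / $heads / $fi.
model_backward <- function(model, outs, dalphas, match_grads = list(),
                           fi_detach = FALSE) {
  stopifnot(!is.null(outs$cache))
  br <- outs$cache$branches
  present <- names(br)
  K <- model$K

  d_alpha <- lapply(outs$alphas[c(present, "FI")], function(a) numeric(K))
  for (nm in intersect(names(dalphas), names(d_alpha))) {
    if (!is.null(dalphas[[nm]])) {
      d_alpha[[nm]] <- d_alpha[[nm]] + dalphas[[nm]]
    }
  }

  # decision-integration head: backprop through alpha <- fused opinion <- fold
  if (!is.null(dalphas$DI)) {
    fb <- outs$fused$combined
    vj <- alpha_from_opinion_vjp(fb$beliefs, fb$uncertainty, dalphas$DI)
    srcs <- outs$fuse_names
    bs <- lapply(outs$opinions[srcs], `[[`, "beliefs")
    us <- vapply(outs$opinions[srcs], `[[`, numeric(1), "uncertainty")
    fwd <- ds_fold_fwd(bs, us)
    back <- ds_fold_bwd(fwd, bs, us, vj$db, vj$du)
    for (i in seq_along(srcs)) {
      nm <- srcs[i]
      d_alpha[[nm]] <- d_alpha[[nm]] +
        opinion_from_alpha_vjp(outs$alphas[[nm]], back$dbs[[i]], back$dus[i])
    }
  }

  grads <- list(branches = list(), heads = list(), fi = NULL)

  # FI branch: alpha = softplus(fi_pre) + 1
  dfi_pre <- d_alpha$FI * sigmoid(outs$cache$fi_pre)
  fi_b <- fc_bwd(outs$cache$cat_fc1, model$fi$W, dfi_pre)
  grads$fi <- list(W = fi_b$dW, b = fi_b$db)
  # fi_detach: the FI branch still learns, but its loss does not reshape the
  # per-modality trunks through the concatenated FC1 features
  dcat <- if (fi_detach) numeric(length(fi_b$dx)) else fi_b$dx

  for (m in present) {
    bc <- br[[m]]
    h <- model$heads[[m]]
    mg <- match_grads[[m]]

    dfc2 <- d_alpha[[m]] * sigmoid(bc$fc2)
    if (!is.null(mg$fc2)) dfc2 <- dfc2 + mg$fc2
    h2 <- fc_bwd(bc$fc1, h$W2, dfc2)
    dfc1 <- h2$dx

    slot <- match(m, model$modalities)
    dcat_slice <- dcat[((slot - 1) * model$hidden + 1):(slot * model$hidden)]
    dfc1 <- dfc1 + dcat_slice
    if (!is.null(mg$fc1)) dfc1 <- dfc1 + mg$fc1

    dfc1_pre <- lrelu_bwd(bc$fc1_pre, dfc1)
    h1 <- fc_bwd(bc$flat, h$W1, dfc1_pre)
    grads$heads[[m]] <- list(W1 = h1$dW, b1 = h1$db, W2 = h2$dW, b2 = h2$db)

    dflat <- h1$dx
    dfeat <- if (model$global_pool) {
      ds <- dim(bc$feat)
      nvox <- prod(ds[1:3])
      array(rep(dflat / nvox, each = nvox), dim = ds)
    } else {
      array(dflat, dim = dim(bc$feat))
    }
    if (!is.null(mg$backbone)) dfeat <- dfeat + mg$backbone
    grads$branches[[m]] <-
      backbone_bwd(model$branches[[m]], bc$cache, dfeat)$grads
  }
  grads
}
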