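# Rank-statistic AUC: fraction of concordant positive/negative pairs, ties
# counting one half (equals the normalized Mann-Whitney U statistic).
auc_stat <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Classification metrics
#'
#' AUC by the rank statistic over all positive/negative pairs (ties count
#' one half); accuracy, sensitivity, specificity and F1 (positive class)
#' from the hard labels.
#'
#' @param scores Per-subject positive-class score.
#' @param labels Binary ground-truth labels.
#' @param preds Optional hard predictions; defaults to `scores >= 0.5`.
#' @return A one-row data.frame with `auc`, `acc`, `sen`, `spe`, `f1`, `n`.
#'   If only one class is present, `auc` is `NA` with a warning; the other
#'   metrics are still returned.
#' @examples
#' compute_metrics(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
#' @export
compute_metrics <- function(scores, labels, preds = NULL) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (is.null(preds)) preds <- as.integer(scores >= 0.5)
  preds <- as.integer(preds)
  auc <- auc_stat(scores, labels)
  if (is.na(auc)) {
    warning("AUC undefined: only one class present", call. = FALSE)
  }
  tp <- sum(preds == 1 & labels == 1)
  tn <- sum(preds == 0 & labels == 0)
  fp <- sum(preds == 1 & labels == 0)
  fn <- sum(preds == 0 & labels == 1)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  data.frame(auc = auc, acc = (tp + tn) / length(labels),
             sen = sen, spe = spe, f1 = f1, n = length(labels))
}

#' Uncertainty-stratified evaluation
#'
#' Categorizes subjects by the confusion matrix (TP/TN/FP/FN) and reports
#' the mean and sd of the fused uncertainty mass per category, plus an
#' accuracy / coverage curve over normalized uncertainty thresholds: at each
#' threshold, accuracy is computed within the subjects whose normalized
#' uncertainty does not exceed it, and coverage is their fraction of the
#' cohort.  Uncertainties are min-max normalized over the evaluated cohort.
#' A two-sided Mann-Whitney test compares the uncertainty of correct vs
#' incorrect predictions.
#'
#' @param preds Binary hard predictions.
#' @param labels Binary ground-truth labels.
#' @param uncertainties Fused uncertainty masses in `(0, 1]`.
#' @return An `uncertainty_report`: `by_category` (data.frame), `curve`
#'   (data.frame with `threshold`, `acc`, `coverage`), and
#'   `p_correct_vs_incorrect` (`NA` if a group is empty).
#' @export
uncertainty_report <- function(preds, labels, uncertainties) {
  n <- length(preds)
  stopifnot(length(labels) == n, length(uncertainties) == n)
  if (any(uncertainties <= 0 | uncertainties > 1)) {
    stop("uncertainty masses must lie in (0, 1]", call. = FALSE)
  }
  preds <- as.integer(preds); labels <- as.integer(labels)
  cat <- ifelse(preds == 1 & labels == 1, "TP",
         ifelse(preds == 0 & labels == 0, "TN",
         ifelse(preds == 1 & labels == 0, "FP", "FN")))
  by_category <- do.call(rbind, lapply(c("TP", "TN", "FP", "FN"), function(cc) {
    u <- uncertainties[cat == cc]
    data.frame(category = cc, n = length(u),
               mean_u = if (length(u)) mean(u) else NA_real_,
               sd_u = if (length(u) > 1) stats::sd(u) else NA_real_,
               coverage = length(u) / n)
  }))

  rng <- range(uncertainties)
  u_norm <- if (diff(rng) > 0) (uncertainties - rng[1]) / diff(rng)
            else rep(0, n)
  correct <- preds == labels
  thresholds <- sort(unique(u_norm))
  curve <- do.call(rbind, lapply(thresholds, function(t) {
    sel <- u_norm <= t
    data.frame(threshold = t, acc = mean(correct[sel]),
               coverage = mean(sel))
  }))

  p <- if (any(correct) && any(!correct)) {
    suppressWarnings(stats::wilcox.test(
      uncertainties[correct], uncertainties[!correct],
      alternative = "two.sided"))$p.value
  } else NA_real_

  structure(list(by_category = by_category, curve = curve,
                 p_correct_vs_incorrect = p, n = n),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat("<uncertainty_report> n =", x$n, "\n")
  print(x$by_category, row.names = FALSE)
  cat("correct vs incorrect uncertainty, two-sided p =",
      format(x$p_correct_vs_incorrect, digits = 3), "\n")
  invisible(x)
}

#' Plot the accuracy / coverage curve of an uncertainty report
#'
#' @param x An [uncertainty_report()].
#' @param ... Passed to [plot()].
#' @export
plot.uncertainty_report <- function(x, ...) {
  plot(x$curve$threshold, x$curve$acc, type = "s", ylim = c(0, 1),
       xlab = "normalized uncertainty threshold", ylab = "",
       col = "firebrick", lwd = 2, ...)
  graphics::lines(x$curve$threshold, x$curve$coverage, type = "s",
                  col = "steelblue", lwd = 2)
  graphics::legend("bottomright", c("accuracy", "coverage"),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
  invisible(x)
}

# Flattened-channel cosine similarity.
cos_sim <- function(x, r) {
  nx <- sqrt(sum(x^2)); nr <- sqrt(sum(r^2))
  if (nx < 1e-12 || nr < 1e-12) return(NA_real_)
  sum(x * r) / (nx * nr)
}

# KL divergence after converting a flattened feature map to a probability
# vector: shift by the minimum, add epsilon, normalize.  (Leaky-ReLU
# features may be negative; the divergence needs positivity.)
feature_kld <- function(syn, ref, eps = 1e-8) {
  to_prob <- function(x) {
    if (min(x) < 0) x <- x - min(x)   # leaky-ReLU features may be negative
    x <- x + eps
    x / sum(x)
  }
  p <- to_prob(ref)
  q <- to_prob(syn)
  sum(p * (log(p) - log(q)))
}

#' Similarity between synthesized and reference feature stacks
#'
#' Per backbone channel: cosine similarity of the flattened maps and KL
#' divergence of their probability-normalized versions; plus the cosine
#' similarity of the FC1 and FC2 activation vectors.
#'
#' @param f_syn,f_ref Feature stacks (`list(backbone, fc1, fc2)` as produced
#'   by [model_forward()]), with matching shapes.
#' @return A `similarity_report`: `channels` (data.frame `channel`, `cs`,
#'   `kld`) and `fc` (data.frame `layer`, `cs`).
#' @export
feature_similarity <- function(f_syn, f_ref) {
  bs <- f_syn$backbone; br <- f_ref$backbone
  if (!identical(dim(bs), dim(br))) {
    stop("backbone feature shapes differ", call. = FALSE)
  }
  nch <- dim(bs)[4]
  sm <- matrix(bs, ncol = nch); rm_ <- matrix(br, ncol = nch)
  channels <- do.call(rbind, lapply(seq_len(nch), function(c) {
    cs <- cos_sim(sm[, c], rm_[, c])
    if (is.na(cs)) message("feature_similarity: zero-norm channel ", c)
    data.frame(channel = c, cs = cs, kld = feature_kld(sm[, c], rm_[, c]))
  }))
  fc <- data.frame(
    layer = c("fc1", "fc2"),
    cs = c(cos_sim(f_syn$fc1, f_ref$fc1), cos_sim(f_syn$fc2, f_ref$fc2)))
  structure(list(channels = channels, fc = fc), class = "similarity_report")
}

#' Gradient saliency maps of the backbone channels
#'
#' For each branch, the absolute gradient of the selected class's evidence
#' with respect to the 16-channel backbone feature map: one saliency volume
#' per channel, plus the channel-averaged per-modality map.  The gradient
#' flows through the branch's evidential head only (the backbone features
#' are the "input" being attributed).
#'
#' @param model An `mmfe_model` or `mmfe_checkpoint`.
#' @param volumes Named list of input volumes (as for [model_forward()]).
#' @param stage `"S1"` or `"S2"`.
#' @param target `"predicted"` (fused decision, default) or `"true"` with
#'   `label` supplied.
#' @param label Ground-truth label (0/1) when `target = "true"`.
#' @param method `"gradient"` (default) or `"grad_x_input"`.
#' @return Named list per modality: `channels` (4-D array of per-channel
#'   absolute saliency) and `mean` (channel-averaged 3-D map).
#' @export
saliency_map <- function(model, volumes, stage = c("S1", "S2"),
                         target = c("predicted", "true"), label = NULL,
                         method = c("gradient", "grad_x_input")) {
  if (inherits(model, "mmfe_checkpoint")) model <- model$model
  stage <- match.arg(stage)
  target <- match.arg(target)
  method <- match.arg(method)
  outs <- model_forward(model, volumes, stage = stage, keep_cache = TRUE)
  k_sel <- if (target == "true") {
    stopifnot(!is.null(label))
    label + 1L
  } else outs$fused$label + 1L

  res <- list()
  for (m in names(outs$cache$branches)) {
    bc <- outs$cache$branches[[m]]
    h <- model$heads[[m]]
    # d evidence_k / d fc2 = e_k basis * sigmoid(fc2_k)
    dfc2 <- numeric(model$K)
    dfc2[k_sel] <- sigmoid(bc$fc2[k_sel])
    dfc1 <- as.numeric(crossprod(h$W2, dfc2))
    dfc1_pre <- lrelu_bwd(bc$fc1_pre, dfc1)
    dflat <- as.numeric(crossprod(h$W1, dfc1_pre))
    dfeat <- if (model$global_pool) {
      ds <- dim(bc$feat); nvox <- prod(ds[1:3])
      array(rep(dflat / nvox, each = nvox), dim = ds)
    } else array(dflat, dim = dim(bc$feat))
    sal <- abs(dfeat)
    if (method == "grad_x_input") sal <- abs(dfeat * bc$feat)
    res[[m]] <- list(channels = sal,
                     mean = apply(sal, 1:3, mean))
  }
  res
}

#' Pearson correlation matrix between real and synthesized saliency maps
#'
#' Entry (i, j) is the Pearson correlation between the flattened saliency
#' map of real channel i and synthesized channel j, averaged over subjects.
#' With reliable synthesis the diagonal is close to 1 and off-diagonal
#' entries are small.
#'
#' @param real_sms,syn_sms Lists (one element per subject) of 4-D saliency
#'   arrays (`D x H x W x channels`), matching in shape.
#' @return A `saliency_correlation`: `matrix` (channels x channels average
#'   Pearson matrix), and `diagonal` (data.frame with per-channel mean and
#'   sd of the diagonal across subjects).
#' @export
saliency_correlation <- function(real_sms, syn_sms) {
  stopifnot(length(real_sms) == length(syn_sms), length(real_sms) >= 1L)
  nch <- dim(real_sms[[1]])[4]
  mats <- lapply(seq_along(real_sms), function(s) {
    r <- matrix(real_sms[[s]], ncol = nch)
    y <- matrix(syn_sms[[s]], ncol = nch)
    if (!identical(dim(r), dim(y))) {
      stop("saliency shapes differ for subject ", s, call. = FALSE)
    }
    m <- suppressWarnings(stats::cor(r, y))
    m
  })
  arr <- array(unlist(mats), dim = c(nch, nch, length(mats)))
  avg <- apply(arr, 1:2, mean, na.rm = TRUE)  # all-NA (constant SM) stays NaN
  diags <- vapply(mats, diag, numeric(nch))
  diags <- matrix(diags, nrow = nch)
  diagonal <- data.frame(
    channel = seq_len(nch),
    mean = rowMeans(diags, na.rm = TRUE),
    sd = apply(diags, 1, function(v)
      if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else NA_real_))
  structure(list(matrix = avg, diagonal = diagonal, n_subjects = length(mats)),
            class = "saliency_correlation")
}

#' @export
print.saliency_correlation <- function(x, ...) {
  cat("<saliency_correlation>", nrow(x$matrix), "channels over",
      x$n_subjects, "subjects; mean diagonal =",
      format(mean(x$diagonal$mean), digits = 4), "\n")
  invisible(x)
}
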