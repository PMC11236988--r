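#' Class weights from binary labels
#'
#' The evidential cross-entropy is weighted to counter label imbalance: the
#' positive (disease, minority) class is weighted by the ratio of negative to
#' positive labels, the negative class by 1.
#'
#' @param labels Integer/numeric vector of binary labels (0 = negative,
#'   1 = positive); both classes must be present.
#' @return Numeric vector `c(w_negative, w_positive)` of positive weights,
#'   indexed by class (class 1 = label 0, class 2 = label 1).
#' @examples
#' class_weights_from_labels(c(rep(0, 60), rep(1, 40)))  # c(1, 1.5)
#' @export
class_weights_from_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to derive class weights", call. = FALSE)
  }
  c(1, n_neg / n_pos)
}

check_one_hot <- function(y) {
  if (!is.numeric(y) || any(!(y %in% c(0, 1))) || sum(y) != 1) {
    stop("y must be a one-hot label vector", call. = FALSE)
  }
  invisible(y)
}

#' Adjusted Dirichlet parameter
#'
#' Resets the true-class entry of `alpha` to 1 while keeping the wrong-class
#' entries: \eqn{\tilde\alpha = y + \alpha (1 - y)}.  The KL regularizer is
#' applied to this adjusted parameter so that only evidence for *wrong*
#' classes is shrunk towards the uniform Dirichlet.
#'
#' @param alpha A [dirichlet_evidence()] or a numeric alpha vector
#'   (entries >= 1).
#' @param y One-hot label vector of the same length.
#' @return A [dirichlet_evidence()] holding the adjusted parameter.
#' @examples
#' adjusted_alpha(c(5, 3), c(1, 0))$alpha  # c(1, 3)
#' @export
adjusted_alpha <- function(alpha, y) {
  a <- as_alpha(alpha)
  check_one_hot(y)
  if (length(y) != length(a)) stop("y and alpha lengths differ", call. = FALSE)
  at <- y + a * (1 - y)
  dirichlet_evidence(at - 1)
}

#' Weighted adjusted cross-entropy (closed digamma form)
#'
#' The expectation of the weighted cross-entropy
#' \eqn{-\sum_k w_k y_k \log p_k} under \eqn{p \sim Dirichlet(\alpha)} has the
#' closed form \eqn{\sum_k w_k y_k (\psi(S) - \psi(\alpha_k))} with
#' \eqn{\psi} the digamma function and \eqn{S} the Dirichlet strength.  It is
#' non-negative and strictly decreasing in the true-class evidence.
#'
#' @param alpha A [dirichlet_evidence()] or numeric alpha vector.
#' @param y One-hot label vector.
#' @param w Positive class weights (recycled scalar allowed).
#' @return Scalar loss.
#' @examples
#' wace_loss(c(1, 1), c(1, 0), c(1, 1))  # digamma(2) - digamma(1) = 1
#' @export
wace_loss <- function(alpha, y, w = 1) {
  a <- as_alpha(alpha)
  check_one_hot(y)
  w <- rep_len(as.numeric(w), length(a))
  if (any(w <= 0)) stop("class weights must be positive", call. = FALSE)
  S <- sum(a)
  sum(w * y * (digamma(S) - digamma(a)))
}

# d wace / d alpha
wace_grad <- function(alpha, y, w = 1) {
  a <- as_alpha(alpha)
  w <- rep_len(as.numeric(w), length(a))
  S <- sum(a)
  wt <- sum(w * y)                       # weight of the true class
  wt * trigamma(S) - w * y * trigamma(a)
}

#' KL divergence from an adjusted Dirichlet to the uniform Dirichlet
#'
#' \eqn{KL[D(p\,|\,\tilde\alpha)\,\|\,D(p\,|\,\mathbf 1)]} in closed form:
#' \deqn{\log\frac{\Gamma(\sum_k \tilde\alpha_k)}{\Gamma(K)\prod_k
#'   \Gamma(\tilde\alpha_k)} + \sum_k (\tilde\alpha_k - 1)
#'   [\psi(\tilde\alpha_k) - \psi(\textstyle\sum_k \tilde\alpha_k)].}
#' Zero iff \eqn{\tilde\alpha = \mathbf 1}.  The second term uses
#' \eqn{\tilde\alpha} throughout (the self-consistent form; anything else
#' would make the regularizer non-zero at its own target).
#'
#' @param alpha_tilde A [dirichlet_evidence()] or numeric vector with all
#'   entries >= 1 (an adjusted Dirichlet parameter).
#' @return Scalar KL divergence (>= 0).
#' @examples
#' kl_to_uniform(c(2, 1))  # log(2) - 0.5
#' @export
kl_to_uniform <- function(alpha_tilde) {
  at <- as_alpha(alpha_tilde)
  if (any(at < 1 - 1e-9)) {
    stop("adjusted alpha entries must be >= 1", call. = FALSE)
  }
  K <- length(at)
  S <- sum(at)
  lgamma(S) - lgamma(K) - sum(lgamma(at)) +
    sum((at - 1) * (digamma(at) - digamma(S)))
}

# d KL / d alpha_tilde  (simplifies to (at-1)*trigamma(at) - (S-K)*trigamma(S))
kl_grad <- function(alpha_tilde) {
  at <- as_alpha(alpha_tilde)
  S <- sum(at)
  (at - 1) * trigamma(at) - (S - length(at)) * trigamma(S)
}

#' Evidential loss of one classification head
#'
#' Sum of the weighted adjusted cross-entropy and the KL regularizer on the
#' adjusted Dirichlet parameter:
#' `wace_loss(alpha, y, w) + kl_weight * kl_to_uniform(adjusted_alpha(alpha, y))`.
#'
#' @inheritParams wace_loss
#' @param kl_weight Non-negative weight of the KL term (optionally annealed
#'   by the trainer).
#' @return Scalar loss.
#' @export
head_loss <- function(alpha, y, w = 1, kl_weight = 1) {
  stopifnot(kl_weight >= 0)
  l <- wace_loss(alpha, y, w)
  if (kl_weight > 0) {
    l <- l + kl_weight * kl_to_uniform(adjusted_alpha(alpha, y))
  }
  l
}

# d head_loss / d alpha (chain through the adjustment: d at/d a = 1 - y)
head_loss_grad <- function(alpha, y, w = 1, kl_weight = 1) {
  a <- as_alpha(alpha)
  g <- wace_grad(a, y, w)
  if (kl_weight > 0) {
    at <- y + a * (1 - y)
    g <- g + kl_weight * kl_grad(at) * (1 - y)
  }
  g
}

#' Stage-1 evidential loss over all heads
#'
#' Sums the per-head evidential loss over the N modality heads, the
#' feature-integration (FI) head and the decision-integration (DI) head
#' (N + 2 components).  Heads of modalities flagged missing for the sample
#' contribute zero.
#'
#' @param alphas Named list of N + 2 alpha vectors / [dirichlet_evidence()]
#'   objects: one per modality, plus `"FI"` and `"DI"` (DI obtained via
#'   [opinion_to_alpha()] of the fused opinion).
#' @param y One-hot label vector.
#' @param w Class weights.
#' @param kl_weight KL regularizer weight.
#' @param missing Character vector of head names masked out (missing
#'   modalities).
#' @return A `loss_breakdown` list with `per_head`, `match_backbone`,
#'   `match_head` and `total`.
#' @export
stage1_loss <- function(alphas, y, w = 1, kl_weight = 1,
                        missing = character()) {
  if (is.null(names(alphas)) || !all(c("FI", "DI") %in% names(alphas))) {
    stop("alphas must be a named list including 'FI' and 'DI' heads",
         call. = FALSE)
  }
  n_modal <- length(alphas) - 2L
  if (n_modal < 1L) stop("need N + 2 heads with N >= 1", call. = FALSE)
  per_head <- vapply(names(alphas), function(nm) {
    if (nm %in% missing) return(0)
    head_loss(alphas[[nm]], y, w, kl_weight)
  }, numeric(1))
  structure(
    list(per_head = per_head, match_backbone = 0, match_head = 0,
         total = sum(per_head)),
    class = "loss_breakdown"
  )
}

#' Hierarchical similarity-matching loss
#'
#' Matches a synthesized feature against its (constant) reference by a
#' point-wise mean-squared-error term plus a vector-wise cosine term:
#' \eqn{L = L_{MSE} + \lambda_{CS} (1 - \cos)}.  For 4-D backbone maps the
#' cosine is computed per channel over the flattened spatial positions and
#' averaged over channels; for head activations it is the cosine of the whole
#' vector.  Zero iff the features coincide.
#'
#' @param f_syn,f_ref Numeric arrays/vectors of identical shape; `f_ref` is a
#'   constant reference (no gradient flows to it).
#' @param lambda_cs Non-negative weight of the cosine term (default 5).
#' @return Scalar loss (>= 0).
#' @export
match_loss <- function(f_syn, f_ref, lambda_cs = 5) {
  match_loss_impl(f_syn, f_ref, lambda_cs, grad = FALSE)$loss
}

# Shared forward (+ optional gradient w.r.t. f_syn). Also reports the mean
# cosine similarity, which the trainer logs for the feature-alignment trend.
match_loss_impl <- function(f_syn, f_ref, lambda_cs = 5, grad = FALSE) {
  stopifnot(lambda_cs >= 0)
  ds <- dim(f_syn)
  if (!identical(dim(f_syn), dim(f_ref)) ||
      length(f_syn) != length(f_ref)) {
    stop("feature shapes differ", call. = FALSE)
  }
  n <- length(f_syn)
  diff <- f_syn - f_ref
  l_mse <- sum(diff^2) / n
  g <- if (grad) 2 * diff / n else NULL

  # channel structure: 4-D map -> per-channel cosine; otherwise whole vector
  if (!is.null(ds) && length(ds) == 4L) {
    nch <- ds[4L]
    sm <- matrix(f_syn, ncol = nch)
    rm_ <- matrix(f_ref, ncol = nch)
  } else {
    nch <- 1L
    sm <- matrix(as.numeric(f_syn), ncol = 1L)
    rm_ <- matrix(as.numeric(f_ref), ncol = 1L)
  }
  cs <- numeric(nch)
  gcs <- if (grad) matrix(0, nrow(sm), nch) else NULL
  for (c in seq_len(nch)) {
    x <- sm[, c]; r <- rm_[, c]
    nx <- sqrt(sum(x^2)); nr <- sqrt(sum(r^2))
    if (nx < 1e-12 || nr < 1e-12) {
      cs[c] <- 0  # defined as maximal dissimilarity
      message("match_loss: zero-norm feature; cosine term set to 1")
      next
    }
    cs[c] <- sum(x * r) / (nx * nr)
    if (grad) gcs[, c] <- -(r / (nx * nr) - cs[c] * x / nx^2)
  }
  l_cs <- mean(1 - cs)
  loss <- l_mse + lambda_cs * l_cs
  if (grad) {
    g <- g + lambda_cs * as.numeric(gcs) / nch
    if (!is.null(ds)) dim(g) <- ds
  }
  list(loss = loss, mse = l_mse, cos_term = l_cs, mean_cs = mean(cs), grad = g)
}

#' Stage-2 total loss
#'
#' \eqn{L_{S2} = L_{S1} + \lambda_B L_B + \lambda_H L_H}: the (scheduled)
#' stage-1 evidential loss plus backbone- and head-level similarity matching
#' between synthesized and reference features, each term a [match_loss()]
#' averaged over its pairs.
#'
#' @param stage1_terms A `loss_breakdown` from [stage1_loss()] (already
#'   masked per the half-epoch schedule).
#' @param backbone_pairs List of `list(syn =, ref =)` 16-channel backbone
#'   feature pairs, one per synthesized modality.
#' @param head_pairs List of `list(syn =, ref =)` FC activation pairs (FC1
#'   and FC2 of each synthesized modality).
#' @param weights List with `lambda_b`, `lambda_h`, `lambda_cs` (all >= 0).
#' @return A `loss_breakdown` with the match terms and combined total.
#' @export
stage2_loss <- function(stage1_terms, backbone_pairs, head_pairs,
                        weights = match_weights()) {
  stopifnot(inherits(stage1_terms, "loss_breakdown"))
  lb <- weights$lambda_b; lh <- weights$lambda_h; lcs <- weights$lambda_cs
  if (lb > 0 && length(backbone_pairs) == 0L) {
    stop("lambda_b > 0 but no backbone pairs supplied", call. = FALSE)
  }
  if (lh > 0 && length(head_pairs) == 0L) {
    stop("lambda_h > 0 but no head pairs supplied", call. = FALSE)
  }
  mean_match <- function(pairs) {
    if (length(pairs) == 0L) return(0)
    mean(vapply(pairs, function(p) match_loss(p$syn, p$ref, lcs), numeric(1)))
  }
  l_b <- mean_match(backbone_pairs)
  l_h <- mean_match(head_pairs)
  structure(
    list(per_head = stage1_terms$per_head, match_backbone = l_b,
         match_head = l_h,
         total = stage1_terms$total + lb * l_b + lh * l_h),
    class = "loss_breakdown"
  )
}

#' Matching-loss weights
#'
#' Defaults follow the reference hyperparameters: `lambda_cs = 5`,
#' `lambda_b = 1e-2`, `lambda_h = 2e-4`.
#'
#' @param lambda_b,lambda_h,lambda_cs Non-negative scalars.
#' @return A named list of class `match_weights`.
#' @export
match_weights <- function(lambda_b = 1e-2, lambda_h = 2e-4, lambda_cs = 5) {
  stopifnot(lambda_b >= 0, lambda_h >= 0, lambda_cs >= 0)
  structure(list(lambda_b = lambda_b, lambda_h = lambda_h,
                 lambda_cs = lambda_cs),
            class = "match_weights")
}
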