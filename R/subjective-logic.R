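#' Dirichlet evidence
#'
#' Wraps a vector of non-negative per-class evidence \eqn{e_k} together with
#' the Dirichlet parameters it induces, \eqn{\alpha_k = e_k + 1}, and the
#' Dirichlet strength \eqn{S = \sum_k \alpha_k}.  Evidence is the support a
#' classification head has accumulated for each class; zero evidence for all
#' classes is a valid (vacuous) state.
#'
#' @param evidence Numeric vector of length \eqn{K \ge 2}, all entries
#'   non-negative.
#' @return An object of class `dirichlet_evidence` with fields `evidence`,
#'   `alpha` and `strength`.
#' @examples
#' dirichlet_evidence(c(2, 0))
#' @export
dirichlet_evidence <- function(evidence) {
  evidence <- as.numeric(evidence)
  if (length(evidence) < 2L) {
    stop("evidence must have at least 2 classes", call. = FALSE)
  }
  neg <- which(evidence < 0)
  if (length(neg) > 0L) {
    stop(sprintf("negative evidence at index %s", paste(neg, collapse = ", ")),
         call. = FALSE)
  }
  alpha <- evidence + 1
  structure(
    list(evidence = evidence, alpha = alpha, strength = sum(alpha)),
    class = "dirichlet_evidence"
  )
}

#' @export
print.dirichlet_evidence <- function(x, ...) {
  cat("<dirichlet_evidence> K =", length(x$alpha),
      " S =", format(x$strength), "\n")
  cat("  alpha:", paste(format(x$alpha, digits = 4), collapse = " "), "\n")
  invisible(x)
}

# Coerce a plain numeric alpha vector (or evidence object) to alpha.
as_alpha <- function(x) {
  if (inherits(x, "dirichlet_evidence")) return(x$alpha)
  alpha <- as.numeric(x)
  if (any(alpha < 1 - 1e-12)) {
    stop("alpha entries must be >= 1", call. = FALSE)
  }
  alpha
}

#' Subjective opinion on the K-simplex
#'
#' A subjective-logic opinion assigns a belief mass \eqn{b_k \ge 0} to each of
#' the \eqn{K} classes and an uncertainty mass \eqn{u > 0} to "don't know",
#' with the simplex constraint \eqn{u + \sum_k b_k = 1}.  The uncertainty is
#' stored explicitly so that the simplex constraint remains an assertable
#' invariant rather than a definition.
#'
#' @param beliefs Numeric vector of per-class belief masses in `[0, 1]`.
#' @param uncertainty Scalar uncertainty mass in `(0, 1]`.
#' @return An object of class `subjective_opinion` with fields `beliefs`,
#'   `uncertainty` and `n_classes`.
#' @examples
#' subjective_opinion(c(0.5, 0), 0.5)
#' @export
subjective_opinion <- function(beliefs, uncertainty) {
  beliefs <- as.numeric(beliefs)
  uncertainty <- as.numeric(uncertainty)
  if (length(beliefs) < 2L) stop("need K >= 2 classes", call. = FALSE)
  if (any(beliefs < -1e-12)) stop("belief masses must be >= 0", call. = FALSE)
  if (length(uncertainty) != 1L || uncertainty <= 0) {
    stop("uncertainty mass must be a scalar > 0", call. = FALSE)
  }
  tot <- uncertainty + sum(beliefs)
  if (abs(tot - 1) > 1e-9) {
    stop(sprintf("u + sum(b) = %.12f; opinion must lie on the simplex", tot),
         call. = FALSE)
  }
  structure(
    list(beliefs = pmax(beliefs, 0), uncertainty = uncertainty,
         n_classes = length(beliefs)),
    class = "subjective_opinion"
  )
}

#' @export
print.subjective_opinion <- function(x, ...) {
  cat("<subjective_opinion> K =", x$n_classes, "\n")
  cat("  b:", paste(format(x$beliefs, digits = 4), collapse = " "),
      "  u:", format(x$uncertainty, digits = 4), "\n")
  invisible(x)
}

#' Convert Dirichlet evidence to a subjective opinion
#'
#' Belief masses are \eqn{b_k = (\alpha_k - 1)/S = e_k/S} and the uncertainty
#' mass is \eqn{u = K/S}, so that \eqn{u + \sum_k b_k = 1} holds exactly.
#' Zero total evidence yields the vacuous opinion (`u = 1`).
#'
#' @param evidence A [dirichlet_evidence()] object, or a numeric vector of
#'   non-negative evidence values.
#' @return A [subjective_opinion()].
#' @examples
#' evidence_to_opinion(dirichlet_evidence(c(2, 0)))
#' @export
evidence_to_opinion <- function(evidence) {
  if (!inherits(evidence, "dirichlet_evidence")) {
    evidence <- dirichlet_evidence(evidence)
  }
  K <- length(evidence$alpha)
  S <- evidence$strength
  subjective_opinion(beliefs = (evidence$alpha - 1) / S, uncertainty = K / S)
}

#' Recover Dirichlet parameters from a subjective opinion
#'
#' Inverse of [evidence_to_opinion()]: \eqn{S = K/u} and
#' \eqn{\alpha_k = b_k S + 1}.  Needed to feed a fused (decision-integration)
#' opinion back into the evidential loss, which is defined on Dirichlet
#' parameters.
#'
#' @param op A [subjective_opinion()].
#' @return A [dirichlet_evidence()].
#' @examples
#' opinion_to_alpha(subjective_opinion(c(0.5, 0), 0.5))
#' @export
opinion_to_alpha <- function(op) {
  stopifnot(inherits(op, "subjective_opinion"))
  if (op$uncertainty <= 0) {
    stop("uncertainty must be > 0; the inverse map is undefined at u = 0",
         call. = FALSE)
  }
  S <- op$n_classes / op$uncertainty
  dirichlet_evidence(op$beliefs * S)
}

# ---- Dempster's combination rule -------------------------------------------

# Numeric core on (b, u) pairs; returns list(b, u, conflict).
ds_pair_num <- function(b1, u1, b2, u2) {
  conflict <- sum(b1) * sum(b2) - sum(b1 * b2)
  bnum <- b1 * b2 + b1 * u2 + b2 * u1
  unum <- u1 * u2
  # the total retained mass equals 1 - C algebraically; dividing by the
  # directly-computed total keeps the simplex closed to the last bit even
  # when C is close to 1
  denom <- sum(bnum) + unum
  if (denom < 1e-12) {
    stop(sprintf("total conflict (C = %.6f); masses are not combinable",
                 conflict), call. = FALSE)
  }
  list(b = bnum / denom, u = unum / denom, conflict = conflict,
       denom = denom)
}

# Vector-Jacobian product of ds_pair_num.  Given upstream gradients (db, du)
# of the combined mass, returns gradients w.r.t. both input masses.  Used by
# the trainer to differentiate through the decision-integration fold.
ds_pair_vjp <- function(b1, u1, b2, u2, out, db, du) {
  denom <- out$denom
  g <- (sum(db * out$b) + du * out$u) / denom
  list(
    db1 = db * (b2 + u2) / denom + g * (sum(b2) - b2),
    du1 = sum(db * b2) / denom + du * u2 / denom,
    db2 = db * (b1 + u1) / denom + g * (sum(b1) - b1),
    du2 = sum(db * b1) / denom + du * u1 / denom
  )
}

#' Combine two subjective opinions with Dempster's rule
#'
#' Reduced Dempster-Shafer combination for mass functions with support on the
#' \eqn{K} singletons plus the whole frame: the combined belief is
#' \eqn{b_k = (b_k^1 b_k^2 + b_k^1 u^2 + b_k^2 u^1) / (1 - C)} and the
#' combined uncertainty \eqn{u = u^1 u^2 / (1 - C)}, where the conflict
#' \eqn{C = \sum_{i \ne j} b_i^1 b_j^2} is the total mass the two sources
#' assign to incompatible classes.
#'
#' @param m1,m2 [subjective_opinion()] objects over the same K classes.
#' @return The combined [subjective_opinion()].
#' @examples
#' m <- subjective_opinion(c(0.5, 0), 0.5)
#' dempster_combine_pair(m, m)
#' @export
dempster_combine_pair <- function(m1, m2) {
  stopifnot(inherits(m1, "subjective_opinion"),
            inherits(m2, "subjective_opinion"))
  if (m1$n_classes != m2$n_classes) {
    stop(sprintf("opinions have different K (%d vs %d)",
                 m1$n_classes, m2$n_classes), call. = FALSE)
  }
  res <- ds_pair_num(m1$beliefs, m1$uncertainty, m2$beliefs, m2$uncertainty)
  subjective_opinion(res$b, res$u)
}

#' Fuse a collection of opinions into a decision
#'
#' Left-fold of [dempster_combine_pair()] over an ordered collection of
#' opinions; the rule is commutative and associative on this representation,
#' so the result is order-invariant up to floating-point noise.  The class
#' with the largest combined belief is the decision (ties break to the lowest
#' class index) and the combined uncertainty mass is the final classification
#' uncertainty.
#'
#' @param opinions A non-empty list of [subjective_opinion()] objects sharing
#'   the same K.
#' @return An object of class `fusion_result` with fields `combined` (the
#'   fused [subjective_opinion()]), `label` (0-based index of the class with
#'   largest belief) and `final_uncertainty`.
#' @examples
#' ops <- replicate(3, subjective_opinion(c(0.5, 0), 0.5), simplify = FALSE)
#' dempster_combine_all(ops)
#' @export
dempster_combine_all <- function(opinions) {
  if (!is.list(opinions) || length(opinions) == 0L) {
    stop("need at least one opinion to fuse", call. = FALSE)
  }
  acc <- opinions[[1L]]
  stopifnot(inherits(acc, "subjective_opinion"))
  if (length(opinions) > 1L) {
    for (i in 2:length(opinions)) {
      acc <- dempster_combine_pair(acc, opinions[[i]])
    }
  }
  structure(
    list(combined = acc,
         label = which.max(acc$beliefs) - 1L,
         final_uncertainty = acc$uncertainty),
    class = "fusion_result"
  )
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("<fusion_result> label =", x$label,
      " u =", format(x$final_uncertainty, digits = 4), "\n")
  print(x$combined)
  invisible(x)
}

# ---- differentiable fold (plain numerics, used by the trainer) -------------

# bs: list of belief vectors; us: numeric vector of uncertainties.
# Returns list(b, u, steps) where steps holds the intermediates needed by
# ds_fold_bwd.
ds_fold_fwd <- function(bs, us) {
  n <- length(bs)
  acc_b <- bs[[1L]]
  acc_u <- us[[1L]]
  steps <- vector("list", if (n > 1L) n - 1L else 0L)
  if (n > 1L) {
    for (i in 2:n) {
      out <- ds_pair_num(acc_b, acc_u, bs[[i]], us[[i]])
      steps[[i - 1L]] <- list(acc_b = acc_b, acc_u = acc_u, out = out)
      acc_b <- out$b
      acc_u <- out$u
    }
  }
  list(b = acc_b, u = acc_u, steps = steps)
}

# Upstream gradients (db, du) of the fused mass -> per-source gradients.
ds_fold_bwd <- function(fwd, bs, us, db, du) {
  n <- length(bs)
  dbs <- vector("list", n)
  dus <- numeric(n)
  if (n == 1L) {
    dbs[[1L]] <- db
    dus[1L] <- du
    return(list(dbs = dbs, dus = dus))
  }
  for (i in seq(n, 2L)) {
    st <- fwd$steps[[i - 1L]]
    vj <- ds_pair_vjp(st$acc_b, st$acc_u, bs[[i]], us[[i]], st$out, db, du)
    dbs[[i]] <- vj$db2
    dus[i] <- vj$du2
    db <- vj$db1
    du <- vj$du1
  }
  dbs[[1L]] <- db
  dus[1L] <- du
  list(dbs = dbs, dus = dus)
}

# VJP of alpha -> opinion (b = (alpha-1)/S, u = K/S).
opinion_from_alpha_vjp <- function(alpha, db, du) {
  S <- sum(alpha)
  b <- (alpha - 1) / S
  u <- length(alpha) / S
  db / S - (sum(db * b) + du * u) / S
}

# VJP of opinion -> alpha (alpha = b*K/u + 1), upstream dalpha.
alpha_from_opinion_vjp <- function(b, u, dalpha) {
  K <- length(b)
  list(db = dalpha * K / u,
       du = -(K / u^2) * sum(dalpha * b))
}
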