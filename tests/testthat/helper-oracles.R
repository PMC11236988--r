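# Independent oracles and small fixtures used across the suite.

# ---- generic power-set Dempster-Shafer combiner ----------------------------
# Frames are represented as bitmasks over K singletons; a mass function is a
# named numeric vector mass[bitmask].  This is a full power-set combiner
# (arbitrary focal sets), used as the independent oracle for the reduced
# singleton + Theta combination rule.

ds_powerset_combine <- function(m1, m2) {
  out <- new.env()
  conflict <- 0
  for (a in names(m1)) {
    for (b in names(m2)) {
      inter <- bitwAnd(as.integer(a), as.integer(b))
      w <- m1[[a]] * m2[[b]]
      if (inter == 0L) {
        conflict <- conflict + w
      } else {
        key <- as.character(inter)
        out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + w
      }
    }
  }
  masses <- mget(ls(out), envir = out)
  masses <- lapply(masses, function(x) x / (1 - conflict))
  list(masses = masses, conflict = conflict)
}

# Express a subjective opinion as a power-set mass function: mass on each
# singleton {k} (bit 2^(k-1)) plus the whole frame Theta.
opinion_to_masses <- function(op) {
  K <- op$n_classes
  m <- as.list(op$beliefs)
  names(m) <- as.character(2^(seq_len(K) - 1L))
  m[[as.character(2^K - 1L)]] <- op$uncertainty
  m
}

masses_to_opinion <- function(masses, K) {
  b <- vapply(seq_len(K), function(k) {
    key <- as.character(2^(k - 1L))
    if (is.null(masses[[key]])) 0 else masses[[key]]
  }, numeric(1))
  u <- masses[[as.character(2^K - 1L)]]
  list(beliefs = b, uncertainty = if (is.null(u)) 0 else u)
}

# Random valid opinion: (b_1..b_K, u) ~ Dirichlet(1) over the (K+1)-simplex,
# with a floor on u so opinion_to_alpha stays defined.
random_opinion <- function(K) {
  repeat {
    g <- stats::rgamma(K + 1L, shape = 1)
    p <- g / sum(g)
    if (p[K + 1L] > 1e-3) {
      return(subjective_opinion(p[seq_len(K)], p[K + 1L]))
    }
  }
}

# ---- numeric oracles for the evidential losses -----------------------------

# Monte-Carlo estimate of E[-sum w_k y_k log p_k], p ~ Dirichlet(alpha).
mc_wace <- function(alpha, y, w, n_draws) {
  K <- length(alpha)
  g <- matrix(stats::rgamma(n_draws * K, shape = rep(alpha, each = n_draws)),
              n_draws, K)
  p <- g / rowSums(g)
  vals <- -log(p[, which(y == 1)]) * sum(w * y)
  c(mean = mean(vals), se = stats::sd(vals) / sqrt(n_draws))
}

# KL(Beta(a1, a2) || Beta(1, 1)) by numerical integration.
numeric_kl_beta <- function(a) {
  f <- function(p) {
    d <- stats::dbeta(p, a[1], a[2])
    ifelse(d > 0, d * log(d), 0)   # log density of Beta(1,1) is 0
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
}

# ---- small fixtures --------------------------------------------------------

tiny_backbone <- function(cascaded = FALSE) {
  backbone_spec(channels = c(2L, 4L, 4L), strides = c(1L, 2L, 2L),
                squeeze_channels = 4L, cascaded_convs = cascaded)
}

tiny_cohort <- function(n = 16, noise_sd = 2, seed = 7, n_modalities = 2,
                        effects = c(0.5, 1)[seq_len(n_modalities)],
                        missing_rate = rep(0, n_modalities)) {
  spec <- cohort_spec(n_subjects = n, n_modalities = n_modalities,
                      volume_shape = rep(16L, 3L), prevalence = 0.5,
                      modality_effect_sizes = effects, noise_sd = noise_sd,
                      missing_rate = missing_rate, seed = seed)
  assign_folds(generate_cohort(spec), k = 4L, seed = seed)
}

tiny_train_config <- function(stage, epochs = 2, seed = 3, ...) {
  train_config(stage, epochs = epochs, batch_size = 4L,
               backbone = tiny_backbone(), hidden = 8L, seed = seed,
               k = 4L, test_fold = 0L, val_fold = 1L, ...)
}
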