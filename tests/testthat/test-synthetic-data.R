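test_that("cohort generation is seed-reproducible and spec-faithful", {
  spec <- cohort_spec(n_subjects = 8, n_modalities = 2,
                      volume_shape = rep(16L, 3L),
                      modality_effect_sizes = c(0.5, 1), seed = 33)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_length(c1, 8)
  for (i in seq_along(c1)) {
    expect_identical(c1[[i]]$volumes, c2[[i]]$volumes)
    expect_identical(c1[[i]]$label, c2[[i]]$label)
  }
  expect_true(all(vapply(c1, function(s)
    all(dim(s$volumes$mod1) == 16), logical(1))))
})

test_that("realized prevalence stays within its binomial bounds", {
  spec <- cohort_spec(n_subjects = 200, n_modalities = 1,
                      volume_shape = rep(16L, 3L), prevalence = 0.4,
                      modality_effect_sizes = 1, seed = 7)
  coh <- generate_cohort(spec)
  npos <- sum(vapply(coh, `[[`, numeric(1), "label"))
  bounds <- stats::qbinom(c(0.005, 0.995), 200, 0.4)
  expect_gte(npos, bounds[1])
  expect_lte(npos, bounds[2])
})

test_that("modality templates are fixed, disjoint, class-0 volumes unloaded", {
  spec <- cohort_spec(n_subjects = 40, n_modalities = 3,
                      volume_shape = rep(32L, 3L), seed = 11)
  tmpl <- mmfe:::build_templates(spec)
  expect_length(tmpl, 3)
  # pairwise disjoint blobs
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(sum(tmpl[[i]] * tmpl[[j]]), 0)
  }
  expect_true(all(vapply(tmpl, sum, numeric(1)) > 0))

  # class-0 volumes carry no template signal: mean template correlation
  # within 3 SE of zero over the cohort
  coh <- generate_cohort(spec)
  lab <- vapply(coh, `[[`, numeric(1), "label")
  crls <- vapply(which(lab == 0), function(i)
    cor(as.numeric(coh[[i]]$volumes$mod2), as.numeric(tmpl$mod2)),
    numeric(1))
  expect_lt(abs(mean(crls)), 3 * stats::sd(crls) / sqrt(length(crls)))
})

test_that("missingness honors per-modality rates", {
  spec <- cohort_spec(n_subjects = 150, n_modalities = 2,
                      volume_shape = rep(16L, 3L),
                      modality_effect_sizes = c(1, 1),
                      missing_rate = c(0, 0.3), seed = 19)
  coh <- generate_cohort(spec)
  n_miss <- vapply(c("mod1", "mod2"), function(m)
    sum(vapply(coh, function(s) m %in% s$missing, logical(1))), numeric(1))
  expect_identical(unname(n_miss[1]), 0)
  bounds <- stats::qbinom(c(0.005, 0.995), 150, 0.3)
  expect_gte(n_miss[2], bounds[1])
  expect_lte(n_miss[2], bounds[2])
  # missing volumes are absent
  miss_idx <- which(vapply(coh, function(s) "mod2" %in% s$missing, logical(1)))
  expect_true(all(vapply(coh[miss_idx], function(s)
    is.null(s$volumes$mod2), logical(1))))
})

test_that("oracle AUC is monotone in the modality subset and effect size", {
  # a high-noise spec keeps the oracle away from its saturation at 1,
  # where strict monotonicity is invisible at double precision
  spec <- cohort_spec(volume_shape = rep(32L, 3L), noise_sd = 8, seed = 1)
  expect_equal(oracle_bayes_auc(spec, character()), 0.5)
  a1 <- oracle_bayes_auc(spec, "mod1")
  a_all <- oracle_bayes_auc(spec, spec$modality_names)
  expect_gt(a1, 0.5)
  expect_gt(a_all, a1)   # complementary templates: the premise behind SI < MI

  spec2 <- spec
  spec2$modality_effect_sizes <- spec$modality_effect_sizes * 2
  expect_gt(oracle_bayes_auc(spec2, "mod1"), a1)
  expect_error(oracle_bayes_auc(spec, "pet"), "unknown modality")

  # matches the Gaussian ROC closed form for a known template energy
  tmpl <- mmfe:::build_templates(spec)
  d <- spec$modality_effect_sizes[1] * sqrt(sum(tmpl$mod1)) / spec$noise_sd
  expect_equal(a1, pnorm(d / sqrt(2)))
})

test_that("zero effect sizes give an uninformative cohort", {
  spec <- cohort_spec(n_subjects = 30, n_modalities = 2,
                      volume_shape = rep(16L, 3L),
                      modality_effect_sizes = c(0, 0), seed = 3)
  expect_equal(oracle_bayes_auc(spec, c("mod1", "mod2")), 0.5)
  coh <- generate_cohort(spec)
  tmpl <- mmfe:::build_templates(spec)
  lab <- vapply(coh, `[[`, numeric(1), "label")
  # blob-mean difference between classes is noise-level only
  bm <- vapply(coh, function(s)
    mean(s$volumes$mod1[tmpl$mod1 > 0]), numeric(1))
  expect_gt(t.test(bm[lab == 1], bm[lab == 0])$p.value, 0.001)
})

test_that("misregistration translates auxiliary modalities only", {
  base <- cohort_spec(n_subjects = 4, n_modalities = 2,
                      volume_shape = rep(16L, 3L),
                      modality_effect_sizes = c(1, 1), noise_sd = 1e-8,
                      misregistration_voxels = 0L, seed = 5)
  shifted <- base
  shifted$misregistration_voxels <- 2L
  c0 <- generate_cohort(base)
  c1 <- generate_cohort(shifted)
  # the acquired modality is untouched by the misregistration knob
  expect_equal(c0[[1]]$volumes$mod1, c1[[1]]$volumes$mod1, tolerance = 1e-6)
})

test_that("cohort_spec rejects invalid parameters", {
  expect_error(cohort_spec(prevalence = 1.2), "prevalence")
  expect_error(cohort_spec(modality_effect_sizes = c(1, -1, 1)),
               "non-negative")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(missing_rate = c(0, 0, 1)), "missing_rate")
})
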