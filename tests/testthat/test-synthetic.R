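# Synthetic cohort generator: phenotypes, BOLD, FA.

test_that("phenotype tables respect ranges, types and determinism", {
  cfg <- cohort_config(seed = 1)
  ph <- generate_phenotypes(cfg)
  expect_equal(nrow(ph), 127L)
  expect_true(all(ph$age >= 18 & ph$age <= 65))
  expect_true(all(ph$assq >= 0 & ph$assq <= 39))
  expect_true(all(ph$srs >= 0 & ph$srs <= 195))
  expect_true(all(levels(ph$gender) == c("female", "male")))
  expect_identical(ph, generate_phenotypes(cohort_config(seed = 1)))
  expect_false(identical(ph, generate_phenotypes(cohort_config(seed = 2))))
  expect_error(generate_phenotypes(cohort_config(n_subjects = 5)),
               "n_subjects")
  expect_error(cohort_config(n_subjects = 0), "positive")
})

test_that("phenotype correlation targets hold at reference scales", {
  # working-cohort scale, reference seed
  ph <- generate_phenotypes(cohort_config(seed = 1))
  expect_gt(cor(ph$verbal_iq, ph$performance_iq), 0.45)
  expect_lt(cor(ph$verbal_iq, ph$performance_iq), 0.65)
  # large-n convergence of the copula calibration
  ph2 <- generate_phenotypes(cohort_config(n_subjects = 5000, seed = 2))
  expect_equal(cor(ph2$verbal_iq, ph2$assq), -0.393, tolerance = 0.03)
  expect_equal(cor(ph2$verbal_iq, ph2$srs), -0.343, tolerance = 0.05)
  expect_equal(cor(ph2$verbal_iq, ph2$performance_iq), 0.55,
               tolerance = 0.05)
  # the generator is unbiased at n = 127: seed-averaged correlations sit
  # on the targets even though single cohorts scatter around them
  r <- vapply(1:20, function(s) {
    p <- generate_phenotypes(cohort_config(seed = s))
    c(cor(p$verbal_iq, p$performance_iq), cor(p$verbal_iq, p$assq),
      cor(p$verbal_iq, p$srs))
  }, numeric(3))
  expect_equal(rowMeans(r), c(0.55, -0.393, -0.343), tolerance = 0.05)
  # ASSQ is right-skewed, SRS roughly symmetric
  skew <- function(x) mean(((x - mean(x)) / sd(x))^3)
  expect_gt(skew(ph2$assq), 1)
  expect_lt(abs(skew(ph2$srs)), 0.6)
})

test_that("BOLD generation is seeded, shaped and phenotype-checked", {
  cfg <- tiny_cohort(seed = 7)
  ph <- generate_phenotypes(cfg)
  bold <- generate_bold(cfg, ph)
  expect_length(bold, cfg$n_subjects)
  expect_equal(dim(bold[[1]]), c(20L, 120L))
  expect_equal(rownames(bold[[3]]), cfg$region_names)
  expect_identical(bold, generate_bold(cfg, ph))
  expect_error(generate_bold(cfg, ph[1:5, ]), "phenotype")
})

test_that("with zero effects the BOLD data are independent of the traits", {
  cfg <- tiny_cohort(
    seed = 8, n_subjects = 10,
    effect_sizes = list(hub_degree = 0, local_efficiency = 0, fa = 0)
  )
  ph1 <- generate_phenotypes(cfg)
  ph2 <- ph1
  ph2$assq <- rev(ph2$assq) # different trait scores, same subjects
  ph2$srs <- rev(ph2$srs)
  expect_identical(generate_bold(cfg, ph1), generate_bold(cfg, ph2))
})

test_that("two regions sharing one community approach r = 1 without noise", {
  cfg <- cohort_config(
    n_subjects = 10, n_regions = 2, n_timepoints = 260,
    module_partition = c(1, 1), hub_region = 1, fa_effect_regions = 2,
    global_strength = 0, noise_sd = 1e-6,
    effect_sizes = list(hub_degree = 0, local_efficiency = 0, fa = 0),
    seed = 3
  )
  ph <- generate_phenotypes(cfg)
  bold <- generate_bold(cfg, ph)
  r <- build_connectivity(bold[[1]])$correlation$r[1, 2]
  expect_gt(r, 0.999)
})

test_that("the injected hub effect lowers hub coupling with the trait", {
  cfg <- cohort_config(n_subjects = 60, n_regions = 24,
                       n_communities = 4, n_timepoints = 260, seed = 13)
  ph <- generate_phenotypes(cfg)
  bold <- generate_bold(cfg, ph)
  trait <- combined_trait_score(ph)
  hub_mean_w <- vapply(bold, function(b) {
    w <- build_connectivity(b)$network$w
    mean(w[cfg$hub_region, -cfg$hub_region])
  }, numeric(1))
  expect_lt(cor(trait, hub_mean_w), -0.3)
})

test_that("FA tables are reproducible, bounded and slope-faithful", {
  cfg <- tiny_cohort(seed = 9, n_subjects = 20)
  ph <- generate_phenotypes(cfg)
  fa <- generate_fa(cfg, ph)$fa
  expect_identical(fa, generate_fa(cfg, ph)$fa)
  expect_true(all(fa > 0 & fa < 1))
  # zero slope: no trait correlation beyond sampling noise (n = 500)
  cfg0 <- cohort_config(
    n_subjects = 500, n_regions = 10, seed = 10,
    effect_sizes = list(hub_degree = 0, local_efficiency = 0, fa = 0)
  )
  ph0 <- generate_phenotypes(cfg0)
  fa0 <- generate_fa(cfg0, ph0)$fa
  trait0 <- combined_trait_score(ph0)
  expect_true(all(abs(cor(trait0, fa0)) < 0.15))
  # negative slope recovered by the GLM in the designated regions
  cfg1 <- cohort_config(
    n_subjects = 500, n_regions = 10, seed = 10,
    effect_sizes = list(hub_degree = 0, local_efficiency = 0, fa = -0.4)
  )
  ph1 <- generate_phenotypes(cfg1)
  fa1 <- generate_fa(cfg1, ph1)$fa
  res <- run_regional_association(fa1, ph1, glm_design(1))
  expect_true(all(res$b_assq[cfg1$fa_effect_regions] < 0))
  expect_true(all(res$fdr_significant[cfg1$fa_effect_regions]))
})

test_that("child seeds derived from one master seed are stable and distinct", {
  expect_identical(derive_seed(1, 3), derive_seed(1, 3))
  expect_false(derive_seed(1, 3) == derive_seed(1, 4))
  expect_false(derive_seed(1, c(3, 5)) == derive_seed(1, c(5, 3)))
  expect_true(derive_seed(2^30, 999) < 2^31)
})
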