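# Unit tests for the synthetic cohort generator.

test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(r_within = 0.2, r_between = 0.5), "r_between")
  expect_error(cohort_spec(r_within = 1.0), "r_within")
  expect_error(cohort_spec(effect_within_b = 0), "positive")
  expect_error(cohort_spec(effect_within_b = 2.5, r_within = 0.5), "below 1")
  expect_error(cohort_spec(n_group_a = 0), "positive")
  expect_error(cohort_spec(n_regions = 12, module_assignment = rep(1, 5)),
               "module_assignment")
})

test_that("independence and uniform-block covariance limits are exact", {
  # r_within = r_between = 0 -> diagonal covariance
  sp <- cohort_spec(n_regions = 6, module_assignment = rep(1:2, each = 3),
                    r_within = 0, r_between = 0, volume_sd = 2)
  expect_equal(build_target_covariance(sp, "A"), diag(4, 6), tolerance = 1e-12)
  # one module -> all off-diagonals r_within * sd^2
  sp1 <- cohort_spec(n_regions = 3, module_assignment = rep(1, 3),
                     r_within = 0.7, r_between = 0, volume_sd = 1)
  expected <- matrix(0.7, 3, 3); diag(expected) <- 1
  expect_equal(build_target_covariance(sp1, "A"), expected, tolerance = 1e-12)
})

test_that("target covariance is block-patterned, PSD, and scaled for group B", {
  sp <- cohort_spec(n_regions = 6, module_assignment = rep(1:2, each = 3),
                    r_within = 0.6, r_between = 0.1, effect_within_b = 0.5)
  sa <- build_target_covariance(sp, "A")
  sb <- build_target_covariance(sp, "B")
  expect_equal(sa[1, 2], 0.6, tolerance = 1e-12)
  expect_equal(sa[1, 4], 0.1, tolerance = 1e-12)
  expect_equal(sb[1, 2], 0.3, tolerance = 1e-12)   # within scaled by 0.5
  expect_equal(sb[1, 4], 0.1, tolerance = 1e-12)   # between untouched
  expect_gte(min(eigen(sa, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_gte(min(eigen(sb, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("same spec and seed give bit-identical cohorts", {
  sp <- cohort_spec(n_group_a = 8, n_group_b = 8, n_regions = 12,
                    module_assignment = rep(1:2, each = 6), seed = 99)
  expect_identical(generate_cohort(sp), generate_cohort(sp))
  sp2 <- cohort_spec(n_group_a = 8, n_group_b = 8, n_regions = 12,
                     module_assignment = rep(1:2, each = 6), seed = 100)
  expect_false(identical(generate_cohort(sp)$tiv, generate_cohort(sp2)$tiv))
})

test_that("cohort table satisfies its structural invariants", {
  coh <- generate_cohort(cohort_spec(n_group_a = 10, n_group_b = 7, seed = 3))
  expect_s3_class(coh, "scn_cohort")
  expect_equal(nrow(coh), 17)
  expect_setequal(unique(coh$group), c("A", "B"))
  vols <- coh[, as.character(attr(coh, "atlas"))]
  expect_true(all(vols > 0))
  expect_equal(ncol(vols), 90)
  expect_false(anyDuplicated(coh$subject_id) > 0)
})

test_that("TIV confound has the configured slope and residualization removes it", {
  sp <- cohort_spec(n_group_a = 2000, n_group_b = 2, n_regions = 10,
                    module_assignment = rep(1:2, each = 5),
                    tiv_beta = 0.004, demographics = FALSE, seed = 8)
  coh <- generate_cohort(sp)
  a <- coh[coh$group == "A", ]
  vols <- as.matrix(a[, as.character(attr(coh, "atlas"))])
  # raw volumes correlate with TIV; slope recovers tiv_beta
  slopes <- apply(vols, 2, function(v) stats::coef(stats::lm(v ~ a$tiv))[2])
  expect_equal(unname(mean(slopes)), 0.004, tolerance = 0.05)
  res <- residualize_tiv(structure(a, atlas = attr(coh, "atlas"),
                                   class = c("scn_cohort", "data.frame")))
  expect_true(all(abs(cor(t(res), a$tiv)) < 1e-10))
})

test_that("with tiv_beta = 0 volumes are uncorrelated with TIV at large n", {
  sp <- cohort_spec(n_group_a = 2000, n_group_b = 2, n_regions = 8,
                    module_assignment = rep(1:2, each = 4),
                    tiv_beta = 0, demographics = FALSE, seed = 21)
  coh <- generate_cohort(sp)
  a <- coh[coh$group == "A", ]
  vols <- as.matrix(a[, as.character(attr(coh, "atlas"))])
  expect_true(all(abs(cor(vols, a$tiv)) < 0.05))
})

test_that("large-sample within-module correlation recovers the target", {
  sp <- cohort_spec(n_group_a = 2000, n_group_b = 2, n_regions = 6,
                    module_assignment = rep(1, 6), r_within = 0.7,
                    r_between = 0, tiv_beta = 0, demographics = FALSE, seed = 5)
  coh <- generate_cohort(sp)
  vols <- as.matrix(coh[coh$group == "A", as.character(attr(coh, "atlas"))])
  r <- cor(vols)
  expect_equal(mean(r[upper.tri(r)]), 0.7, tolerance = 0.03)
})

test_that("demographics are exactly matched for equal group sizes", {
  coh <- generate_cohort(cohort_spec(seed = 13))
  a <- coh[coh$group == "A", ]; b <- coh[coh$group == "B", ]
  expect_identical(a$age, b$age)
  expect_identical(a$sex, b$sex)
  expect_identical(a$education, b$education)
  expect_equal(sum(a$sex == "male"), 22)   # 49 subjects, 44.9% male
})

test_that("ring-structured covariance decays with circular distance", {
  sp <- cohort_spec(n_regions = 10, structure = "ring", r_within = 0.6,
                    ring_decay = 0.9, seed = 1)
  s <- build_target_covariance(sp, "A")
  expect_equal(s[1, 2], 0.6, tolerance = 1e-9)           # distance 1
  expect_equal(s[1, 3], 0.6 * 0.9, tolerance = 1e-9)     # distance 2
  expect_equal(s[1, 10], 0.6, tolerance = 1e-9)          # wraps around
  expect_gt(s[1, 2], s[1, 5])
})
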