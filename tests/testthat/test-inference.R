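# Unit tests for AUC, BH-FDR, the permutation engine, and demographic tests.

test_that("auc computes the trapezoid integral and validates inputs", {
  g <- density_grid(0.1, 0.5, 0.2)     # points 0.1 0.3 0.5
  expect_equal(auc(c(1, 1, 1), g), 0.4, tolerance = 1e-12)
  expect_equal(auc(c(0, 1, 0), g), 0.4 / 2, tolerance = 1e-12)
  # linear curve: exact for the trapezoid rule
  expect_equal(auc(c(1, 2, 3), density_grid(0.5, 1, 0.25)), 1, tolerance = 1e-12)
  expect_error(auc(c(1, 2), g), "3 points")
  expect_error(auc(c(1, NA, 3), g), "missing")
})

test_that("bh_fdr matches the textbook step-up on random vectors", {
  set.seed(201)
  for (rep in 1:50) {
    m <- sample(1:40, 1)
    p <- stats::runif(m)
    expect_identical(bh_fdr(p), oracle_bh(p))
    expect_true(all(bh_fdr(p) >= p))
  }
  expect_error(bh_fdr(c(0.5, 0)), "in \\(0, 1\\]")
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("permutation p-values use the add-one rule and are valid", {
  coh <- generate_cohort(cohort_spec(n_group_a = 30, n_group_b = 30,
                                     n_regions = 20,
                                     module_assignment = rep(1:4, each = 5),
                                     r_within = 0.6, r_between = 0.2, seed = 55))
  cfg <- perm_config(n_perm = 19, seed = 7,
                     grid = density_grid(0.35, 0.5, 0.075), n_null = 3)
  res <- permutation_test(coh, cfg)
  denom <- 20
  all_p <- c(res$auc_p, as.vector(res$per_density_p), res$nodal$p_raw)
  expect_true(all(all_p >= 1 / denom & all_p <= 1))
  # every p is k/denom for integer k
  expect_true(all(abs(all_p * denom - round(all_p * denom)) < 1e-9))
  expect_true(all(res$nodal$p_fdr >= res$nodal$p_raw))
  expect_identical(res$group_levels, c("A", "B"))
  # diffs are B minus A
  expect_equal(res$auc_diff, res$auc_b - res$auc_a, tolerance = 1e-12)
})

test_that("the permutation test is deterministic under a fixed seed", {
  coh <- generate_cohort(cohort_spec(n_group_a = 30, n_group_b = 30,
                                     n_regions = 20,
                                     module_assignment = rep(1:4, each = 5),
                                     r_within = 0.6, r_between = 0.2, seed = 60))
  cfg <- perm_config(n_perm = 9, seed = 11,
                     grid = density_grid(0.35, 0.5, 0.075), n_null = 3)
  r1 <- permutation_test(coh, cfg)
  r2 <- permutation_test(coh, cfg)
  expect_identical(r1, r2)
  cfg2 <- perm_config(n_perm = 9, seed = 12,
                      grid = density_grid(0.35, 0.5, 0.075), n_null = 3)
  r3 <- permutation_test(coh, cfg2)
  expect_false(identical(r1$auc_p, r3$auc_p) && identical(r1$nodal, r3$nodal))
})

test_that("duplicated-group cohorts give p = 1 everywhere", {
  # identical volumes in both groups: every permuted split reproduces the
  # observed difference of exactly zero, so all p-values must be 1
  coh <- generate_cohort(cohort_spec(n_group_a = 30, n_group_b = 30,
                                     n_regions = 20,
                                     module_assignment = rep(1:4, each = 5),
                                     r_within = 0.6, r_between = 0.2, seed = 77))
  atlas_labels <- as.character(attr(coh, "atlas"))
  a_rows <- coh[coh$group == "A", ]
  dup <- a_rows
  dup$group <- "B"
  dup$subject_id <- sub("^A", "B", dup$subject_id)
  both <- rbind(a_rows, dup)
  attr(both, "atlas") <- attr(coh, "atlas")
  class(both) <- class(coh)
  cfg <- perm_config(n_perm = 19, seed = 5,
                     grid = density_grid(0.35, 0.5, 0.075), n_null = 3)
  res <- permutation_test(both, cfg)
  expect_true(all(res$auc_p == 1))
  expect_true(all(res$per_density_p == 1))
  expect_true(all(res$nodal$p_raw == 1))
  expect_equal(res$auc_diff, stats::setNames(rep(0, 10), names(res$auc_diff)),
               tolerance = 1e-12)
})

test_that("demographic tests run the advertised procedures", {
  coh <- generate_cohort(cohort_spec(seed = 19))
  dm <- demographic_matching(coh)
  expect_identical(dm$variable, c("sex", "age", "education"))
  expect_identical(dm$test, c("chi-square", "t-test", "rank-sum"))
  # groups are exactly matched by construction
  expect_equal(dm$statistic[1], 0, tolerance = 1e-12)
  expect_equal(dm$p[1], 1, tolerance = 1e-12)
  expect_equal(dm$p[2], 1, tolerance = 1e-12)
  coh$age <- NULL
  expect_error(demographic_matching(coh), "age")
})

test_that("disconnected observed networks are refused with a hint", {
  # two modules with zero between-correlation: the graph at low density has
  # two components
  coh <- generate_cohort(cohort_spec(n_group_a = 30, n_group_b = 30,
                                     n_regions = 20,
                                     module_assignment = rep(1:2, each = 10),
                                     r_within = 0.8, r_between = 0,
                                     tiv_beta = 0, seed = 42))
  cfg <- perm_config(n_perm = 5, seed = 1, grid = density_grid(0.1, 0.2, 0.1),
                     n_null = 2)
  expect_error(permutation_test(coh, cfg), "disconnected")
})
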