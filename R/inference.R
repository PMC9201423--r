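# Group comparison of SCN metrics by label permutation, per density and on
# AUCs across the density grid, with BH-FDR for the 90 regional tests.

GLOBAL_METRICS <- c("cp", "lp", "eglob", "eloc", "trans", "assort", "q",
                    "gamma", "lambda", "sigma")

#' Permutation-test configuration
#'
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer RNG seed controlling permutations and null networks.
#' @param grid an [density_grid()].
#' @param n_null null networks per graph for gamma/lambda/sigma (default 20).
#' @param alpha significance level (default 0.05).
#' @param threshold_mode `"signed"` (default) or `"absolute"` edge ranking.
#' @param null_model `"degree_preserving"` (default) or `"er"`.
#' @param swap_factor successful double-edge swaps per edge in the
#'   degree-preserving null (default 10).
#' @return An object of class `scn_perm_config`.
#' @export
perm_config <- function(n_perm = 1000, seed = 1L, grid = density_grid(),
                        n_null = 20, alpha = 0.05,
                        threshold_mode = c("signed", "absolute"),
                        null_model = c("degree_preserving", "er"),
                        swap_factor = 10) {
  threshold_mode <- match.arg(threshold_mode)
  null_model <- match.arg(null_model)
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  stopifnot(inherits(grid, "scn_density_grid"))
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 grid = grid, n_null = as.integer(n_null), alpha = alpha,
                 threshold_mode = threshold_mode, null_model = null_model,
                 swap_factor = swap_factor),
            class = "scn_perm_config")
}

#' Area under a metric curve across the density grid
#'
#' Trapezoidal integral of a metric over the density points.
#'
#' @param values metric values, one per grid point (no missing values).
#' @param grid an [density_grid()] (or a numeric vector of density points).
#' @return The trapezoidal AUC.
#' @export
auc <- function(values, grid = density_grid()) {
  x <- if (inherits(grid, "scn_density_grid")) grid$points else as.numeric(grid)
  if (length(values) != length(x))
    stop("curve must be defined at every grid point (", length(x),
         " points, got ", length(values), " values)")
  if (anyNA(values)) stop("curve has missing values at ",
                          sum(is.na(values)), " grid point(s)")
  sum(diff(x) * (head(values, -1) + tail(values, -1)) / 2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, capped at 1.
#'
#' @param p_values vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# metric curves for one group: residualize -> correlate -> threshold across
# the (nested) grid -> all metrics + null normalization, in one C++ pass
group_metric_curves <- function(volumes, tiv, cfg, seed, with_nulls = TRUE) {
  res <- residualize_matrix(volumes, tiv)
  r <- stats::cor(res)
  diag(r) <- 0
  n <- ncol(volumes)
  e <- vapply(cfg$grid$points, edge_count_at, integer(1), n = n)
  .cpp_metric_curves(r, e, cfg$n_null, cfg$swap_factor, as.integer(seed),
                     with_nulls, cfg$threshold_mode == "absolute",
                     cfg$null_model == "er")
}

next_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)

#' Permutation test of group differences in SCN metrics
#'
#' For the observed group labels and for each of `n_perm` random
#' reassignments preserving group sizes, the full pipeline is re-run per
#' group: TIV residualization within group, Pearson association, density
#' thresholding across the grid, and all global metrics (including the
#' null-normalized gamma/lambda/sigma) plus normalized nodal betweenness.
#' Two-tailed p-values use the add-one rule
#' `p = (1 + #\{|diff_perm| >= |diff_obs|\}) / (n_perm + 1)`, computed per
#' metric per density, for each metric's AUC across the grid, and per region
#' for betweenness (regional statistic: group difference of normalized
#' betweenness averaged over the density grid), the latter corrected by
#' BH-FDR. A permuted split whose graph is disconnected at the smallest grid
#' density is resampled (bounded retries; the count is reported).
#'
#' The two groups of every pair (observed or permuted) share one
#' null-network seed, i.e. common random numbers: group differences in
#' gamma/lambda/sigma are not inflated by independent null-ensemble noise,
#' and comparing a group against an exact copy of itself yields zero
#' differences and p-values of 1 for every metric.
#'
#' All differences are reported as group B minus group A (second minus first
#' group level).
#'
#' @param cohort an `scn_cohort` with exactly two group levels.
#' @param config an [perm_config()].
#' @return A list of class `scn_comparison`; see Details.
#' @export
permutation_test <- function(cohort, config = perm_config()) {
  stopifnot(inherits(config, "scn_perm_config"))
  atlas <- cohort_atlas(cohort)
  lv <- sort(unique(cohort$group))
  if (length(lv) != 2) stop("cohort must contain exactly two groups, found: ",
                            paste(lv, collapse = ", "))
  X <- cohort_volumes(cohort)
  tiv <- cohort$tiv
  n <- nrow(X)
  ia <- which(cohort$group == lv[1])
  n_a <- length(ia)

  set.seed(config$seed)
  # both groups of a pair share one null-network seed (common random numbers):
  # group differences are not inflated by independent null-ensemble noise, and
  # identical groups yield exactly zero differences for every metric
  s0 <- next_seed()
  obs_a <- group_metric_curves(X[ia, , drop = FALSE], tiv[ia], config, s0)
  obs_b <- group_metric_curves(X[-ia, , drop = FALSE], tiv[-ia], config, s0)
  if (!all(obs_a$connected) || !all(obs_b$connected))
    stop("observed group network is disconnected at the smallest grid density ",
         config$grid$d_min, "; raise d_min (see find_dmin)")

  n_d <- length(config$grid$points)
  mnames <- GLOBAL_METRICS
  obs_curve_diff <- obs_b$global[, mnames, drop = FALSE] -
                    obs_a$global[, mnames, drop = FALSE]
  auc_a <- apply(obs_a$global[, mnames, drop = FALSE], 2, auc, grid = config$grid)
  auc_b <- apply(obs_b$global[, mnames, drop = FALSE], 2, auc, grid = config$grid)
  obs_auc_diff <- auc_b - auc_a
  obs_bc_a <- colMeans(obs_a$bc_norm)
  obs_bc_b <- colMeans(obs_b$bc_norm)
  obs_bc_diff <- obs_bc_b - obs_bc_a

  cnt_density <- matrix(0L, n_d, length(mnames), dimnames = list(NULL, mnames))
  cnt_auc <- stats::setNames(integer(length(mnames)), mnames)
  cnt_bc <- integer(ncol(X))
  n_resampled <- 0L
  max_attempts <- 10L * config$n_perm + 100L

  k <- 0L
  attempts <- 0L
  while (k < config$n_perm) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("too many permuted splits produced disconnected networks at density ",
           config$grid$d_min, " (", n_resampled, " resampled)")
    idx <- sample(n, n_a)
    sk <- next_seed()
    pa <- group_metric_curves(X[idx, , drop = FALSE], tiv[idx], config, sk)
    if (!all(pa$connected)) { n_resampled <- n_resampled + 1L; next }
    pb <- group_metric_curves(X[-idx, , drop = FALSE], tiv[-idx], config, sk)
    if (!all(pb$connected)) { n_resampled <- n_resampled + 1L; next }
    k <- k + 1L

    pdiff <- pb$global[, mnames, drop = FALSE] - pa$global[, mnames, drop = FALSE]
    exceed <- abs(pdiff) >= abs(obs_curve_diff)
    exceed[is.na(exceed)] <- TRUE   # undefined permuted stat counts as extreme
    cnt_density <- cnt_density + exceed
    pauc_a <- apply(pa$global[, mnames, drop = FALSE], 2, auc, grid = config$grid)
    pauc_b <- apply(pb$global[, mnames, drop = FALSE], 2, auc, grid = config$grid)
    eauc <- abs(pauc_b - pauc_a) >= abs(obs_auc_diff)
    eauc[is.na(eauc)] <- TRUE
    cnt_auc <- cnt_auc + eauc
    pbc <- colMeans(pb$bc_norm) - colMeans(pa$bc_norm)
    cnt_bc <- cnt_bc + (abs(pbc) >= abs(obs_bc_diff))
  }

  denom <- config$n_perm + 1
  nodal_p_raw <- (1 + cnt_bc) / denom
  nodal <- data.frame(region = as.character(atlas),
                      bc_norm_a = unname(obs_bc_a),
                      bc_norm_b = unname(obs_bc_b),
                      diff = unname(obs_bc_diff),
                      p_raw = nodal_p_raw,
                      p_fdr = bh_fdr(nodal_p_raw),
                      stringsAsFactors = FALSE)

  structure(list(
    grid = config$grid,
    metrics = mnames,
    group_levels = lv,
    curves_a = obs_a$global,
    curves_b = obs_b$global,
    per_density_p = (1 + cnt_density) / denom,
    auc_a = auc_a, auc_b = auc_b,
    auc_diff = obs_auc_diff,
    auc_p = (1 + cnt_auc) / denom,
    nodal = nodal,
    n_resampled = n_resampled,
    config = config
  ), class = "scn_comparison")
}

#' @export
print.scn_comparison <- function(x, ...) {
  cat("SCN group comparison (", x$group_levels[2], " - ", x$group_levels[1],
      "), ", x$config$n_perm, " permutations, densities ",
      x$grid$d_min, "-", x$grid$d_max, "\n", sep = "")
  tab <- data.frame(metric = x$metrics, auc_diff = x$auc_diff, p = x$auc_p)
  print(tab, row.names = FALSE)
  sig <- x$nodal[x$nodal$p_fdr < x$config$alpha, "region"]
  cat("regions significant after FDR: ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}

#' Demographic matching tests
#'
#' Between-group tests of the demographic decorations: chi-square
#' (uncorrected) for categorical variables, two-sample Student's t-test for
#' continuous variables, Wilcoxon rank-sum for ordinal variables.
#'
#' @param cohort an `scn_cohort` with `age`, `sex`, `education` columns.
#' @return A data.frame with one row per variable: test name, statistic,
#'   degrees of freedom where applicable, and p-value.
#' @export
demographic_matching <- function(cohort) {
  for (col in c("age", "sex", "education")) {
    if (!col %in% names(cohort)) stop("missing demographic column: ", col)
  }
  grp <- factor(cohort$group)
  ct <- suppressWarnings(stats::chisq.test(table(grp, cohort$sex), correct = FALSE))
  tt <- stats::t.test(age ~ grp, data = cohort, var.equal = TRUE)
  wt <- suppressWarnings(stats::wilcox.test(education ~ grp, data = cohort,
                                            exact = FALSE, correct = TRUE))
  data.frame(
    variable = c("sex", "age", "education"),
    test = c("chi-square", "t-test", "rank-sum"),
    statistic = c(unname(ct$statistic), unname(tt$statistic), unname(wt$statistic)),
    df = c(unname(ct$parameter), unname(tt$parameter), NA),
    p = c(ct$p.value, tt$p.value, wt$p.value),
    stringsAsFactors = FALSE
  )
}
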